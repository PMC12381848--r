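#' Distance-RMSD between two conformations
#'
#' Root-mean-square deviation of the internal C-alpha distance sets,
#' `dRMSD = sqrt((1/N_p) sum_ij (r_ij_k - r_ij_l)^2)`: symmetric, zero iff the
#' internal distances coincide, and invariant to rigid motions (no
#' superposition needed).
#'
#' @param conf_k,conf_l conformations as `n x 3` matrices with equal residue
#'   counts.
#' @param exclude_adjacent see [internal_distances()].
#' @return Length in Angstrom.
#' @export
distance_rmsd <- function(conf_k, conf_l, exclude_adjacent = FALSE) {
  if (nrow(conf_k) != nrow(conf_l))
    abort(sprintf("residue count mismatch: %d vs %d", nrow(conf_k), nrow(conf_l)))
  dk <- internal_distances(conf_k, exclude_adjacent)
  dl <- internal_distances(conf_l, exclude_adjacent)
  sqrt(mean((dk[1, ] - dl[1, ])^2))
}

#' Resolve a region selection to conformation indices
#'
#' Regions of the projected space can be selected three ways: an explicit
#' index vector, a polygon in projection coordinates (vertices in order;
#' even-odd rule), or top-density seeding — the densest point of the
#' projection's kernel density estimate plus all points within `radius` of it.
#'
#' @param proj a `conf_projection`.
#' @param indices explicit pooled-conformation indices.
#' @param polygon two-column matrix of polygon vertices in projection
#'   coordinates.
#' @param radius selection radius around the density mode (top-density
#'   seeding); used when neither `indices` nor `polygon` is given.
#' @param bandwidth optional KDE bandwidth for top-density seeding.
#' @return Integer vector of row positions into `proj` (>= 2 of them).
#' @export
select_region <- function(proj, indices = NULL, polygon = NULL, radius = NULL,
                          bandwidth = NULL) {
  sel <- if (!is.null(indices)) {
    match(indices, proj$index)
  } else if (!is.null(polygon)) {
    which(point_in_polygon(proj$x, proj$y, polygon))
  } else if (!is.null(radius)) {
    dens <- kde_density(proj, bandwidth)$density
    mode <- which.max(dens)
    which((proj$x - proj$x[mode])^2 + (proj$y - proj$y[mode])^2 <= radius^2)
  } else {
    abort("supply one of `indices`, `polygon` or `radius`")
  }
  if (anyNA(sel)) abort("selection refers to indices absent from the projection")
  if (length(sel) < 2) abort("region selection must resolve to at least 2 conformations")
  sel
}

# Even-odd ray-casting point-in-polygon test (boundary points count as inside).
point_in_polygon <- function(px, py, polygon) {
  vx <- polygon[, 1]; vy <- polygon[, 2]
  nv <- length(vx)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Extract a local conformational signature
#'
#' Characterises a selected region of the projection by its distance-RMSD
#' medoid: the member conformation minimising the mean dRMSD to all other
#' selected members (exhaustive search; ties broken by lowest pooled index),
#' together with its `n_neighbors` closest members and their contact map. The
#' medoid plus neighbors are the region's representative structures.
#'
#' @param pooled the `pooled_set` the projection was computed from.
#' @param selection integer vector of pooled-conformation indices (e.g. from
#'   [select_region()]), `>= 2` of them.
#' @param n_neighbors neighbors displayed with the medoid (default 30; must be
#'   smaller than the selection).
#' @param contact_cutoff C-alpha contact distance for the signature's contact
#'   map (Angstrom, default 8).
#' @param exclude_adjacent see [internal_distances()].
#' @return An `lcs_result`: list with `medoid` (pooled index), `neighbors`
#'   (pooled indices, closest first), `members` (tibble `index`, `label`,
#'   `drmsd_to_medoid`, `member`), `mean_drmsd` (medoid's mean dRMSD over the
#'   selection, Angstrom) and `contact_map` (matrix of contact frequencies over
#'   medoid + neighbors).
#' @export
extract_lcs <- function(pooled, selection, n_neighbors = 30L,
                        contact_cutoff = 8, exclude_adjacent = FALSE) {
  stopifnot(inherits(pooled, "pooled_set"))
  selection <- sort(unique(as.integer(selection)))
  if (length(selection) < 2) abort("selection must contain at least 2 conformations")
  if (any(selection < 1 | selection > n_frames(pooled)))
    abort("selection indices out of range of the pooled set")
  if (n_neighbors >= length(selection))
    abort(sprintf("`n_neighbors` (%d) must be smaller than the selection (%d members)",
                  n_neighbors, length(selection)))
  sub <- pooled$coords[selection, , , drop = FALSE]
  D <- cpp_internal_distances(sub, exclude_adjacent)
  dr <- cpp_drmsd_matrix(D)
  mean_dr <- rowSums(dr) / (nrow(dr) - 1)
  med_local <- which.min(mean_dr)  # which.min takes the first (= lowest index) tie
  to_medoid <- dr[med_local, ]
  ord <- order(to_medoid, selection)
  ord <- ord[ord != med_local]
  nb_local <- ord[seq_len(n_neighbors)]
  members <- tibble::tibble(
    index = selection,
    label = pooled$meta$label[selection],
    drmsd_to_medoid = to_medoid,
    member = seq_along(selection) %in% c(med_local, nb_local)
  )
  cm_sel <- selection[c(med_local, nb_local)]
  cmap <- contact_map(pooled$coords[cm_sel, , , drop = FALSE], cutoff = contact_cutoff)
  structure(list(medoid = selection[med_local],
                 neighbors = selection[nb_local],
                 members = members,
                 mean_drmsd = mean_dr[med_local],
                 contact_map = cmap,
                 contact_cutoff = contact_cutoff),
            class = "lcs_result")
}

#' @export
print.lcs_result <- function(x, ...) {
  cat(sprintf("<lcs_result> medoid %d + %d neighbors (of %d selected), mean dRMSD %.2f A\n",
              x$medoid, length(x$neighbors), nrow(x$members), x$mean_drmsd))
  invisible(x)
}

#' @export
tidy.lcs_result <- function(x, ...) x$members

#' @export
glance.lcs_result <- function(x, ...) {
  tibble::tibble(medoid = x$medoid, n_members = sum(x$members$member),
                 n_selected = nrow(x$members), mean_drmsd = x$mean_drmsd,
                 contact_cutoff = x$contact_cutoff)
}

#' Contact frequency map of a set of conformations
#'
#' Fraction of conformations in which each residue pair sits within `cutoff`
#' Angstrom. The result is symmetric with 1 on the diagonal by convention
#' (a residue is always in contact with itself).
#'
#' @param x a [conf_ensemble()], `pooled_set`, or coordinate array
#'   `(n_frames, n_residues, 3)`.
#' @param cutoff C-alpha contact distance (Angstrom, default 8).
#' @return An `n_residues x n_residues` matrix of frequencies in `[0, 1]`.
#' @export
contact_map <- function(x, cutoff = 8) {
  coords <- if (is.array(x) && !is.matrix(x)) x else x$coords
  nres <- dim(coords)[2]
  D <- cpp_internal_distances(coords, FALSE)
  freq <- colMeans(D <= cutoff)
  out <- diag(1, nres)
  out[lower.tri(out)] <- 0
  p <- 1L
  for (i in seq_len(nres - 1)) {
    for (j in (i + 1):nres) {
      out[i, j] <- out[j, i] <- freq[p]
      p <- p + 1L
    }
  }
  out
}

#' Least-squares superposition onto a reference (visualisation only)
#'
#' Kabsch alignment of each frame onto a reference conformation; affects no
#' statistic in the package (all metrics are internal-coordinate based) but
#' makes LCS members superposable in figures and exported PDBs.
#'
#' @param coords array `(n_frames, n_residues, 3)`.
#' @param reference `n_residues x 3` matrix (default: first frame).
#' @return Aligned array of the same shape.
#' @export
superpose_frames <- function(coords, reference = NULL) {
  if (is.null(reference)) {
    reference <- coords[1, , ]
    dim(reference) <- dim(coords)[2:3]
  }
  ref_c <- scale(reference, scale = FALSE)
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    m <- coords[f, , ]
    dim(m) <- dim(coords)[2:3]
    mc <- scale(m, scale = FALSE)
    s <- svd(t(mc) %*% ref_c)
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    out[f, , ] <- mc %*% t(rot)
  }
  out
}
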