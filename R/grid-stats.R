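#' Grid occupancy of a shared projection
#'
#' Overlays a regular grid (default 27 x 27) on the tight bounding box of the
#' projected points and counts, per bin, the conformations contributed by each
#' model. Bin intervals are half-open except the final right/top edge, so every
#' point falls in exactly one bin. Bins with fewer than `min_count` points in
#' total carry poor statistics (border effects) and are masked invalid for the
#' fraction/overlap statistics.
#'
#' @param proj a `conf_projection` from [force_scheme()] (any tibble with
#'   `x`, `y`, `label` works).
#' @param grid grid dimensions `c(nx, ny)` (default `c(27, 27)`).
#' @param min_count minimum per-bin total for a bin to be considered valid
#'   (default 3).
#' @return A `grid_occupancy`: list with `counts` (array `nx x ny x n_models`),
#'   `totals` (`nx x ny`), `fraction` (per-model relative fraction, `NA` on
#'   empty bins), `valid` (logical mask), `labels`, bin `breaks_x`/`breaks_y`,
#'   and `min_count`.
#' @export
bin_projection <- function(proj, grid = c(27, 27), min_count = 3L) {
  if (nrow(proj) == 0) abort("projection is empty")
  if (length(grid) == 1) grid <- c(grid, grid)
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  if (nx < 1 || ny < 1) abort("grid dimensions must be positive")
  rx <- range(proj$x); ry <- range(proj$y)
  if (diff(rx) == 0 || diff(ry) == 0)
    abort("degenerate bounding box: all points identical along one axis")
  breaks_x <- seq(rx[1], rx[2], length.out = nx + 1L)
  breaks_y <- seq(ry[1], ry[2], length.out = ny + 1L)
  ix <- pmin(findInterval(proj$x, breaks_x, left.open = FALSE), nx)
  iy <- pmin(findInterval(proj$y, breaks_y, left.open = FALSE), ny)
  labels <- sort(unique(proj$label))
  counts <- array(0L, c(nx, ny, length(labels)), dimnames = list(NULL, NULL, labels))
  for (w in seq_along(labels)) {
    sel <- proj$label == labels[w]
    if (any(sel)) {
      tab <- table(factor(ix[sel], levels = seq_len(nx)),
                   factor(iy[sel], levels = seq_len(ny)))
      counts[, , w] <- as.integer(tab)
    }
  }
  totals <- apply(counts, c(1, 2), sum)
  valid <- totals >= min_count
  fraction <- counts
  storage.mode(fraction) <- "double"
  for (w in seq_along(labels)) {
    fw <- fraction[, , w] / totals
    fw[totals == 0] <- NA_real_
    fraction[, , w] <- fw
  }
  structure(list(counts = counts, totals = totals, fraction = fraction,
                 valid = valid, labels = labels,
                 breaks_x = breaks_x, breaks_y = breaks_y,
                 min_count = as.integer(min_count),
                 bin_x = ix, bin_y = iy, point_label = proj$label),
            class = "grid_occupancy")
}

#' @export
print.grid_occupancy <- function(x, ...) {
  cat(sprintf("<grid_occupancy> %d x %d grid, %d models, %d/%d valid bins (min_count %d)\n",
              dim(x$totals)[1], dim(x$totals)[2], length(x$labels),
              sum(x$valid), length(x$valid), x$min_count))
  invisible(x)
}

#' @export
tidy.grid_occupancy <- function(x, ...) {
  nx <- dim(x$totals)[1]; ny <- dim(x$totals)[2]
  base <- tidyr::expand_grid(bin_x = seq_len(nx), bin_y = seq_len(ny))
  purrr::map_dfr(x$labels, function(w) {
    tibble::tibble(base,
                   label = w,
                   n = as.vector(x$counts[, , w]),
                   total = as.vector(x$totals),
                   fraction = as.vector(x$fraction[, , w]),
                   valid = as.vector(x$valid))
  })
}

#' Relative fraction surface of one model
#'
#' Per-bin occupancy proportion `F_ij = n_ij / N_ij` of model `model`:
#' dimensionless, 1 where the model populates a bin exclusively, and `NA` on
#' bins masked invalid (poor statistics) or empty.
#'
#' @param occ a [bin_projection()] result.
#' @param model model label.
#' @return A tibble `bin_x`, `bin_y`, `x`, `y` (bin centers), `n`, `total`,
#'   `fraction`, `valid`.
#' @export
relative_fraction_map <- function(occ, model) {
  stopifnot(inherits(occ, "grid_occupancy"))
  if (!model %in% occ$labels)
    abort(sprintf("unknown model '%s'; available: %s", model,
                  paste(occ$labels, collapse = ", ")))
  nx <- dim(occ$totals)[1]; ny <- dim(occ$totals)[2]
  cx <- (occ$breaks_x[-1] + occ$breaks_x[-(nx + 1)]) / 2
  cy <- (occ$breaks_y[-1] + occ$breaks_y[-(ny + 1)]) / 2
  grid <- tidyr::expand_grid(bin_x = seq_len(nx), bin_y = seq_len(ny))
  fr <- occ$fraction[, , model]
  fr[!occ$valid] <- NA_real_
  tibble::tibble(grid,
                 x = cx[grid$bin_x], y = cy[grid$bin_y],
                 n = occ$counts[cbind(grid$bin_x, grid$bin_y,
                                      match(model, occ$labels))],
                 total = occ$totals[cbind(grid$bin_x, grid$bin_y)],
                 fraction = fr[cbind(grid$bin_x, grid$bin_y)],
                 valid = occ$valid[cbind(grid$bin_x, grid$bin_y)])
}

#' Density overlap between two models
#'
#' Measures how much of the (gridded) conformational space two models share.
#' Each model's relative-fraction surface over the valid bins is L2-normalised,
#' `f_ij = F_ij / sqrt(sum F^2)`, and the overlap is the inner product
#' `O = sum_ij f_ij^w f_ij^z`: 1 for identical density distributions, 0 for
#' disjoint supports (a cosine similarity of occupancy surfaces).
#'
#' @param occ a [bin_projection()] result.
#' @param w,z model labels.
#' @return Overlap in `[0, 1]`.
#' @export
density_overlap <- function(occ, w, z) {
  stopifnot(inherits(occ, "grid_occupancy"))
  for (m in c(w, z)) {
    if (!m %in% occ$labels) abort(sprintf("unknown model '%s'", m))
  }
  fw <- normalized_surface(occ, w)
  fz <- normalized_surface(occ, z)
  sum(fw * fz)
}

normalized_surface <- function(occ, model) {
  fr <- occ$fraction[, , model]
  fr[!occ$valid | is.na(fr)] <- 0
  norm <- sqrt(sum(fr^2))
  if (norm == 0)
    abort(sprintf("model '%s' has no mass on valid bins; overlap undefined", model))
  fr / norm
}

#' Overlap matrix over all model pairs
#'
#' @param occ a [bin_projection()] result.
#' @return An `overlap_table`: symmetric matrix with unit diagonal.
#' @export
overlap_matrix <- function(occ) {
  stopifnot(inherits(occ, "grid_occupancy"))
  surfaces <- lapply(occ$labels, function(w) normalized_surface(occ, w))
  k <- length(surfaces)
  O <- diag(1, k)
  dimnames(O) <- list(occ$labels, occ$labels)
  if (k > 1) {
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        O[a, b] <- O[b, a] <- sum(surfaces[[a]] * surfaces[[b]])
      }
    }
  }
  structure(O, class = c("overlap_table", class(O)))
}

#' @export
tidy.overlap_table <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    w = rep(rownames(m), times = ncol(m)),
    z = rep(colnames(m), each = nrow(m)),
    overlap = as.vector(m),
    se = if (!is.null(attr(x, "se"))) as.vector(attr(x, "se")) else NA_real_
  ) %>% dplyr::filter(match(.data$w, rownames(m)) <= match(.data$z, colnames(m)))
}

#' Bootstrap uncertainty of the overlap matrix
#'
#' The overlap's sampling noise is estimated by resampling conformations with
#' replacement within each model, re-binning on the fixed grid of the observed
#' projection, and recomputing all pairwise overlaps. (A stand-in for an
#' undocumented uncertainty procedure; replicate projections probe layout
#' noise instead, see [replicate_projections()].)
#'
#' @param proj a `conf_projection`.
#' @param grid,min_count as in [bin_projection()].
#' @param n_boot number of bootstrap resamples (`>= 2`).
#' @param seed RNG seed.
#' @return An `overlap_table` (point estimate on the full data) with attribute
#'   `"se"`: the matrix of bootstrap standard deviations.
#' @export
overlap_uncertainty <- function(proj, grid = c(27, 27), min_count = 3L,
                                n_boot = 50L, seed = 1L) {
  if (n_boot < 2) abort("`n_boot` must be >= 2")
  occ <- bin_projection(proj, grid, min_count)
  point <- overlap_matrix(occ)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx_by_label <- split(seq_len(nrow(proj)), proj$label)
  boots <- array(NA_real_, c(length(occ$labels), length(occ$labels), n_boot))
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_label, function(ii) sample(ii, length(ii), replace = TRUE)))
    res <- proj[take, , drop = FALSE]
    occ_b <- bin_projection_fixed(res, occ)
    # a resample can strand a diffuse model entirely on invalid bins; skip it
    boots[, , b] <- tryCatch(unclass(overlap_matrix(occ_b)),
                             error = function(e) NA_real_)
  }
  se <- apply(boots, c(1, 2), sd, na.rm = TRUE)
  dimnames(se) <- dimnames(point)
  attr(point, "se") <- se
  point
}

# Re-bin points on the grid of an existing occupancy (fixed breaks).
bin_projection_fixed <- function(proj, occ) {
  nx <- dim(occ$totals)[1]; ny <- dim(occ$totals)[2]
  ix <- pmax(pmin(findInterval(proj$x, occ$breaks_x, left.open = FALSE), nx), 1L)
  iy <- pmax(pmin(findInterval(proj$y, occ$breaks_y, left.open = FALSE), ny), 1L)
  labels <- occ$labels
  counts <- array(0L, c(nx, ny, length(labels)), dimnames = list(NULL, NULL, labels))
  for (w in seq_along(labels)) {
    sel <- proj$label == labels[w]
    if (any(sel)) {
      tab <- table(factor(ix[sel], levels = seq_len(nx)),
                   factor(iy[sel], levels = seq_len(ny)))
      counts[, , w] <- as.integer(tab)
    }
  }
  totals <- apply(counts, c(1, 2), sum)
  fraction <- counts
  storage.mode(fraction) <- "double"
  for (w in seq_along(labels)) {
    fw <- fraction[, , w] / totals
    fw[totals == 0] <- NA_real_
    fraction[, , w] <- fw
  }
  out <- occ
  out$counts <- counts
  out$totals <- totals
  out$fraction <- fraction
  out$valid <- totals >= occ$min_count
  out
}

#' Projection entropy of one model
#'
#' Shannon entropy of the model's bin-occupancy distribution,
#' `H = -sum_ij p_ij log(p_ij)` with `p_ij = n_ij / N` and `0 log 0 = 0`:
#' a dimensionless heterogeneity proxy, 0 when all conformations share one bin
#' and `H_max = log(n_bins)` when they spread uniformly. Reported alongside
#' the normalised value `H / H_max`.
#'
#' @param occ a [bin_projection()] result.
#' @param model model label (default: all models).
#' @return A tibble `label`, `n`, `entropy`, `h_max`, `normalized`.
#' @export
projection_entropy <- function(occ, model = NULL) {
  stopifnot(inherits(occ, "grid_occupancy"))
  labels <- if (is.null(model)) occ$labels else model
  h_max <- log(length(occ$totals))
  purrr::map_dfr(labels, function(w) {
    if (!w %in% occ$labels) abort(sprintf("unknown model '%s'", w))
    nw <- occ$counts[, , w]
    total <- sum(nw)
    if (total == 0) abort(sprintf("model '%s' has no conformations", w))
    p <- nw[nw > 0] / total
    H <- -sum(p * log(p))
    tibble::tibble(label = w, n = total, entropy = H, h_max = h_max,
                   normalized = H / h_max)
  })
}

#' Entropy robustness across replicate projections
#'
#' Bins each replicate projection independently and reports the mean and
#' standard deviation of the normalised projection entropy per model: low
#' spread indicates the heterogeneity ranking is a property of the ensembles,
#' not of projection noise.
#'
#' @param projections list of `conf_projection` objects over the same pooled
#'   set (e.g. from [replicate_projections()]).
#' @param grid,min_count as in [bin_projection()].
#' @return An `entropy_report` tibble: `label`, `mean_normalized`,
#'   `sd_normalized`, `mean_entropy`, `sd_entropy`, `n_replicates`.
#' @export
entropy_across_replicates <- function(projections, grid = c(27, 27), min_count = 3L) {
  if (length(projections) < 2) abort("need at least 2 replicate projections")
  labs <- lapply(projections, function(p) sort(unique(p$label)))
  if (!all(vapply(labs, identical, logical(1), labs[[1]])))
    abort("replicates carry inconsistent model labels")
  per <- purrr::imap_dfr(projections, function(p, i) {
    occ <- bin_projection(p, grid, min_count)
    dplyr::mutate(projection_entropy(occ), replicate = i)
  })
  out <- per %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(mean_normalized = mean(.data$normalized),
                     sd_normalized = sd(.data$normalized),
                     mean_entropy = mean(.data$entropy),
                     sd_entropy = sd(.data$entropy),
                     n_replicates = dplyr::n(), .groups = "drop")
  attr(out, "per_replicate") <- per
  class(out) <- c("entropy_report", class(out))
  out
}

#' @export
tidy.entropy_report <- function(x, ...) {
  per <- attr(x, "per_replicate")
  if (is.null(per)) tibble::as_tibble(x) else per
}

#' @export
glance.entropy_report <- function(x, ...) {
  tibble::tibble(n_models = nrow(x),
                 n_replicates = x$n_replicates[1],
                 max_sd_normalized = max(x$sd_normalized))
}

#' Gaussian kernel density at the projected points
#'
#' 2-D Gaussian kernel density estimate with a diagonal Scott's-rule bandwidth
#' (`h_d = sd_d * n^(-1/6)`), evaluated at each projected point: the effective
#' density of states of the layout, used to rank high-density regions when
#' seeding local conformational signatures.
#'
#' @param proj a `conf_projection` (or tibble with `x`, `y`).
#' @param bandwidth optional length-2 numeric overriding Scott's rule.
#' @return The input as a tibble with a `density` column (integrates to ~1
#'   over the plane).
#' @export
kde_density <- function(proj, bandwidth = NULL) {
  n <- nrow(proj)
  if (n < 2) abort("need at least 2 points for a density estimate")
  if (sd(proj$x) == 0 && sd(proj$y) == 0) abort("zero-variance point cloud")
  if (is.null(bandwidth)) {
    bandwidth <- c(sd(proj$x), sd(proj$y)) * n^(-1 / 6)
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  if (any(bandwidth <= 0)) abort("bandwidth must be positive in both directions")
  dens <- kde_eval(proj$x, proj$y, proj$x, proj$y, bandwidth)
  out <- tibble::as_tibble(proj)
  out$density <- dens
  out
}

# Evaluate the Gaussian product-kernel density of data (dx, dy) at (px, py).
kde_eval <- function(px, py, dx, dy, bandwidth) {
  hx <- bandwidth[1]; hy <- bandwidth[2]
  n <- length(dx)
  kx <- outer(px, dx, function(a, b) stats::dnorm(a - b, sd = hx))
  ky <- outer(py, dy, function(a, b) stats::dnorm(a - b, sd = hy))
  rowSums(kx * ky) / n
}
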