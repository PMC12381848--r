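#' Sequence-distance weighting for internal-distance comparison
#'
#' The Gaussian width used when comparing the (i, j) internal distance of two
#' conformations grows slowly with sequence separation:
#' `sigma_ij = |i - j|^0.15` (Angstrom). Long-range distances are therefore
#' allowed more slack than short-range ones, which are geometrically stiffer.
#'
#' @param i,j 1-based residue positions (vectorised); only `|i - j|` matters.
#' @return Weights in Angstrom.
#' @examples
#' sigma_weight(1, 2)   # 1
#' sigma_weight(1, 33)  # 32^0.15
#' @export
sigma_weight <- function(i, j) {
  if (any(i == j)) abort("sigma_weight is undefined for i == j (zero sequence separation)")
  abs(i - j)^0.15
}

#' Internal C-alpha distance set of conformations
#'
#' All pairwise C-alpha distances r_ij (i < j) per conformation, the
#' rotation/translation-invariant representation every comparison in this
#' package is built on. Pair order: i outer, j inner.
#'
#' @param x a conformation (`n x 3` matrix), [conf_ensemble()], or
#'   `pooled_set`.
#' @param exclude_adjacent drop bonded `|i - j| = 1` pairs (sensitivity
#'   option; default keeps all pairs).
#' @return A matrix `n_conformations x n_pairs` with attribute `"separations"`
#'   (the `|i - j|` of each column).
#' @export
internal_distances <- function(x, exclude_adjacent = FALSE) {
  coords <- if (is.matrix(x)) {
    array(x, c(1L, nrow(x), 3L))
  } else {
    x$coords
  }
  nres <- dim(coords)[2]
  if (nres < 2) abort("need at least 2 residues")
  D <- cpp_internal_distances(coords, exclude_adjacent)
  attr(D, "separations") <- cpp_pair_separations(nres, exclude_adjacent)
  D
}

#' Pairwise structural similarity Q_w of two conformations
#'
#' A Gaussian-weighted agreement of all internal C-alpha distances:
#' `Q_w = (1/N_p) * sum_ij exp(-(r_ij_k - r_ij_l)^2 / (2 sigma_ij^2))`,
#' with `sigma_ij` from [sigma_weight()]. Equals 1 for identical internal
#' geometry and decays toward 0 for very different structures. Symmetric in
#' its arguments and invariant to rigid motions.
#'
#' @param conf_k,conf_l conformations as `n x 3` coordinate matrices with the
#'   same residue count.
#' @param exclude_adjacent see [internal_distances()].
#' @return Similarity in `(0, 1]`.
#' @export
qw_pair <- function(conf_k, conf_l, exclude_adjacent = FALSE) {
  if (nrow(conf_k) != nrow(conf_l))
    abort(sprintf("residue count mismatch: %d vs %d", nrow(conf_k), nrow(conf_l)))
  dk <- internal_distances(conf_k, exclude_adjacent)
  dl <- internal_distances(conf_l, exclude_adjacent)
  sep <- attr(dk, "separations")
  mean(exp(-(dk[1, ] - dl[1, ])^2 / (2 * sigma_weight(0, sep)^2)))
}

#' Pairwise dissimilarity matrix over a pooled conformation set
#'
#' Computes `delta_kl = 1 - Q_w(k, l)` for all conformation pairs of the
#' pooled set: a symmetric, zero-diagonal matrix with entries in `[0, 1)`,
#' the input of the force-scheme projection.
#'
#' @param pooled a `pooled_set` from [pool_ensembles()] (a single
#'   [conf_ensemble()] is accepted and pooled on the fly).
#' @param exclude_adjacent see [internal_distances()].
#' @param max_conformations memory guard: refuse pooled counts whose dense
#'   matrix would be unreasonably large (default 12000, ~1.2 GB).
#' @return A `dissim_matrix`: numeric matrix with the pooled `meta` tibble
#'   attached as attribute `"meta"`.
#' @export
dissimilarity_matrix <- function(pooled, exclude_adjacent = FALSE,
                                 max_conformations = 12000L) {
  if (inherits(pooled, "conf_ensemble")) pooled <- pool_ensembles(list(pooled))
  stopifnot(inherits(pooled, "pooled_set"))
  n <- n_frames(pooled)
  if (n < 1) abort("pooled set is empty")
  if (n > max_conformations)
    abort(sprintf(paste0("pooled set has %d conformations; a dense %d x %d matrix exceeds the ",
                         "memory guard (max_conformations = %d). Subsample further or raise the cap."),
                  n, n, n, max_conformations))
  D <- internal_distances(pooled, exclude_adjacent)
  sep <- attr(D, "separations")
  delta <- cpp_delta_matrix(D, 2 * sigma_weight(0, sep)^2)
  structure(delta, meta = pooled$meta, class = c("dissim_matrix", class(delta)))
}

# Validate a square dissimilarity matrix (symmetric, zero diagonal, [0, 1)).
validate_delta <- function(delta) {
  if (!is.matrix(delta) || nrow(delta) != ncol(delta))
    abort("dissimilarity matrix must be square")
  if (any(abs(diag(delta)) > 0)) abort("dissimilarity matrix must have a zero diagonal")
  if (max(abs(delta - t(delta))) > 1e-12) abort("dissimilarity matrix must be symmetric")
  if (min(delta) < 0 || max(delta) >= 1 + 1e-12)
    abort("dissimilarity entries must lie in [0, 1)")
  invisible(delta)
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("<dissim_matrix> %d x %d, range [%.4f, %.4f]\n",
              nrow(x), ncol(x), min(x), max(x[upper.tri(x)])))
  invisible(x)
}
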