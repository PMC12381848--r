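#' Force-scheme 2-D embedding of a dissimilarity matrix
#'
#' Places one point per conformation in the plane and iteratively moves each
#' point toward or away from every other so that planar distances approach the
#' dissimilarities: a shared "effective conformational space" in which the
#' proximity of points reflects structural similarity across all pooled
#' models. Points are initialised uniformly in the unit square from `seed`;
#' each sweep performs a full Gauss-Seidel pass over ordered point pairs with
#' a learning rate decaying linearly from `lr_start` to `lr_end`. Runs are
#' deterministic given the seed; projection noise across seeds is handled by
#' [replicate_projections()].
#'
#' @param delta dissimilarity matrix from [dissimilarity_matrix()] (symmetric,
#'   zero diagonal, entries in `[0, 1)`).
#' @param seed integer seed for the random initial layout.
#' @param max_iter number of sweeps (default 100).
#' @param lr_start,lr_end learning-rate bounds (defaults 1 and 0.05; the update is a damped per-point mean-residual step, so 1 is a full step).
#' @param align rotate the final layout onto its principal axes (visual
#'   comparability across replicates only; default `FALSE`, coordinates are
#'   reported as produced).
#' @return A `conf_projection`: tibble with columns `index`, `label`,
#'   `source_frame`, `x`, `y`; attributes `seed`, `stress` (per-sweep residual
#'   sum of squares) and `n_iter`.
#' @export
force_scheme <- function(delta, seed = 1L, max_iter = 100L,
                         lr_start = 1, lr_end = 0.05, align = FALSE) {
  validate_delta(unclass(delta))
  if (max_iter < 1) abort("`max_iter` must be >= 1")
  n <- nrow(delta)
  meta <- attr(delta, "meta")
  if (is.null(meta))
    meta <- tibble::tibble(index = seq_len(n), label = "all", source_frame = seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x0 <- matrix(stats::runif(2 * n), n, 2)
  res <- cpp_force_scheme(unclass(delta), x0, as.integer(max_iter), lr_start, lr_end)
  xy <- res$coords
  if (align && n > 1) {
    ctr <- scale(xy, scale = FALSE)
    xy <- ctr %*% svd(ctr)$v
  }
  out <- tibble::tibble(index = meta$index, label = meta$label,
                        source_frame = meta$source_frame,
                        x = xy[, 1], y = xy[, 2])
  attr(out, "seed") <- as.integer(seed)
  attr(out, "stress") <- res$stress
  attr(out, "n_iter") <- as.integer(max_iter)
  class(out) <- c("conf_projection", class(out))
  out
}

#' Replicate projections for noise estimation
#'
#' The force scheme gives slightly different layouts for different random
#' initialisations; global properties (grid statistics, entropies) are stable.
#' This runs independent projections with seeds `base_seed, base_seed + 1, ...`
#' so downstream statistics can be reported as mean +/- standard deviation
#' across replicates.
#'
#' @param delta dissimilarity matrix.
#' @param n_replicates number of independent projections (`>= 1`).
#' @param base_seed seed of the first replicate.
#' @param ... passed to [force_scheme()].
#' @return A list of `conf_projection` objects.
#' @export
replicate_projections <- function(delta, n_replicates, base_seed = 1L, ...) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  lapply(seq_len(n_replicates) - 1L, function(k) force_scheme(delta, seed = base_seed + k, ...))
}

#' @export
print.conf_projection <- function(x, ...) {
  st <- attr(x, "stress")
  cat(sprintf("<conf_projection> %d points, %d models, seed %d, final stress %.4g\n",
              nrow(x), length(unique(x$label)), attr(x, "seed"), st[length(st)]))
  NextMethod()
}

#' @export
tidy.conf_projection <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "conf_projection")
  out
}

#' @export
glance.conf_projection <- function(x, ...) {
  st <- attr(x, "stress")
  tibble::tibble(n_points = nrow(x), n_models = length(unique(x$label)),
                 seed = attr(x, "seed"), n_iter = attr(x, "n_iter"),
                 final_stress = st[length(st)])
}
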