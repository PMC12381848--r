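#' Radius of gyration per conformation
#'
#' Root-mean-square distance of the beads from their center of mass, with
#' uniform masses (C-alpha-only model): the standard compactness observable
#' used to color the projected conformational space.
#'
#' @param x a conformation (`n x 3` matrix), [conf_ensemble()], or
#'   `pooled_set`.
#' @return For a single conformation, a length-1 numeric (Angstrom); otherwise
#'   a numeric vector with one value per frame.
#' @export
radius_of_gyration <- function(x) {
  coords <- if (is.matrix(x)) array(x, c(1L, nrow(x), 3L)) else x$coords
  if (dim(coords)[2] < 2) abort("need at least 2 beads")
  nf <- dim(coords)[1]
  ctr <- apply(coords, c(1, 3), mean)
  dim(ctr) <- c(nf, 3L)
  sq <- matrix(0, nf, dim(coords)[2])
  for (d in 1:3) {
    slab <- coords[, , d]
    dim(slab) <- dim(coords)[1:2]
    sq <- sq + (slab - ctr[, d])^2
  }
  rg <- sqrt(rowMeans(sq))
  if (is.matrix(x)) rg[1] else rg
}

#' Observable track over a pooled set
#'
#' Pairs each pooled conformation with a named scalar observable, the form
#' consumed by the plotting and smoothness utilities.
#'
#' @param pooled a `pooled_set`.
#' @param values numeric vector, one value per conformation, or a function of
#'   an `n x 3` coordinate matrix applied to every frame.
#' @param name observable name (e.g. `"rg"`).
#' @return A tibble `index`, `label`, `value` with attribute `"observable"`.
#' @export
observable_track <- function(pooled, values = radius_of_gyration, name = "rg") {
  stopifnot(inherits(pooled, "pooled_set"))
  if (is.function(values)) {
    if (identical(values, radius_of_gyration)) {
      values <- radius_of_gyration(pooled)
    } else {
      values <- vapply(seq_len(n_frames(pooled)),
                       function(i) values(frame_coords(pooled, i)), numeric(1))
    }
  }
  if (length(values) != n_frames(pooled))
    abort("one observable value per pooled conformation required")
  if (any(!is.finite(values))) abort("observable values must be finite")
  out <- tibble::tibble(index = pooled$meta$index, label = pooled$meta$label,
                        value = as.numeric(values))
  attr(out, "observable") <- name
  out
}

#' Smoothness of an observable over the projected space
#'
#' Quantifies the claim that an observable "varies smoothly" across the
#' projection: the mean absolute difference between each point's value and the
#' mean over its `k` nearest planar neighbors, normalised by the same statistic
#' under random assignment (the track's mean absolute deviation from its
#' mean). 0 for a locally constant field; ~1 when the observable carries no
#' spatial structure. Scale- and shift-invariant in the track values.
#'
#' @param proj a `conf_projection`.
#' @param track numeric vector of observable values (one per projected point)
#'   or an [observable_track()] tibble.
#' @param k number of nearest neighbors (default 10).
#' @return A single dimensionless score.
#' @export
smoothness_score <- function(proj, track, k = 10L) {
  values <- if (is.data.frame(track)) track$value else as.numeric(track)
  n <- nrow(proj)
  if (length(values) != n) abort("track length must match the projection")
  if (k < 1) abort("`k` must be >= 1")
  k <- min(k, n - 1L)
  spread <- mean(abs(values - mean(values)))
  if (spread == 0) return(0)
  d2 <- as.matrix(stats::dist(cbind(proj$x, proj$y)))^2
  diag(d2) <- Inf
  local_dev <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    abs(values[i] - mean(values[nb]))
  }, numeric(1))
  mean(local_dev) / spread
}
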