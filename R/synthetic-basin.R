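#' Generate a tight conformational basin around a template
#'
#' Disordered chains sampled by [generate_polymer_ensemble()] are individually
#' heterogeneous; a *basin* ensemble instead emulates a locally ordered
#' conformational mode: one template conformation is drawn from `spec`, and
#' every frame is the template perturbed by `n_pivots` small pivot moves
#' (the tail beyond a random bead rotated by a Gaussian angle about a random
#' axis). Bond lengths are preserved exactly; excluded volume and any
#' `exclusive_motif` of the spec are re-enforced by rejection. Small
#' `pivot_sd` gives a tight basin (small within-ensemble dissimilarity), which
#' is what produces clear multi-basin structure in the projected space.
#'
#' @param spec a [polymer_spec()]; its seed fixes both the template and the
#'   perturbations.
#' @param n_frames conformations to draw, `>= 1`.
#' @param pivot_sd standard deviation of the pivot angle in radians
#'   (default 0.08).
#' @param n_pivots pivot moves per frame (default 10).
#' @param label ensemble label.
#' @param max_frame_retries rejection cap per frame (default 10000).
#' @return A [conf_ensemble()].
#' @export
generate_basin_ensemble <- function(spec, n_frames, pivot_sd = 0.08,
                                    n_pivots = 10L, label = "basin",
                                    max_frame_retries = 10000L) {
  stopifnot(inherits(spec, "polymer_spec"))
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (pivot_sd <= 0) abort("`pivot_sd` must be > 0")
  template <- generate_polymer_ensemble(spec, 1L, label = label)
  motif <- spec$exclusive_motif
  if (is.null(motif)) {
    pairs <- matrix(integer(0), 0, 2)
    cuts <- numeric(0)
  } else {
    pairs <- do.call(rbind, lapply(motif, function(m) as.integer(m[1:2])))
    cuts <- vapply(motif, function(m) as.numeric(m[3]), numeric(1))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)
  coords <- cpp_basin_frames(frame_coords(template, 1), as.integer(n_frames),
                             as.integer(n_pivots), pivot_sd,
                             spec$excluded_volume, pairs, cuts,
                             as.integer(max_frame_retries))
  conf_ensemble(coords, label)
}
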