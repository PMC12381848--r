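#' Conformation ensembles
#'
#' A `conf_ensemble` is a labeled set of frames of one molecular system, each
#' frame an ordered list of C-alpha positions in Angstrom. Coordinates are held
#' as a numeric array with dimensions `(n_frames, n_residues, 3)`; frames carry
#' their original trajectory indices so subsampled sets stay traceable.
#'
#' @param coords numeric array `(n_frames, n_residues, 3)`, or a list of
#'   `n_residues x 3` matrices.
#' @param label single string naming the model/system (e.g. `"WT"`).
#' @param source_indices integer vector of original frame numbers (1-based,
#'   strictly increasing). Defaults to `1:n_frames`.
#' @return A `conf_ensemble` object.
#' @examples
#' ens <- conf_ensemble(array(rnorm(5 * 4 * 3), c(5, 4, 3)), label = "toy")
#' n_frames(ens)
#' @export
conf_ensemble <- function(coords, label, source_indices = NULL) {
  if (is.list(coords)) {
    nr <- unique(vapply(coords, nrow, integer(1)))
    if (length(nr) != 1L) {
      bad <- which(vapply(coords, nrow, integer(1)) != nrow(coords[[1]]))[1]
      abort(sprintf("mixed residue counts across frames: frame %d has %d residues, frame 1 has %d",
                    bad, nrow(coords[[bad]]), nrow(coords[[1]])))
    }
    arr <- array(0, c(length(coords), nr, 3))
    for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.character(label) || length(label) != 1L) abort("`label` must be a single string")
  nf <- dim(coords)[1]
  if (is.null(source_indices)) source_indices <- seq_len(nf)
  source_indices <- as.integer(source_indices)
  if (length(source_indices) != nf) abort("`source_indices` must have one entry per frame")
  if (nf > 1 && any(diff(source_indices) <= 0)) abort("`source_indices` must be strictly increasing")
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  structure(list(label = label, coords = coords, source_indices = source_indices),
            class = "conf_ensemble")
}

#' @rdname conf_ensemble
#' @param x a `conf_ensemble` or `pooled_set`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.conf_ensemble <- function(x) dim(x$coords)[1]

#' @export
n_frames.pooled_set <- function(x) dim(x$coords)[1]

#' @rdname conf_ensemble
#' @export
n_residues <- function(x) UseMethod("n_residues")

#' @export
n_residues.conf_ensemble <- function(x) dim(x$coords)[2]

#' @export
n_residues.pooled_set <- function(x) dim(x$coords)[2]

#' Extract one frame as an n_residues x 3 coordinate matrix
#' @param x a `conf_ensemble` or `pooled_set`.
#' @param i frame index (within `x`).
#' @export
frame_coords <- function(x, i) {
  stopifnot(length(i) == 1L, i >= 1, i <= dim(x$coords)[1])
  m <- x$coords[i, , , drop = TRUE]
  dim(m) <- c(dim(x$coords)[2], 3L)
  m
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> label '%s': %d frames x %d residues\n",
              x$label, n_frames(x), n_residues(x)))
  invisible(x)
}

#' Subsample an ensemble by burn-in and stride
#'
#' Retains frames `discard + 1, discard + 1 + stride, ...` (i.e. the half-open
#' window after discarding the first `discard` frames, stepped by `stride`),
#' the standard equilibration/decorrelation rule for trajectory analysis.
#' Source frame indices are updated so provenance survives.
#'
#' @param ensemble a [conf_ensemble()].
#' @param discard number of leading frames to drop (burn-in), `>= 0`.
#' @param stride keep every `stride`-th remaining frame, `>= 1`.
#' @return A `conf_ensemble` with the retained frames.
#' @examples
#' ens <- conf_ensemble(array(rnorm(30 * 4 * 3), c(30, 4, 3)), "toy")
#' n_frames(subsample_frames(ens, discard = 10, stride = 5))
#' @export
subsample_frames <- function(ensemble, discard = 0L, stride = 1L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (discard < 0) abort("`discard` must be >= 0")
  if (stride < 1) abort("`stride` must be >= 1")
  nf <- n_frames(ensemble)
  if (discard >= nf) {
    abort(sprintf("discarding %d frames empties an ensemble of %d frames", discard, nf))
  }
  keep <- seq.int(discard + 1L, nf, by = stride)
  conf_ensemble(ensemble$coords[keep, , , drop = FALSE], ensemble$label,
                ensemble$source_indices[keep])
}

#' Pool labeled ensembles into one conformation set
#'
#' Concatenates several ensembles (all sharing a residue count) into a single
#' pooled set over which one dissimilarity matrix and one shared 2-D projection
#' are computed, so all models live in the same effective conformational space.
#'
#' @param ensembles a list of [conf_ensemble()] objects with distinct labels.
#' @return A `pooled_set`: coordinates array plus a `meta` tibble
#'   (`index`, `label`, `source_frame`) and per-model index `offsets`.
#' @export
pool_ensembles <- function(ensembles) {
  if (inherits(ensembles, "conf_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1L,
            all(vapply(ensembles, inherits, logical(1), "conf_ensemble")))
  nres <- vapply(ensembles, n_residues, integer(1))
  if (length(unique(nres)) != 1L) {
    bad <- which(nres != nres[1])[1]
    abort(sprintf("residue count mismatch: '%s' has %d residues but '%s' has %d",
                  ensembles[[1]]$label, nres[1], ensembles[[bad]]$label, nres[bad]))
  }
  labels <- vapply(ensembles, function(e) e$label, character(1))
  if (anyDuplicated(labels)) abort("ensemble labels must be distinct")
  counts <- vapply(ensembles, n_frames, integer(1))
  total <- sum(counts)
  coords <- array(0, c(total, nres[1], 3))
  at <- 0L
  for (e in ensembles) {
    coords[at + seq_len(n_frames(e)), , ] <- e$coords
    at <- at + n_frames(e)
  }
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  meta <- tibble::tibble(
    index = seq_len(total),
    label = rep(labels, counts),
    source_frame = unlist(lapply(ensembles, function(e) e$source_indices))
  )
  structure(list(coords = coords, meta = meta,
                 offsets = tibble::tibble(label = labels, start = starts, end = ends)),
            class = "pooled_set")
}

#' @export
print.pooled_set <- function(x, ...) {
  cat(sprintf("<pooled_set> %d conformations x %d residues, %d models (%s)\n",
              n_frames(x), n_residues(x), nrow(x$offsets),
              paste(x$offsets$label, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pooled_set <- function(x, ...) x$meta
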