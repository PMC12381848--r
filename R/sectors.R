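#' Cylindrical sector geometry around a reference particle
#'
#' Defines how the space around a disc-shaped binding partner (e.g. a
#' nucleosome core) is carved into binding sectors: frames whose tracked
#' center of mass lies beyond `unbound_radius` (cylindrical radial distance)
#' or outside the axial slab are "unbound" (sector 0); bound frames fall into
#' `n_wedges` equal azimuthal wedges, sector 1 centered on the `dyad`
#' direction, subsequent sectors counter-clockwise.
#'
#' @param unbound_radius radial threshold (Angstrom) beyond which a frame is
#'   unbound.
#' @param n_wedges number of azimuthal wedges for the bound sectors (default 7,
#'   giving sectors 1-7 plus the unbound sector 0).
#' @param dyad lab-frame direction fixing azimuth zero (projected onto the
#'   particle plane); by convention points at the dyad.
#' @param axial_halfwidth half-width of the axial slab (Angstrom); frames with
#'   larger axial offset count as unbound. Default `Inf` (one slab).
#' @return A `sector_geometry` object.
#' @export
sector_geometry <- function(unbound_radius, n_wedges = 7L, dyad = c(1, 0, 0),
                            axial_halfwidth = Inf) {
  if (unbound_radius <= 0) abort("`unbound_radius` must be > 0")
  if (n_wedges < 1) abort("`n_wedges` must be >= 1: sectors must cover the azimuth")
  if (length(dyad) != 3 || sqrt(sum(dyad^2)) < 1e-12)
    abort("`dyad` must be a non-zero 3-vector")
  if (axial_halfwidth <= 0) abort("`axial_halfwidth` must be > 0")
  structure(list(unbound_radius = unbound_radius, n_wedges = as.integer(n_wedges),
                 dyad = dyad / sqrt(sum(dyad^2)), axial_halfwidth = axial_halfwidth),
            class = "sector_geometry")
}

# Orthonormal cylindrical frame of a particle: origin at its center of
# geometry, axial axis = smallest-extent principal axis, azimuth zero at the
# projected dyad direction. Axis signs are fixed deterministically.
particle_frame <- function(particle, geometry) {
  center <- colMeans(particle)
  ev <- eigen(stats::cov(particle), symmetric = TRUE)
  axial <- ev$vectors[, 3]
  if (axial[which.max(abs(axial))] < 0) axial <- -axial
  e1 <- geometry$dyad - sum(geometry$dyad * axial) * axial
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) abort("dyad direction is parallel to the particle axis")
  e1 <- e1 / n1
  e2 <- c(axial[2] * e1[3] - axial[3] * e1[2],
          axial[3] * e1[1] - axial[1] * e1[3],
          axial[1] * e1[2] - axial[2] * e1[1])
  list(center = center, e1 = e1, e2 = e2, axial = axial)
}

#' Center of mass of a residue range, per frame
#'
#' Uniform bead masses (C-alpha-only model).
#'
#' @param ensemble a [conf_ensemble()] or `pooled_set`.
#' @param residues integer vector (or range) of residue indices to average.
#' @return An `n_frames x 3` matrix.
#' @export
domain_com <- function(ensemble, residues) {
  if (length(residues) == 2 && residues[2] > residues[1] + 1)
    residues <- seq.int(residues[1], residues[2])
  sub <- ensemble$coords[, residues, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Assign frames to cylindrical binding sectors
#'
#' Maps each tracked center-of-mass position to exactly one sector: sector 0
#' (unbound) iff it lies beyond the radial threshold or outside the axial slab,
#' otherwise the azimuthal wedge containing it, with sector 1 centered on the
#' dyad direction.
#'
#' @param com `n x 3` matrix of tracked center-of-mass coordinates (lab frame),
#'   one row per frame.
#' @param particle reference-particle coordinate matrix defining the
#'   cylindrical frame.
#' @param geometry a [sector_geometry()].
#' @return A tibble of class `sector_trace` with columns `frame`, `r` (radial
#'   distance, Angstrom), `theta` (azimuth, radians in `[-pi, pi)`), `z` (axial
#'   offset, Angstrom) and `sector`.
#' @export
assign_sectors <- function(com, particle, geometry) {
  stopifnot(inherits(geometry, "sector_geometry"))
  com <- rbind(com)
  fr <- particle_frame(particle, geometry)
  rel <- sweep(com, 2, fr$center)
  x <- rel %*% fr$e1
  y <- rel %*% fr$e2
  z <- drop(rel %*% fr$axial)
  r <- drop(sqrt(x^2 + y^2))
  theta <- drop(atan2(y, x))
  wedge <- 2 * pi / geometry$n_wedges
  idx <- floor(((theta + wedge / 2) %% (2 * pi)) / wedge) + 1L
  sector <- ifelse(r > geometry$unbound_radius | abs(z) > geometry$axial_halfwidth,
                   0L, as.integer(idx))
  out <- tibble::tibble(frame = seq_len(nrow(com)), r = r, theta = theta,
                        z = z, sector = sector)
  class(out) <- c("sector_trace", class(out))
  out
}

#' Sector occupancy frequencies
#'
#' Percentage of frames spent in each sector over the whole trace; sectors
#' never visited are reported with 0 so the table always covers sector 0 and
#' all wedges. Percentages sum to 100.
#'
#' @param trace a `sector_trace` from [assign_sectors()] (or any tibble with a
#'   `sector` column).
#' @param n_wedges number of bound sectors in the geometry (default 7).
#' @return A tibble with columns `sector`, `n_frames`, `percent`.
#' @export
sector_occupancy <- function(trace, n_wedges = 7L) {
  if (nrow(trace) == 0) abort("trace is empty")
  counts <- table(factor(trace$sector, levels = 0:n_wedges))
  tibble::tibble(sector = 0:n_wedges,
                 n_frames = as.integer(counts),
                 percent = 100 * as.integer(counts) / nrow(trace))
}

#' Stratify a projection by binding sector
#'
#' Splits the projected points by the sector of the corresponding frame,
#' enabling per-sector overlays, densities, and local conformational
#' signatures on the shared conformational space.
#'
#' @param proj a [force_scheme()] projection whose points correspond 1:1, in
#'   order, to the frames of `trace`.
#' @param trace a `sector_trace` from [assign_sectors()].
#' @return The projection tibble with a `sector` column appended, ordered as
#'   `proj`.
#' @export
stratify_projection <- function(proj, trace) {
  if (nrow(proj) != nrow(trace))
    abort(sprintf("projection has %d points but trace has %d frames", nrow(proj), nrow(trace)))
  out <- tibble::as_tibble(proj)
  out$sector <- trace$sector
  out
}
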