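#' Specification of a synthetic protein-particle binding system
#'
#' Describes a three-domain chain (disordered N-terminal tail, globular core,
#' disordered C-terminal tail) whose globular-domain center of mass moves among
#' cylindrical sectors around a fixed disc-shaped reference particle — the
#' geometry of a linker histone exploring binding modes around a nucleosome.
#' The sector schedule is the ground truth against which sector assignment is
#' tested.
#'
#' @param n_nter,n_glob,n_cter residues per domain; all `>= 1` and
#'   `n_glob >= 4`.
#' @param reference_radius radius (Angstrom) of the fixed reference particle
#'   disc (default 45, nucleosome-like).
#' @param sector_schedule list of `c(sector_id, n_frames)` pairs; sector ids in
#'   `0..7` (0 = unbound), `n_frames >= 1`.
#' @param seed integer RNG seed.
#' @return A `sector_system_spec` object.
#' @export
sector_system_spec <- function(n_nter, n_glob, n_cter, reference_radius = 45,
                               sector_schedule = list(c(1, 100)), seed = 1L) {
  if (n_nter < 1 || n_cter < 1) abort("tail domains must have at least 1 residue each")
  if (n_glob < 4) abort("`n_glob` must be >= 4")
  if (reference_radius <= 0) abort("`reference_radius` must be > 0")
  if (!is.list(sector_schedule) || length(sector_schedule) == 0)
    abort("`sector_schedule` must be a non-empty list of c(sector, n_frames) pairs")
  for (s in sector_schedule) {
    if (length(s) != 2 || s[1] < 0 || s[1] > 7 || s[2] < 1)
      abort("each schedule entry must be c(sector in 0..7, n_frames >= 1)")
  }
  structure(list(n_nter = as.integer(n_nter), n_glob = as.integer(n_glob),
                 n_cter = as.integer(n_cter), reference_radius = reference_radius,
                 sector_schedule = sector_schedule, seed = as.integer(seed)),
            class = "sector_system_spec")
}

#' Fixed disc-shaped reference particle
#'
#' Deterministic bead model of a disc (three stacked rings plus axis beads),
#' used as the fixed binding partner of [generate_sector_system()]. Its
#' principal axes define the cylindrical frame: the smallest-extent axis is the
#' disc symmetry (axial) axis.
#'
#' @param radius disc radius in Angstrom.
#' @param half_height half the disc height in Angstrom.
#' @return An `n x 3` coordinate matrix.
#' @export
reference_particle <- function(radius = 45, half_height = 25) {
  zs <- c(-half_height, 0, half_height)
  beads <- list()
  for (z in zs) {
    a_out <- seq(0, 2 * pi, length.out = 25)[-25]
    a_in <- seq(0, 2 * pi, length.out = 13)[-13]
    beads[[length(beads) + 1]] <- cbind(radius * cos(a_out), radius * sin(a_out), z)
    beads[[length(beads) + 1]] <- cbind(radius / 2 * cos(a_in), radius / 2 * sin(a_in), z)
    beads[[length(beads) + 1]] <- matrix(c(0, 0, z), 1, 3)
  }
  unname(do.call(rbind, beads))
}

#' Generate a scheduled protein-particle trajectory with ground truth
#'
#' For each schedule entry, draws chain conformations and rigidly places them
#' so the globular-domain center of mass lies inside the scheduled cylindrical
#' sector (safely away from sector boundaries, so ground truth is
#' recoverable). Returns the ensemble, the true per-frame sector labels, the
#' particle coordinates, and the sector geometry used.
#'
#' @param spec a [sector_system_spec()].
#' @return A list of class `sector_system` with elements `ensemble`
#'   ([conf_ensemble()]), `truth` (tibble `frame`, `sector`), `particle`
#'   (coordinate matrix), `geometry` ([sector_geometry()]), and
#'   `globular_range` (residue index range of the tracked domain).
#' @export
generate_sector_system <- function(spec) {
  stopifnot(inherits(spec, "sector_system_spec"))
  particle <- reference_particle(spec$reference_radius)
  geom <- sector_geometry(unbound_radius = spec$reference_radius + 20)
  n_res <- spec$n_nter + spec$n_glob + spec$n_cter
  glob <- spec$n_nter + seq_len(spec$n_glob)
  total <- sum(vapply(spec$sector_schedule, function(s) s[2], numeric(1)))
  coords <- array(0, c(total, n_res, 3))
  sectors <- integer(total)
  wedge <- 2 * pi / geom$n_wedges
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  at <- 0L
  for (entry in spec$sector_schedule) {
    s <- entry[1]; nf <- as.integer(entry[2])
    raw <- cpp_polymer_frames(nf, n_res, 3.8, 0.5, 2.0,
                              matrix(integer(0), 0, 2), numeric(0), 200L, 1000L)
    for (f in seq_len(nf)) {
      if (s == 0) {
        rho <- geom$unbound_radius + 25 + 15 * runif(1)
        theta <- 2 * pi * runif(1)
      } else {
        # stay in the middle 60% of the wedge and well inside the bound shell
        rho <- spec$reference_radius * (1.05 + 0.2 * runif(1))
        theta <- (s - 1) * wedge + wedge * 0.3 * (2 * runif(1) - 1)
      }
      z <- 4 * (2 * runif(1) - 1)
      target <- c(rho * cos(theta), rho * sin(theta), z)
      fr <- raw[f, , ]
      dim(fr) <- c(n_res, 3L)
      shift <- target - colMeans(fr[glob, , drop = FALSE])
      coords[at + f, , ] <- sweep(fr, 2, shift, "+")
      sectors[at + f] <- s
    }
    at <- at + nf
  }
  structure(list(
    ensemble = conf_ensemble(coords, "sector_system"),
    truth = tibble::tibble(frame = seq_len(total), sector = sectors),
    particle = particle,
    geometry = geom,
    globular_range = range(glob)
  ), class = "sector_system")
}
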