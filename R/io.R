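#' Write an ensemble as a C-alpha-only multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, one `CA` atom per residue (glycine
#' placeholder residue names, chain A), fixed-width PDB columns with
#' 3-decimal coordinates.
#'
#' @param ensemble a [conf_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  nr <- n_residues(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   generated by idpscape: %s, %d frames x %d residues",
                     ensemble$label, nf, nr), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(ensemble, f)
    writeLines(sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       seq_len(nr), seq_len(nr), m[, 1], m[, 2], m[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a C-alpha trajectory from a multi-model PDB
#'
#' Retains only `CA` atoms (or the sole bead per residue), ordered by residue
#' sequence number within each model. All frames must have identical residue
#' counts.
#'
#' @param path PDB file path.
#' @param label ensemble label (default: file name without extension).
#' @return A [conf_ensemble()].
#' @export
read_calpha_pdb <- function(path, label = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) abort(sprintf("no atom records found in %s: not a PDB coordinate file", path))
  # frame id per line: cumulative MODEL count (single implicit model if none)
  frame_id <- cumsum(is_model)
  if (max(frame_id) == 0) frame_id <- frame_id + 1L
  atom_lines <- lines[is_atom]
  atom_frame <- frame_id[is_atom]
  name <- trimws(substr(atom_lines, 13, 16))
  keep <- name == "CA"
  if (!any(keep)) abort(sprintf("no C-alpha atoms found in %s", path))
  atom_lines <- atom_lines[keep]
  atom_frame <- atom_frame[keep]
  resid <- as.integer(substr(atom_lines, 23, 26))
  x <- as.numeric(substr(atom_lines, 31, 38))
  y <- as.numeric(substr(atom_lines, 39, 46))
  z <- as.numeric(substr(atom_lines, 47, 54))
  frames <- sort(unique(atom_frame))
  counts <- tabulate(match(atom_frame, frames))
  if (length(unique(counts)) != 1) {
    bad <- frames[which(counts != counts[1])[1]]
    abort(sprintf("mixed residue counts across frames in %s: frame %d has %d C-alpha atoms, expected %d",
                  path, bad, counts[which(frames == bad)], counts[1]))
  }
  nr <- counts[1]
  coords <- array(0, c(length(frames), nr, 3))
  for (fi in seq_along(frames)) {
    sel <- which(atom_frame == frames[fi])
    ord <- sel[order(resid[sel])]
    coords[fi, , ] <- cbind(x[ord], y[ord], z[ord])
  }
  conf_ensemble(coords, label)
}

#' Write an ensemble as a CHARMM-style DCD trajectory
#'
#' Minimal single-precision DCD (no unit cell, no fixed atoms, little-endian
#' Fortran records), readable by the usual MD toolchains.
#'
#' @param ensemble a [conf_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  nr <- n_residues(ensemble)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf      # frames in file
  icntrl[2] <- 1L      # first step
  icntrl[3] <- 1L      # step interval
  icntrl[4] <- nf      # total steps
  icntrl[20] <- 24L    # CHARMM version stamp
  rec(function(c2) {
    writeBin(charToRaw("CORD"), c2)
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", paste("idpscape ensemble", ensemble$label))
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeBin(charToRaw(title), c2)
  })
  rec(function(c2) writeBin(nr, c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    m <- frame_coords(ensemble, f)
    for (d in 1:3) {
      rec(function(c2) writeBin(as.numeric(m[, d]), c2, size = 4, endian = "little"))
    }
  }
  invisible(path)
}

#' Read a CHARMM-style DCD trajectory
#'
#' Supports the plain fixed-atom-free, cell-free layout written by
#' [write_dcd()] and common MD engines; single or double precision via the
#' record sizes.
#'
#' @param path DCD file path.
#' @param topology optional path to a C-alpha PDB supplying the residue count
#'   for validation.
#' @param label ensemble label (default: file name).
#' @return A [conf_ensemble()].
#' @export
read_dcd <- function(path, topology = NULL, label = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  read_rec <- function() {
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(len) == 0) return(NULL)
    payload <- readBin(con, "raw", len)
    tail <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(tail) == 0 || tail != len) abort(sprintf("corrupt DCD record in %s", path))
    payload
  }
  hdr <- read_rec()
  if (is.null(hdr) || length(hdr) < 84 || rawToChar(hdr[1:4]) != "CORD")
    abort(sprintf("%s is not a DCD trajectory (missing CORD magic)", path))
  icntrl <- readBin(hdr[5:84], "integer", 20, size = 4, endian = "little")
  nf_declared <- icntrl[1]
  read_rec()  # title block
  nr <- readBin(read_rec(), "integer", 1, size = 4, endian = "little")
  if (!is.null(topology)) {
    topo <- read_calpha_pdb(topology)
    if (n_residues(topo) != nr)
      abort(sprintf("topology %s has %d residues but DCD stores %d atoms",
                    topology, n_residues(topo), nr))
  }
  frames <- list()
  repeat {
    xr <- read_rec()
    if (is.null(xr)) break
    sz <- length(xr) / nr
    if (!sz %in% c(4, 8)) abort(sprintf("unexpected coordinate record size in %s", path))
    xyz <- matrix(0, nr, 3)
    xyz[, 1] <- readBin(xr, "numeric", nr, size = sz, endian = "little")
    xyz[, 2] <- readBin(read_rec(), "numeric", nr, size = sz, endian = "little")
    xyz[, 3] <- readBin(read_rec(), "numeric", nr, size = sz, endian = "little")
    frames[[length(frames) + 1]] <- xyz
  }
  if (length(frames) == 0) abort(sprintf("no frames found in %s", path))
  if (nf_declared > 0 && length(frames) != nf_declared)
    warning(sprintf("%s declares %d frames but contains %d", path, nf_declared, length(frames)))
  conf_ensemble(frames, label)
}

#' Write an ensemble as a delimited coordinate table
#'
#' Long-format TSV with columns `frame`, `residue`, `x`, `y`, `z` (Angstrom).
#'
#' @param ensemble a [conf_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coord_table <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  nr <- n_residues(ensemble)
  tab <- tibble::tibble(
    frame = rep(ensemble$source_indices, each = nr),
    residue = rep(seq_len(nr), nf),
    x = as.vector(t(ensemble$coords[, , 1])),
    y = as.vector(t(ensemble$coords[, , 2])),
    z = as.vector(t(ensemble$coords[, , 3]))
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a delimited coordinate table
#'
#' @param path TSV/CSV with columns `frame`, `residue`, `x`, `y`, `z`.
#' @param label ensemble label (default: file name).
#' @return A [conf_ensemble()].
#' @export
read_coord_table <- function(path, label = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  tab <- if (grepl("\\.csv$", path)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  need <- c("frame", "residue", "x", "y", "z")
  if (!all(need %in% names(tab)))
    abort(sprintf("coordinate table %s must have columns %s", path,
                  paste(need, collapse = ", ")))
  frames <- sort(unique(tab$frame))
  counts <- table(tab$frame)
  if (length(unique(counts)) != 1) {
    bad <- names(counts)[which(counts != counts[1])[1]]
    abort(sprintf("mixed residue counts across frames in %s: frame %s", path, bad))
  }
  nr <- as.integer(counts[1])
  coords <- array(0, c(length(frames), nr, 3))
  for (fi in seq_along(frames)) {
    sub <- tab[tab$frame == frames[fi], ]
    sub <- sub[order(sub$residue), ]
    coords[fi, , ] <- cbind(sub$x, sub$y, sub$z)
  }
  conf_ensemble(coords, label, source_indices = as.integer(frames))
}

#' Load a C-alpha trajectory, dispatching on file format
#'
#' Multi-model PDB (`.pdb`), DCD (`.dcd`, optionally validated against a
#' topology PDB), and delimited coordinate tables (`.tsv`/`.csv`) are
#' supported. XTC is not: no reader for its compressed-integer codec is
#' available here, and requesting one raises an explicit error.
#'
#' @param path trajectory file path.
#' @param topology optional topology PDB (used by the DCD route).
#' @param label ensemble label (default: file name).
#' @return A [conf_ensemble()].
#' @export
load_calpha_trajectory <- function(path, topology = NULL, label = NULL) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    pdb = read_calpha_pdb(path, label),
    dcd = read_dcd(path, topology, label),
    xtc = abort("XTC trajectories are not supported (no reader for the XTC codec is available); convert to DCD or multi-model PDB"),
    tsv = ,
    csv = read_coord_table(path, label),
    abort(sprintf("unrecognised trajectory format '.%s' (supported: .pdb, .dcd, .tsv, .csv)", ext))
  )
}

#' Write ground-truth or assigned sector labels
#'
#' Two-column delimited text (`frame`, `sector`).
#'
#' @param trace tibble with `frame` and `sector` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sector_labels <- function(trace, path) {
  readr::write_tsv(trace[, intersect(c("frame", "r", "theta", "z", "sector"), names(trace))], path)
  invisible(path)
}
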