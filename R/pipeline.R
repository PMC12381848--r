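#' Configuration of a full landscape-comparison run
#'
#' Collects everything [run_pipeline()] needs: input ensembles (paths to
#' trajectories or synthetic [polymer_spec()]s), the subsampling rule,
#' dissimilarity/projection hyperparameters, grid settings, LCS settings, and
#' seeds. A persisted config plus its seeds reproduces every deterministic
#' artifact.
#'
#' @param models named list: each element either a file path (string) or a
#'   list `list(spec = polymer_spec(...), n_frames = ...)`.
#' @param discard,stride subsampling rule applied to every model (defaults 0
#'   and 1: keep everything).
#' @param exclude_adjacent dissimilarity pair-set flag.
#' @param max_conformations memory guard for the dissimilarity matrix.
#' @param seed master seed; projection replicates use `seed, seed + 1, ...`.
#' @param max_iter,lr_start,lr_end force-scheme settings.
#' @param n_replicates replicate projections for the entropy report.
#' @param grid,min_count grid settings for the occupancy statistics.
#' @param n_boot bootstrap resamples for overlap uncertainties.
#' @param lcs_neighbors,lcs_radius,contact_cutoff LCS settings (densest-region
#'   seeding with `lcs_radius`; `NULL` skips the LCS stage).
#' @param out_dir output directory (created if missing); `NULL` returns
#'   results in memory only.
#' @param write_figures also render PNG figures for each result table.
#' @return A `landscape_config` object.
#' @export
landscape_config <- function(models, discard = 0L, stride = 1L,
                             exclude_adjacent = FALSE, max_conformations = 12000L,
                             seed = 1L, max_iter = 100L, lr_start = 1,
                             lr_end = 0.05, n_replicates = 10L,
                             grid = c(27, 27), min_count = 3L, n_boot = 30L,
                             lcs_neighbors = 30L, lcs_radius = NULL,
                             contact_cutoff = 8, out_dir = NULL,
                             write_figures = FALSE) {
  if (length(models) == 0 || is.null(names(models)) || any(names(models) == ""))
    abort("`models` must be a non-empty named list")
  for (nm in names(models)) {
    m <- models[[nm]]
    ok <- (is.character(m) && length(m) == 1) ||
      (is.list(m) && inherits(m$spec, "polymer_spec") && !is.null(m$n_frames))
    if (!ok) abort(sprintf("model '%s' must be a file path or list(spec =, n_frames =)", nm))
    if (is.character(m) && !file.exists(m))
      abort(sprintf("model '%s': input file not found: %s", nm, m))
  }
  structure(list(models = models, discard = as.integer(discard),
                 stride = as.integer(stride), exclude_adjacent = exclude_adjacent,
                 max_conformations = as.integer(max_conformations),
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 lr_start = lr_start, lr_end = lr_end,
                 n_replicates = as.integer(n_replicates), grid = grid,
                 min_count = as.integer(min_count), n_boot = as.integer(n_boot),
                 lcs_neighbors = as.integer(lcs_neighbors), lcs_radius = lcs_radius,
                 contact_cutoff = contact_cutoff, out_dir = out_dir,
                 write_figures = isTRUE(write_figures)),
            class = "landscape_config")
}

#' Run the full landscape-comparison pipeline
#'
#' Generate/load the labeled ensembles, subsample, pool, compute the pairwise
#' dissimilarity matrix, embed with the force scheme (with replicates), and
#' derive the grid statistics (relative fractions, overlap table with
#' bootstrap errors, entropy report), the radius-of-gyration track, and the
#' density-seeded local conformational signature. Every figure-backing table
#' is written as delimited text; a manifest records seeds and stage inputs.
#'
#' @param config a [landscape_config()].
#' @param quiet suppress stage log messages.
#' @return A `landscape_run` list: `pooled`, `delta`, `projection`,
#'   `replicates`, `occupancy`, `fractions`, `overlap`, `entropy`, `rg_track`,
#'   `lcs`, `config`, plus `files` when `out_dir` is set.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "landscape_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[idpscape] ", fmt), ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    say("%s done in %.1fs", name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  ensembles <- stage("load", {
    purrr::imap(config$models, function(m, nm) {
      ens <- if (is.character(m)) {
        load_calpha_trajectory(m, label = nm)
      } else {
        generate_polymer_ensemble(m$spec, m$n_frames, label = nm)
      }
      ens$label <- nm
      subsample_frames(ens, config$discard, config$stride)
    })
  })
  pooled <- stage("pool", pool_ensembles(unname(ensembles)))
  say("pooled %d conformations x %d residues", n_frames(pooled), n_residues(pooled))
  delta <- stage("dissimilarity", dissimilarity_matrix(
    pooled, exclude_adjacent = config$exclude_adjacent,
    max_conformations = config$max_conformations))
  replicates <- stage("projection", replicate_projections(
    delta, n_replicates = config$n_replicates, base_seed = config$seed,
    max_iter = config$max_iter, lr_start = config$lr_start, lr_end = config$lr_end))
  proj <- replicates[[1]]
  occ <- stage("grid", bin_projection(proj, config$grid, config$min_count))
  fractions <- purrr::map(setNames(occ$labels, occ$labels),
                          ~relative_fraction_map(occ, .x))
  overlap <- stage("overlap", overlap_uncertainty(
    proj, grid = config$grid, min_count = config$min_count,
    n_boot = config$n_boot, seed = config$seed))
  entropy <- stage("entropy", {
    if (length(replicates) >= 2) {
      entropy_across_replicates(replicates, config$grid, config$min_count)
    } else {
      projection_entropy(occ)
    }
  })
  rg_track <- observable_track(pooled, radius_of_gyration, "rg")
  lcs <- NULL
  if (!is.null(config$lcs_radius)) {
    lcs <- stage("lcs", {
      sel <- select_region(proj, radius = config$lcs_radius)
      extract_lcs(pooled, proj$index[sel], n_neighbors = min(config$lcs_neighbors,
                                                             length(sel) - 1L),
                  contact_cutoff = config$contact_cutoff,
                  exclude_adjacent = config$exclude_adjacent)
    })
  }

  run <- structure(list(pooled = pooled, delta = delta, projection = proj,
                        replicates = replicates, occupancy = occ,
                        fractions = fractions, overlap = overlap,
                        entropy = entropy, rg_track = rg_track, lcs = lcs,
                        config = config),
                   class = "landscape_run")
  if (!is.null(config$out_dir)) {
    run$files <- stage("write", write_run_artifacts(run, config))
  }
  run
}

write_run_artifacts <- function(run, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  readr::write_tsv(tidy(run$projection), path("projection.tsv")); add(path("projection.tsv"))
  utils::write.table(round(unclass(run$delta), 6), path("dissimilarity.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  add(path("dissimilarity.tsv"))
  readr::write_tsv(run$pooled$meta, path("pooled_manifest.tsv")); add(path("pooled_manifest.tsv"))
  for (w in names(run$fractions)) {
    f <- path(sprintf("fraction_%s.tsv", w))
    readr::write_tsv(run$fractions[[w]], f); add(f)
  }
  readr::write_tsv(tidy(run$overlap), path("overlap.tsv")); add(path("overlap.tsv"))
  readr::write_tsv(tibble::as_tibble(run$entropy), path("entropy.tsv")); add(path("entropy.tsv"))
  readr::write_tsv(run$rg_track, path("rg_track.tsv")); add(path("rg_track.tsv"))
  if (!is.null(run$lcs)) {
    readr::write_tsv(run$lcs$members, path("lcs_members.tsv")); add(path("lcs_members.tsv"))
    utils::write.table(round(run$lcs$contact_map, 4), path("lcs_contact_map.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    add(path("lcs_contact_map.tsv"))
  }
  if (config$write_figures) {
    figs <- list(
      projection = autoplot(run$projection, track = run$rg_track),
      overlap = autoplot(run$overlap),
      entropy = if (inherits(run$entropy, "entropy_report")) autoplot(run$entropy)
    )
    for (w in names(run$fractions)) figs[[paste0("fraction_", w)]] <-
        plot_fraction_map(run$occupancy, w)
    for (nm in names(figs)) {
      if (is.null(figs[[nm]])) next
      f <- path(paste0(nm, ".png"))
      ggplot2::ggsave(f, figs[[nm]], width = 6, height = 5, dpi = 120)
      add(f)
    }
  }
  manifest <- list(
    package = "idpscape",
    version = as.character(utils::packageVersion("idpscape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    n_conformations = n_frames(run$pooled),
    n_residues = n_residues(run$pooled),
    models = run$pooled$offsets$label,
    settings = config[c("discard", "stride", "exclude_adjacent", "max_iter",
                        "lr_start", "lr_end", "n_replicates", "grid",
                        "min_count", "n_boot")],
    files = basename(files)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  add(path("manifest.json"))
  files
}

#' @export
print.landscape_run <- function(x, ...) {
  cat(sprintf("<landscape_run> %d conformations, %d models, %d replicate projections\n",
              n_frames(x$pooled), nrow(x$pooled$offsets), length(x$replicates)))
  invisible(x)
}
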