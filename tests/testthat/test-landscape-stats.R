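cross_proj <- function(x, y, label) {
  structure(tibble::tibble(index = seq_along(x), label = label,
                           source_frame = seq_along(x), x = x, y = y),
            class = c("conf_projection", class(tibble::tibble())))
}

test_that("grid binning matches constructions and the per-point oracle", {
  # one point per bin center of a 27 x 27 grid, single model
  centers <- seq_len(27) - 0.5
  g <- expand.grid(x = centers, y = centers)
  proj <- cross_proj(g$x, g$y, "only")
  occ <- bin_projection(proj, grid = c(27, 27), min_count = 1)
  expect_true(all(occ$totals == 1))
  expect_true(all(occ$fraction[, , "only"] == 1))
  expect_true(all(occ$valid))

  # two models sharing one bin 3:1
  proj2 <- cross_proj(c(rep(0.2, 3), 0.21, 5), c(rep(0.3, 3), 0.31, 5),
                      c("A", "A", "A", "B", "B"))
  occ2 <- bin_projection(proj2, grid = c(4, 4), min_count = 1)
  b <- c(occ2$bin_x[1], occ2$bin_y[1])
  expect_equal(unname(occ2$fraction[b[1], b[2], "A"]), 0.75)
  expect_equal(unname(occ2$fraction[b[1], b[2], "B"]), 0.25)

  # random fixture vs naive loop oracle
  set.seed(14)
  projr <- cross_proj(runif(400), runif(400), sample(c("A", "B", "C"), 400, TRUE))
  occr <- bin_projection(projr, grid = c(9, 7), min_count = 2)
  oracle <- oracle_bin_counts(projr$x, projr$y, projr$label,
                              occr$breaks_x, occr$breaks_y)
  expect_identical(occr$counts, oracle)
  # per-bin fraction normalisation holds exactly on occupied bins
  fr_sum <- apply(occr$fraction, c(1, 2), sum)
  expect_true(all(abs(fr_sum[occr$totals > 0] - 1) < 1e-12))

  expect_error(bin_projection(cross_proj(rep(1, 5), rep(2, 5), "A")), "degenerate")
})

test_that("relative fraction maps flag exclusivity and validity", {
  fx <- basin_fixture()
  occ <- bin_projection(fx$proj)
  # sole-occupant model: F = 1 wherever the ensemble is alone and stats valid
  fm <- relative_fraction_map(occ, "b3")
  expect_true(all(fm$fraction[fm$valid & !is.na(fm$fraction) & fm$n == fm$total] == 1))
  expect_true(all(is.na(fm$fraction[!fm$valid])))
  expect_error(relative_fraction_map(occ, "nope"), "unknown model")

  # balanced mixture: duplicate one cloud under two labels -> F = 0.5 everywhere
  set.seed(3)
  x <- runif(200); y <- runif(200)
  bal <- cross_proj(c(x, x), c(y, y), rep(c("A", "B"), each = 200))
  occ_b <- bin_projection(bal, grid = c(5, 5), min_count = 1)
  fr <- occ_b$fraction[, , "A"]
  expect_true(all(abs(fr[occ_b$totals > 0] - 0.5) < 1e-12))
})

test_that("density overlap is a cosine similarity over valid bins", {
  fx <- basin_fixture()
  occ <- bin_projection(fx$proj)
  for (w in occ$labels) expect_equal(density_overlap(occ, w, w), 1, tolerance = 1e-12)
  O <- overlap_matrix(occ)
  expect_identical(unclass(O), t(unclass(O)))
  expect_true(all(O >= 0 & O <= 1 + 1e-12))
  # disjoint supports give exactly zero
  proj_d <- cross_proj(c(runif(50), runif(50) + 10), runif(100),
                       rep(c("L", "R"), each = 50))
  occ_d <- bin_projection(proj_d, grid = c(10, 3), min_count = 1)
  expect_equal(density_overlap(occ_d, "L", "R"), 0)
  # hand-coded oracle over bins
  hand <- function(occ, w, z) {
    fw <- occ$fraction[, , w]; fz <- occ$fraction[, , z]
    fw[!occ$valid | is.na(fw)] <- 0; fz[!occ$valid | is.na(fz)] <- 0
    sum((fw / sqrt(sum(fw^2))) * (fz / sqrt(sum(fz^2))))
  }
  for (pair in list(c("b1", "b2"), c("b1", "b3"), c("b2", "b3"))) {
    expect_equal(density_overlap(occ, pair[1], pair[2]),
                 hand(occ, pair[1], pair[2]), tolerance = 1e-12)
  }
  expect_error(density_overlap(occ, "b1", "zz"), "unknown")
})

test_that("bootstrap overlap uncertainty behaves on degenerate and real input", {
  # identical duplicated models on a single support bin: every resampled
  # overlap is exactly 1, sd 0 (resampling cannot change a one-bin density)
  proj <- cross_proj(c(rep(0.1, 50), rep(0.1, 50), 5, 5),
                     c(rep(0.1, 50), rep(0.1, 50), 5, 5),
                     c(rep("A", 50), rep("B", 50), "C", "C"))
  O <- overlap_uncertainty(proj, grid = c(4, 4), min_count = 1, n_boot = 10, seed = 4)
  expect_equal(unname(unclass(O)["A", "B"]), 1, tolerance = 1e-12)
  expect_equal(unname(attr(O, "se")["A", "B"]), 0)

  fx <- basin_fixture()
  Ofx <- overlap_uncertainty(fx$proj, n_boot = 20, seed = 8)
  se <- attr(Ofx, "se")
  expect_true(all(se >= 0))
  expect_error(overlap_uncertainty(fx$proj, n_boot = 1), "n_boot")
  # smoke: the minimal bootstrap size runs
  expect_s3_class(overlap_uncertainty(fx$proj, n_boot = 2, seed = 1), "overlap_table")
})

test_that("projection entropy hits its closed-form landmarks", {
  # uniform occupancy of all 729 bins
  centers <- seq_len(27) - 0.5
  g <- expand.grid(x = centers, y = centers)
  occ_u <- bin_projection(cross_proj(g$x, g$y, "u"), grid = c(27, 27), min_count = 1)
  ent_u <- projection_entropy(occ_u, "u")
  expect_equal(ent_u$entropy, log(729), tolerance = 1e-12)
  expect_equal(round(ent_u$entropy, 2), 6.59)
  expect_equal(ent_u$normalized, 1)

  # delta distribution: everything in one bin (needs a second model to span a box)
  proj_1 <- cross_proj(c(rep(0.1, 40), 3), c(rep(0.1, 40), 3),
                       c(rep("point", 40), "other"))
  occ_1 <- bin_projection(proj_1, grid = c(8, 8), min_count = 1)
  expect_equal(projection_entropy(occ_1, "point")$entropy, 0)

  # two equally occupied bins
  proj_2 <- cross_proj(c(rep(0.1, 20), rep(7.9, 20)),
                       seq(0.5, 0.52, length.out = 40), "two")
  occ_2 <- bin_projection(proj_2, grid = c(8, 1), min_count = 1)
  expect_equal(projection_entropy(occ_2, "two")$entropy, log(2), tolerance = 1e-12)

  expect_error(projection_entropy(occ_2, "none"), "unknown")
})

test_that("entropy respects bounds and never increases under bin merging", {
  fx <- basin_fixture()
  ent27 <- projection_entropy(bin_projection(fx$proj, grid = c(27, 27)))
  expect_true(all(ent27$entropy >= 0 & ent27$entropy <= log(729) + 1e-12))
  # a 9 x 9 grid over the same bounding box merges 3 x 3 blocks of bins
  ent9 <- projection_entropy(bin_projection(fx$proj, grid = c(9, 9)))
  merged <- dplyr::left_join(ent9, ent27, by = "label", suffix = c("_9", "_27"))
  expect_true(all(merged$entropy_9 <= merged$entropy_27 + 1e-12))
})

test_that("entropy across replicates quantifies projection noise", {
  fx <- basin_fixture()
  same <- list(fx$proj, fx$proj, fx$proj)
  rep_same <- entropy_across_replicates(same)
  expect_true(all(rep_same$sd_normalized == 0))

  reps <- replicate_projections(fx$delta, 3, base_seed = 21)
  report <- entropy_across_replicates(reps)
  expect_s3_class(report, "entropy_report")
  expect_true(all(report$sd_normalized < 0.1))
  per <- tidy(report)
  expect_equal(nrow(per), 3 * 3)

  relabeled <- reps
  relabeled[[2]]$label <- sub("b1", "zz", relabeled[[2]]$label)
  expect_error(entropy_across_replicates(relabeled), "inconsistent")
  expect_error(entropy_across_replicates(reps[1]), "at least 2")
})

test_that("broader ensembles carry higher projection entropy in every replicate", {
  fx <- mixed_fixture()
  reps <- replicate_projections(fx$delta, 4, base_seed = 31)
  for (p in reps) {
    ent <- projection_entropy(bin_projection(p))
    expect_gt(ent$entropy[ent$label == "broad"], ent$entropy[ent$label == "narrow"])
  }
})

test_that("the Gaussian KDE finds modes and integrates to one", {
  set.seed(9)
  cl1 <- cbind(rnorm(100, 0, 0.2), rnorm(100, 0, 0.2))
  cl2 <- cbind(rnorm(100, 6, 0.2), rnorm(100, 6, 0.2))
  proj <- cross_proj(c(cl1[, 1], cl2[, 1]), c(cl1[, 2], cl2[, 2]), "m")
  dens <- kde_density(proj)
  top <- dens[order(-dens$density)[1:20], ]
  expect_true(any(top$x < 3) && any(top$x > 3))  # maxima at both clusters

  # single Gaussian cloud: densest point close to the centroid
  set.seed(10)
  g <- cbind(rnorm(400), rnorm(400))
  pg <- cross_proj(g[, 1], g[, 2], "g")
  dg <- kde_density(pg)
  bw <- c(sd(pg$x), sd(pg$y)) * 400^(-1 / 6)
  peak <- dg[which.max(dg$density), ]
  expect_lt(sqrt((peak$x - mean(pg$x))^2 + (peak$y - mean(pg$y))^2), max(bw) * 2)

  # density integrates to ~1 over a fine grid
  xs <- seq(min(pg$x) - 4, max(pg$x) + 4, length.out = 150)
  ys <- seq(min(pg$y) - 4, max(pg$y) + 4, length.out = 150)
  grid <- expand.grid(x = xs, y = ys)
  dv <- idpscape:::kde_eval(grid$x, grid$y, pg$x, pg$y, bw)
  integral <- sum(dv) * diff(xs[1:2]) * diff(ys[1:2])
  expect_equal(integral, 1, tolerance = 0.02)

  expect_error(kde_density(cross_proj(rep(1, 10), rep(1, 10), "z")), "zero-variance")
  expect_error(kde_density(proj[1, ]), "at least 2")
})
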