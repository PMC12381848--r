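test_that("distance-RMSD matches hand arithmetic and rigid-motion invariance", {
  a <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  b <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0))
  expect_identical(distance_rmsd(a, a), 0)
  r13_b <- sqrt(2) * 3.8
  by_hand <- sqrt(((7.6 - r13_b)^2 + 0 + 0) / 3)
  expect_equal(distance_rmsd(a, b), by_hand, tolerance = 1e-12)
  expect_equal(distance_rmsd(a, b), oracle_drmsd(a, b), tolerance = 1e-14)
  expect_equal(distance_rmsd(a, b), distance_rmsd(b, a))

  rot <- rotation_matrix(c(0, 1, 1), 0.7)
  moved <- a %*% t(rot) + matrix(c(4, 4, 4), 3, 3, byrow = TRUE)
  expect_lt(distance_rmsd(a, moved), 1e-10)
  expect_error(distance_rmsd(a, rbind(a, c(1, 1, 1))), "mismatch")
})

test_that("the LCS medoid equals the exhaustive oracle", {
  fx <- basin_fixture()
  selection <- 1:50
  lcs <- extract_lcs(fx$pooled, selection, n_neighbors = 10)
  # O(m^2) brute force over the selection
  m <- length(selection)
  dr <- matrix(0, m, m)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      dr[i, j] <- dr[j, i] <- oracle_drmsd(frame_coords(fx$pooled, selection[i]),
                                           frame_coords(fx$pooled, selection[j]))
    }
  }
  means <- rowSums(dr) / (m - 1)
  expect_equal(lcs$medoid, selection[which.min(means)])
  expect_equal(lcs$mean_drmsd, min(means), tolerance = 1e-10)
  # neighbors are the n smallest dRMSD to the medoid
  to_med <- dr[which.min(means), ]
  expect_setequal(lcs$neighbors,
                  selection[setdiff(order(to_med), which.min(means))[1:10]])
})

test_that("LCS handles duplicates, clusters around a template, and bad input", {
  one <- random_conformation(10, 44)
  dup <- conf_ensemble(array(rep(one, each = 6), c(6, 10, 3)), "dup")
  pooled <- pool_ensembles(list(dup))
  lcs <- extract_lcs(pooled, 1:6, n_neighbors = 3)
  expect_equal(lcs$medoid, 1L)  # tie broken by lowest index
  expect_true(all(lcs$members$drmsd_to_medoid == 0))

  # cluster generated around a known template: medoid is near the template
  spec <- polymer_spec(20, compactness = 0.4, seed = 77)
  basin <- generate_basin_ensemble(spec, 20, pivot_sd = 0.05)
  template <- frame_coords(generate_polymer_ensemble(spec, 1), 1)
  pooled_b <- pool_ensembles(list(basin))
  lcs_b <- extract_lcs(pooled_b, 1:20, n_neighbors = 5)
  to_template <- vapply(1:20, function(i) {
    distance_rmsd(frame_coords(pooled_b, i), template)
  }, numeric(1))
  expect_lte(rank(to_template)[lcs_b$medoid], 3)

  expect_error(extract_lcs(pooled, 3, n_neighbors = 1), "at least 2")
  expect_error(extract_lcs(pooled, 1:6, n_neighbors = 6), "smaller than the selection")
  expect_error(extract_lcs(pooled, c(1, 99), n_neighbors = 1), "out of range")
})

test_that("contact maps reflect chain geometry and enforced motifs", {
  ext <- conf_ensemble(array(straight_chain(15), c(1, 15, 3)), "ext")
  cm <- contact_map(ext, cutoff = 8)
  expect_identical(dim(cm), c(15L, 15L))
  expect_identical(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  sep <- abs(row(cm) - col(cm))
  expect_true(all(cm[sep > 2] == 0))   # 3 * 3.8 = 11.4 > 8
  expect_true(all(cm[sep == 1] == 1))  # bonded at 3.8 < 8

  hairpin <- generate_polymer_ensemble(
    polymer_spec(20, compactness = 0.3, seed = 13, exclusive_motif = list(c(2, 18, 8))), 40)
  cmh <- contact_map(hairpin, cutoff = 8)
  expect_equal(cmh[2, 18], 1)
})

test_that("region selection supports polygons, radius seeding, and purity", {
  fx <- basin_fixture()
  # polygon around the b3 basin only
  b3 <- fx$proj[fx$proj$label == "b3", ]
  pad <- 0.02
  poly <- cbind(c(min(b3$x) - pad, max(b3$x) + pad, max(b3$x) + pad, min(b3$x) - pad),
                c(min(b3$y) - pad, min(b3$y) - pad, max(b3$y) + pad, max(b3$y) + pad))
  sel <- select_region(fx$proj, polygon = poly)
  expect_true(all(fx$proj$label[sel] == "b3"))
  expect_gte(length(sel), nrow(b3))

  lcs <- extract_lcs(fx$pooled, fx$proj$index[sel], n_neighbors = 20)
  expect_true(all(lcs$members$label == "b3"))

  sel_r <- select_region(fx$proj, radius = 0.05)
  expect_gte(length(sel_r), 2)
  expect_error(select_region(fx$proj), "supply one")
  expect_error(select_region(fx$proj, indices = c(1, 999999)), "absent")
})

test_that("superposition is rigid and leaves internal distances untouched", {
  basin <- generate_basin_ensemble(polymer_spec(12, compactness = 0.4, seed = 3), 5)
  aligned <- superpose_frames(basin$coords)
  for (f in 1:5) {
    before <- frame_coords(basin, f)
    after <- aligned[f, , ]
    expect_equal(as.numeric(dist(before)), as.numeric(dist(after)), tolerance = 1e-9)
  }
})
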