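test_that("polymer generator produces exact chain geometry, reproducibly", {
  spec <- polymer_spec(26, compactness = 0, seed = 1)
  ens <- generate_polymer_ensemble(spec, 10)
  expect_equal(n_frames(ens), 10L)
  expect_equal(n_residues(ens), 26L)
  for (f in seq_len(10)) {
    m <- frame_coords(ens, f)
    bonds <- sqrt(rowSums(diff(m)^2))
    expect_true(all(abs(bonds - 3.8) < 1e-6))
  }
  # non-bonded excluded volume
  d1 <- internal_distances(frame_coords(ens, 1))
  sep <- attr(d1, "separations")
  expect_true(all(d1[1, sep > 1] >= 2.0))
  # seed determinism, bitwise
  again <- generate_polymer_ensemble(polymer_spec(26, compactness = 0, seed = 1), 10)
  expect_identical(ens$coords, again$coords)
  # custom bond length honoured
  short <- generate_polymer_ensemble(polymer_spec(8, bond_length = 1.5, seed = 3), 2)
  m <- frame_coords(short, 1)
  expect_true(all(abs(sqrt(rowSums(diff(m)^2)) - 1.5) < 1e-6))
})

test_that("compactness controls the radius-of-gyration distribution", {
  loose <- generate_polymer_ensemble(polymer_spec(26, compactness = 0.2, seed = 21), 2000)
  tight <- generate_polymer_ensemble(polymer_spec(26, compactness = 0.8, seed = 22), 2000)
  rg_l <- radius_of_gyration(loose)
  rg_t <- radius_of_gyration(tight)
  expect_gt(mean(rg_l), mean(rg_t))
  wt <- t.test(rg_l, rg_t, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("exclusive motifs are enforced in every frame and validated upfront", {
  spec <- polymer_spec(26, compactness = 0.3, seed = 5,
                       exclusive_motif = list(c(2, 20, 8)))
  ens <- generate_polymer_ensemble(spec, 50)
  d <- apply(ens$coords, 1, function(m) sqrt(sum((m[2, ] - m[20, ])^2)))
  expect_true(all(d <= 8))
  # unsatisfiable constraints fail with the offending pair named
  expect_error(polymer_spec(26, exclusive_motif = list(c(2, 20, 1.5))),
               "\\(2, 20\\)")
  expect_error(polymer_spec(26, exclusive_motif = list(c(3, 4, 2.5))),
               "\\(3, 4\\)")
  expect_error(polymer_spec(26, exclusive_motif = list(c(0, 5, 8))), "valid residue")
  expect_error(generate_polymer_ensemble(
    polymer_spec(26, compactness = 0, seed = 1, exclusive_motif = list(c(1, 26, 2.05))),
    5, max_frame_retries = 50L), "\\(1, 26\\)")
})

test_that("spec validation rejects degenerate chains", {
  expect_error(polymer_spec(3), "n_residues")
  expect_error(polymer_spec(10, bond_length = 0), "bond_length")
  expect_error(polymer_spec(10, compactness = 1.2), "compactness")
  expect_error(generate_polymer_ensemble(polymer_spec(10), 0), "n_frames")
})

test_that("basin ensembles are tight around their template and keep constraints", {
  spec <- polymer_spec(26, compactness = 0.4, seed = 9,
                       exclusive_motif = list(c(3, 22, 8)))
  ens <- generate_basin_ensemble(spec, 30)
  expect_equal(n_frames(ens), 30L)
  for (f in c(1, 15, 30)) {
    m <- frame_coords(ens, f)
    expect_true(all(abs(sqrt(rowSums(diff(m)^2)) - 3.8) < 1e-6))
    expect_lte(sqrt(sum((m[3, ] - m[22, ])^2)), 8)
  }
  # within-basin dissimilarity is far below between-basin dissimilarity
  other <- generate_basin_ensemble(polymer_spec(26, compactness = 0.4, seed = 10), 30,
                                   label = "other")
  delta <- unclass(dissimilarity_matrix(pool_ensembles(list(ens, other))))
  within <- delta[1:30, 1:30][upper.tri(diag(30))]
  between <- delta[1:30, 31:60]
  expect_lt(mean(within), mean(between) / 3)
  expect_identical(generate_basin_ensemble(spec, 5)$coords,
                   generate_basin_ensemble(spec, 5)$coords)
})

test_that("ensembles with disjoint engineered motifs separate in the projection", {
  fx <- basin_fixture()
  sil <- silhouette_score(cbind(fx$proj$x, fx$proj$y), fx$proj$label)
  expect_gt(sil, 0)
})

test_that("sector-system generator places the scheduled sectors and validates input", {
  expect_error(sector_system_spec(5, 10, 0), "at least 1 residue")
  expect_error(sector_system_spec(5, 2, 5), "n_glob")
  expect_error(sector_system_spec(5, 10, 5, sector_schedule = list()), "non-empty")
  expect_error(sector_system_spec(5, 10, 5, sector_schedule = list(c(8, 10))), "0..7")

  spec <- sector_system_spec(5, 12, 8, sector_schedule = list(c(1, 50)), seed = 2)
  sys <- generate_sector_system(spec)
  expect_equal(n_frames(sys$ensemble), 50L)
  expect_equal(n_residues(sys$ensemble), 25L)
  expect_true(all(sys$truth$sector == 1))
  com <- domain_com(sys$ensemble, sys$globular_range)
  trace <- assign_sectors(com, sys$particle, sys$geometry)
  expect_true(all(trace$sector == 1))

  # 50/50 two-sector schedule recovered exactly
  sys2 <- generate_sector_system(
    sector_system_spec(5, 12, 8, sector_schedule = list(c(0, 10), c(2, 10)), seed = 3))
  tr2 <- assign_sectors(domain_com(sys2$ensemble, sys2$globular_range),
                        sys2$particle, sys2$geometry)
  occ <- sector_occupancy(tr2)
  expect_equal(occ$percent[occ$sector == 0], 50)
  expect_equal(occ$percent[occ$sector == 2], 50)
})
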