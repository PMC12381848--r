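test_that("multi-model PDB round-trips C-alpha coordinates", {
  ens <- generate_polymer_ensemble(polymer_spec(12, compactness = 0.3, seed = 4), 3,
                                   label = "toy")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_calpha_pdb(path)
  expect_equal(n_frames(back), 3L)
  expect_equal(n_residues(back), 12L)
  expect_equal(back$coords, ens$coords, tolerance = 1e-3)  # PDB has 3 decimals
  # generic loader dispatches on extension
  again <- load_calpha_trajectory(path)
  expect_equal(again$coords, back$coords)
})

test_that("PDB reader validates frame consistency and atom content", {
  ens <- generate_polymer_ensemble(polymer_spec(6, seed = 1), 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  lines <- readLines(path)
  # drop one CA from the second MODEL block
  atom_idx <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atom_idx[8]], path)
  expect_error(read_calpha_pdb(path), "frame 2")

  # a PDB with atoms but no C-alphas
  writeLines(c("MODEL     1",
               "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
               "ENDMDL"), path)
  expect_error(read_calpha_pdb(path), "no C-alpha")
  expect_error(read_calpha_pdb(withr::local_tempfile(fileext = ".pdb")), "not found")
})

test_that("DCD route matches the PDB route on the same system", {
  ens <- generate_polymer_ensemble(polymer_spec(10, compactness = 0.4, seed = 8), 5,
                                   label = "sys")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_ensemble_pdb(ens, pdb)
  write_dcd(ens, dcd)
  via_pdb <- load_calpha_trajectory(pdb)
  via_dcd <- load_calpha_trajectory(dcd, topology = pdb)
  expect_equal(n_frames(via_dcd), 5L)
  expect_lt(max(abs(via_dcd$coords - via_pdb$coords)), 1e-3)
  # topology mismatch is caught
  small <- generate_polymer_ensemble(polymer_spec(6, seed = 2), 1)
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(small, pdb2)
  expect_error(read_dcd(dcd, topology = pdb2), "topology")
  expect_error(read_dcd(pdb), "DCD")
})

test_that("XTC and unknown formats produce explicit errors", {
  expect_error(load_calpha_trajectory("traj.xtc"), "XTC")
  expect_error(load_calpha_trajectory("traj.foo"), "unrecognised")
})

test_that("coordinate tables round-trip", {
  ens <- generate_polymer_ensemble(polymer_spec(7, compactness = 0.2, seed = 5), 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coord_table(ens, path)
  back <- load_calpha_trajectory(path)
  expect_equal(back$coords, ens$coords, tolerance = 1e-9)
  expect_equal(back$source_indices, ens$source_indices)
})

test_that("subsampling follows the burn-in/stride rule", {
  ens <- conf_ensemble(array(seq_len(88000 * 4 * 3), c(88000, 4, 3)), "long")
  sub <- subsample_frames(ens, discard = 4000, stride = 14)
  # arithmetic oracle: frames 4001, 4015, ... <= 88000
  expect_equal(n_frames(sub), length(seq(4001, 88000, by = 14)))
  expect_equal(n_frames(sub), 6000L)
  expect_equal(sub$source_indices[1:3], c(4001L, 4015L, 4029L))
  expect_identical(sub$coords[1, , ], ens$coords[4001, , ])

  ten <- conf_ensemble(array(rnorm(10 * 4 * 3), c(10, 4, 3)), "ten")
  expect_identical(subsample_frames(ten, 0, 1)$coords, ten$coords)
  expect_error(subsample_frames(ten, 10, 1), "empties")
})

test_that("pooling preserves order, counts and labels", {
  mk <- function(n, lab, nres = 5) {
    conf_ensemble(array(rnorm(n * nres * 3), c(n, nres, 3)), lab)
  }
  e1 <- mk(30, "A"); e2 <- mk(20, "B"); e3 <- mk(10, "C")
  pooled <- pool_ensembles(list(e1, e2, e3))
  expect_equal(n_frames(pooled), 60L)
  expect_equal(pooled$offsets$start, c(1L, 31L, 51L))
  expect_equal(pooled$meta$label, rep(c("A", "B", "C"), c(30, 20, 10)))
  expect_identical(pooled$coords[31, , ], e2$coords[1, , ])
  # single-ensemble pooling is the identity on coordinates
  solo <- pool_ensembles(list(e1))
  expect_identical(solo$coords[seq_len(30), , ], e1$coords)
  # mismatched residue counts name both labels
  expect_error(pool_ensembles(list(e1, mk(5, "D", nres = 4))), "'A'.*'D'|'D'.*'A'")
  expect_error(pool_ensembles(list(e1, mk(5, "A"))), "distinct")
})

test_that("subsample-then-pool commutes with pool-then-blockwise-subsample", {
  mk <- function(n, lab, seed) {
    generate_polymer_ensemble(polymer_spec(6, compactness = 0.2, seed = seed), n, label = lab)
  }
  e1 <- mk(40, "A", 1); e2 <- mk(25, "B", 2)
  route1 <- pool_ensembles(list(subsample_frames(e1, 5, 3), subsample_frames(e2, 5, 3)))
  pooled <- pool_ensembles(list(e1, e2))
  blocks <- lapply(seq_len(nrow(pooled$offsets)), function(i) {
    idx <- pooled$offsets$start[i]:pooled$offsets$end[i]
    sub <- conf_ensemble(pooled$coords[idx, , , drop = FALSE], pooled$offsets$label[i],
                         pooled$meta$source_frame[idx])
    subsample_frames(sub, 5, 3)
  })
  route2 <- pool_ensembles(blocks)
  expect_equal(route1$coords, route2$coords)
  expect_equal(route1$meta, route2$meta)
})
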