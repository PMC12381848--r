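# idpscape

Differential conformational-landscape analysis for intrinsically disordered
protein (IDP) ensembles.

IDPs — histone tails are the textbook case — function as heterogeneous
conformational ensembles, and the biologically interesting questions are
comparative: how does acetylation, a mutation, or binding to a partner reshape
the set of conformations a chain visits? `idpscape` compares labeled
ensembles of Cα (or single-bead) conformations inside **one shared 2-D
"effective conformational space"**, so statements like "this model occupies a
region no other model visits" are geometrically meaningful.

## The method

1. **Dissimilarity.** Conformations are compared through internal Cα–Cα
   distances only (rigid-motion invariant, no superposition):

   Q_w(k,l) = (1/N_p) Σ_{i<j} exp[ −(r_ij^k − r_ij^l)² / (2 σ_ij²) ],
   with σ_ij = |i−j|^0.15 Å, and pairwise dissimilarity δ = 1 − Q_w ∈ [0, 1).

2. **Projection.** The δ matrix is embedded in the plane by an iterative
   force-scheme layout (seeded, hence reproducible; replicate projections
   quantify layout noise).

3. **Grid statistics** on a 27 × 27 grid over the shared projection:
   - *relative fraction* F_ij^w = n_ij^w / N_ij (F = 1 ⇒ exclusively
     populated bins),
   - *density overlap* O^{w,z} = Σ f^w f^z with f = F/√ΣF² (1 identical,
     0 disjoint),
   - *projection entropy* H^w = −Σ p ln p, normalized by
     H_max = ln 729 ≈ 6.59 (a heterogeneity proxy).

4. **Local conformational signatures**: the distance-RMSD medoid of a selected
   region plus its n nearest members and their contact map.

5. **Binding sectors**: frames of a protein–particle trajectory assigned to
   eight cylindrical sectors around the partner (sector 0 = unbound, sector 1
   on the dyad), with occupancy frequencies and sector-stratified projections.

A synthetic-data module generates coarse-grained polymer ensembles (tunable
compactness, enforced contact motifs, tight "basin" ensembles, scheduled
binding-sector systems) so the whole analysis is testable end to end without
MD trajectories.

## Worked example

Three synthetic 26-residue models: a broad disordered ensemble, a compact one,
and one confined to an exclusive basin carrying an enforced 3–22 contact.

```r
library(idpscape)

wide  <- generate_polymer_ensemble(polymer_spec(26, compactness = 0,   seed = 2), 200, label = "wide")
mid   <- generate_polymer_ensemble(polymer_spec(26, compactness = 0.5, seed = 3), 200, label = "mid")
motif <- generate_basin_ensemble(polymer_spec(26, compactness = 0.5, seed = 4,
                                              exclusive_motif = list(c(3, 22, 8))), 200, label = "motif")

pooled <- pool_ensembles(list(wide, mid, motif))
delta  <- dissimilarity_matrix(pooled)
proj   <- force_scheme(delta, seed = 1)

occ <- bin_projection(proj)                  # 27 x 27 grid, min_count 3
round(unclass(overlap_matrix(occ)), 3)
#>         mid motif  wide
#> mid   1.000     0 0.038
#> motif 0.000     1 0.000
#> wide  0.038     0 1.000

projection_entropy(occ)
#>   label     n entropy h_max normalized
#> 1 mid     200   4.70   6.59      0.712
#> 2 motif   200   0.701  6.59      0.106
#> 3 wide    200   5.05   6.59      0.766
```

Read: the basin model overlaps nobody (O = 0 against both others) and is by
far the least heterogeneous (normalized entropy 0.11 vs 0.71–0.77); the broad
model spreads the most. A density-seeded local conformational signature of the
densest region lands entirely inside the exclusive model:

```r
sel <- select_region(proj, radius = 0.05)    # KDE mode + radius
lcs <- extract_lcs(pooled, proj$index[sel], n_neighbors = 30)
lcs
#> <lcs_result> medoid 569 + 30 neighbors (of 200 selected), mean dRMSD 0.25 A
table(lcs$members$label)
#> motif
#>   200
```

`autoplot(proj, track = radius_of_gyration(pooled))` draws the landscape
colored by compactness; `plot_fraction_map(occ, "motif")` shows the exclusive
(F = 1) region. `run_pipeline(landscape_config(...))` chains every stage and
writes all tables, figures and a manifest to disk.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch against the
installed package: it generates the six-model synthetic fixture (compactness
ladder plus one exclusive-motif basin model), runs subsampling, the Q_w
dissimilarity matrix, ten replicate force-scheme projections, the grid
statistics (fractions, overlaps with bootstrap errors, entropies), a
density-seeded LCS, and the cylindrical-sector analysis on a scheduled
binding trajectory, then writes the JSON report to `--out`. All randomness
derives from `--seed`.
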