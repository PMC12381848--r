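---
title: "Comparing disordered-protein ensembles in one effective conformational space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing disordered-protein ensembles in one effective conformational space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpscape)
```

## The problem

Intrinsically disordered proteins (IDPs) function as heterogeneous
conformational ensembles rather than single folds, so the interesting
questions are differential: how does a post-translational modification, a
mutation, or binding to a partner reshape the *set* of conformations a chain
visits? Histone tails are the canonical case — lysine acetylation of the H4
tail and nucleosome binding of linker histone H1 both remodel disordered
ensembles without creating a unique structure.

`idpscape` answers such questions by placing all compared ensembles into one
shared two-dimensional "effective conformational space" and computing
per-ensemble statistics on that common map. Because every ensemble is embedded
jointly, geometric statements ("model A occupies a region no other model
visits") are directly meaningful.

## The model

**Dissimilarity.** Conformations are compared through their internal C-alpha
distances only — no superposition is needed and rigid motions cancel exactly.
For conformations $k, l$ the structural similarity is

$$Q_w^{k,l} = \frac{1}{N_p} \sum_{i<j} \exp\!\left[-\frac{(r_{ij}^k - r_{ij}^l)^2}{2\,\sigma_{ij}^2}\right],
\qquad \sigma_{ij} = |i-j|^{0.15}\ \text{Å},$$

where $r_{ij}$ is the distance between C-alphas $i$ and $j$ and $N_p$ the
number of pairs. The sequence-separation weight gives long-range distances
more slack than stiff short-range ones. The pairwise dissimilarity is
$\delta_{k,l} = 1 - Q_w^{k,l} \in [0, 1)$: zero for identical internal
geometry, approaching one for very different structures. All $i<j$ pairs are
used by default, including bonded neighbours; `exclude_adjacent = TRUE`
drops $|i-j| = 1$ pairs as a sensitivity check (for fixed-bond chains those
pairs contribute a constant).

**Projection.** The dissimilarity matrix is embedded in the plane by a
force-scheme layout: points are initialised uniformly in the unit square from
a seed, and each sweep moves every point along the mean of its directional
residuals $(d^{2D}_{kl} - \delta_{kl})/d^{2D}_{kl} \,(x_l - x_k)$, with a
learning rate decaying linearly from 1 to 0.05 over 100 sweeps. This damped
per-point mean step behaves like a SMACOF iteration: stress (the residual sum
of squares) is monotone at 10-sweep checkpoints in our property tests, unlike
the textbook per-pair immediate update, which we found to oscillate without
converging to comparable stress. All three constants are exposed
(`max_iter`, `lr_start`, `lr_end`). Layouts depend on the seed; rather than
pretending otherwise, `replicate_projections()` runs many seeds and downstream
statistics are reported as mean ± sd across replicates.

**Grid statistics.** A $27 \times 27$ grid over the tight bounding box of the
projection (half-open bins, final edge inclusive — every point lands in
exactly one bin) supports three statistics:

* *Relative fraction* $F_{ij}^w = n_{ij}^w / N_{ij}$ — the occupancy
  proportion of model $w$ in bin $(i,j)$; $F = 1$ marks exclusively populated
  regions.
* *Density overlap* $O^{w,z} = \sum_{ij} f_{ij}^w f_{ij}^z$ with
  $f^w = F^w / \sqrt{\sum (F^w)^2}$ — a cosine similarity of occupancy
  surfaces, 1 for identical distributions and 0 for disjoint supports. The L2
  normalisation is the unique reading of the defining formula consistent with
  $O^{w,w} = 1$; note this is stated prominently because the alternative
  (L1) normalisation does not have that property.
* *Projection entropy* $H^w = -\sum_{ij} p_{ij}^w \ln p_{ij}^w$ with
  $p^w = n^w / N^w$, normalised by $H_\max = \ln 729 \approx 6.59$ — a
  heterogeneity proxy: 0 when a model sits in one bin, 1 when it spreads
  uniformly.

Bins with fewer than `min_count` total points (default 3; the threshold for
"poor statistics" is not canonical, so it is config-exposed) are masked out of
the fraction and overlap statistics to avoid border artifacts. Overlap
uncertainties are bootstrap standard deviations over within-model resampling
of conformations on the fixed grid — a defensible stand-in, clearly labelled,
for an unspecified published procedure; replicate projections probe layout
noise separately.

**Local conformational signatures (LCS).** A selected region (explicit
indices, a polygon, or the KDE density mode plus a radius) is summarised by
its distance-RMSD medoid — the member minimising the mean
$\mathrm{dRMSD} = \sqrt{\tfrac{1}{N_p}\sum_{i<j}(r_{ij}^k - r_{ij}^l)^2}$
over the selection, found exhaustively, ties broken by lowest index — plus its
$n$ closest members (default 30, the usual choice for short tails; 20 suits
larger systems) and their contact map (default 8 Å C-alpha cutoff,
config-exposed since no single value is canonical).

**Binding sectors.** For a chain bound to a disc-shaped partner, each frame's
tracked center of mass is expressed in the partner's cylindrical frame
(principal axes; the axial direction is the smallest-extent axis, the
azimuth zero points at the dyad). Frames beyond an unbound radial threshold
(default: particle radius + 20 Å) or outside the axial slab are sector 0;
bound frames fall in seven equal azimuthal wedges, sector 1 centred on the
dyad. Published analyses of this kind do not print their boundary geometry,
so the whole construction is config-driven (`sector_geometry()`) and the
defaults reproduce the qualitative scheme. Occupancy percentages always sum
to 100, and unvisited sectors are reported as zero.

## The synthetic world

No public trajectories accompany the analyses this package mirrors, so the
`synthetic_data` functions generate coarse-grained stand-ins with the
statistical structure the method assumes. Design choices, made once:

* **Walk ensembles** (`generate_polymer_ensemble()`): self-avoiding random
  walks with fixed 3.8 Å bonds (the trans C-alpha spacing), a hard 2 Å
  excluded-volume core, and a centroid-attraction bias whose strength scales
  with `compactness` and with the bead's distance from the centroid (a radial
  confinement; a constant pull would wedge high-compactness walks into
  excluded-volume dead ends). Compactness 0 → mean Rg ≈ 8.8 Å for 26 beads;
  compactness 1 → ≈ 4.0 Å, monotone in between with shrinking spread.
* **Exclusive motifs**: residue-pair contacts enforced in every frame by
  rejection sampling (cap 10,000 tries/frame) over a walk that is *guided*
  toward satisfying the motif (beads en route to a motif partner are pulled
  back when the partner would leave the remaining reach); the final check is
  exact, so guidance only improves acceptance.
* **Basin ensembles** (`generate_basin_ensemble()`): a template conformation
  locally sampled by small pivot moves (default 10 pivots of sd 0.08 rad per
  frame). Measured on 26-bead chains, free walks have within-model
  $\bar\delta \approx 0.6$ — as large as between-model values — so walks alone
  can never produce "clear multi-basin structure". Basin ensembles have
  within-model $\bar\delta \approx 0.04$ against between-basin $\approx 0.6$,
  which is what makes exclusive regions, low overlaps, and high projection
  quality (Spearman > 0.9 between $\delta$ and planar distance) testable.
* **Sector systems** (`generate_sector_system()`): a three-domain chain whose
  globular-domain center of mass is placed inside scheduled sectors (middle
  60 % of each wedge, binding shell 1.05–1.25 × particle radius), around a
  deterministic three-ring disc particle. Ground-truth labels are returned
  for round-trip tests.

What a green test does **not** establish: the generator mimics landscape
*structure* only — there is no force field, no acetylation chemistry, no
thermodynamic weighting, and walk ensembles are far more heterogeneous than
REMD ensembles of real peptides. Published headline numbers (specific overlap
tables, entropy values, sector percentages) derive from unavailable MD data
and are mirrored only qualitatively here.

## Numerical choices and degenerate inputs

* Dissimilarities accumulate in double precision; the matrix is dense with a
  configurable memory guard (default cap 12,000 conformations ≈ 1.2 GB).
* The force scheme guards $d^{2D} \approx 0$ with an $\epsilon = 10^{-9}$
  denominator floor; duplicate conformations collapse onto one point.
* Degenerate projections (all points identical along an axis) are refused by
  the binning stage rather than silently producing one occupied bin.
* Medoid ties are broken by lowest pooled index, making LCS extraction
  deterministic.
* All RNG flows through `set.seed()`; generators restore the caller's RNG
  state, and every pipeline artifact is a pure function of (config, seeds,
  inputs).

## Known limitations

* XTC trajectories are not readable (no codec available in this stack);
  multi-model PDB, DCD and delimited coordinate tables are supported.
* Observables beyond C-alpha geometry (solvent accessibility, helicity)
  are out of scope; `observable_track()` is the extension point for values
  computed elsewhere.
* The dense dissimilarity matrix limits pooled sets to ~10⁴ conformations on
  desktop memory; subsample first (the standard practice this package's
  `subsample_frames()` implements).
* Entropy comparisons across models assume comparable per-model counts;
  the statistic is not bias-corrected for small samples.
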