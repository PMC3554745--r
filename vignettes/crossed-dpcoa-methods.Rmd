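---
title: "Crossed-DPCoA: model, numerical choices and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossed-DPCoA: model, numerical choices and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdpcoa)
```

## The data and the assumptions

The method takes three ingredients:

1. a species × community table of nonnegative importance values (densities,
   abundances, biomass, percentage cover, or presence/absence), which is
   normalised column-wise to proportions `p_ij`;
2. a complete balanced crossing of two factors: exactly one community per
   combination of a level of factor A (`r` levels) and a level of factor B
   (`m` levels);
3. a species dissimilarity matrix `Δ` that is *Euclidean-embeddable*: `S`
   points must exist in some Euclidean space with pairwise distances
   `δ_kl`.

Proportions are the modelling choice with the largest influence on results:
species with large, uneven proportions dominate the analysis.
`presence_absence()` replaces each community with the uniform profile
`1/S_ij` over its observed species, and `transform_values()` offers `sqrt`
and `log1p` damping before normalisation, for data where a few species
would otherwise swamp everything.

`Δ` may come from a phylogeny (`dist_sqrt_branch()`, the square root of the
patristic path length, always embeddable; or `dist_nodal()`, the raw edge
count, *not* guaranteed embeddable), from a taxonomy (`dist_taxonomic()`,
the index of the finest shared rank, an ultrametric), from the equidistant
constructor (`dist_equidistant()`), or from the user.  Embeddability is
verified (`is_euclidean()`, and again inside the fit in the weighted
metric); a failure is a hard error.  We deliberately do **not** apply a
Lingoes or Cailliez correction automatically: the correction changes the
diversity being analysed, and that choice should be the user's.

## The space and the partition

With species weights `w = p_global` (the weighted mean profile over all
communities), the Gower-centred matrix of `−δ²/2` under the weighted
centering operator is eigen-decomposed in the `diag(w)` metric.  The
resulting species coordinates `X` satisfy, and the test suite asserts:

* `‖M_k − M_l‖ = δ_kl` for all species pairs (distance reproduction),
* `wᵗX = 0` (the species cloud is centred),
* `Xᵗ diag(w) X = diag(λ)` (axes are `w`-orthogonal),
* `Σλ = QE(p_global, Δ²/2)` (total inertia is Rao diversity).

Profiles place points at weighted centroids (`place_points()`), giving the
community, level and doubly-recentred interaction clouds; their inertias
are the ANOQE components, which `anoqe()` computes independently from the
QE/DISC formulas so either route can serve as the other's check.  The
decomposition always uses `D = Δ²/2` internally — this is the scale on
which the cross-entropy equals half a squared Euclidean distance;
`quadratic_entropy()` also accepts any raw `D` for general use.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tol` (fit, space) | `1e-9` | relative eigenvalue cut: axes with `λ ≤ tol·λ_max` are dropped; an eigenvalue below `−tol·λ_max` aborts as non-Euclidean; the same cut sets the rank of the co-factor subspace `G_B` in version 2 |
| `tol` (`is_euclidean`) | `1e-10` | relative tolerance of the standalone embeddability predicate |
| `community_weights` | even, `1/(rm)` | weights of the communities; level weights are the marginals; the exact three-way split of SS(C) requires product-form weights, so other choices draw a warning |
| `q` | 2 | axes shown by `print`/`plot`; all retained axes are stored and written |
| `transform` | `"none"` | optional `sqrt`/`log1p` damping of raw values |

Percentages per axis are reported against **two** bases: the retained-axis
total and the exact SS component of the target factor.  The two coincide
when no axes are discarded, but only the SS-based figure is comparable
across analyses, so both are kept.

## Numerical choices

* **Sign convention.**  Eigenvector signs are arbitrary; we orient every
  axis so the coordinate of largest absolute value (species side) is
  positive, making outputs reproducible across platforms.
* **Ties.**  Equal eigenvalues leave the eigenbasis of the tied subspace
  arbitrary; the orthogonal-complement projector of version 2 is
  basis-invariant, and tests compare only rotation-invariant quantities
  (distances, inertias, eigenvalue multisets) wherever a tie can occur.
* **Clamping.**  ANOQE components in `(−1e-12, 0)` — pure floating-point
  cancellation — are clamped to zero.
* **Degenerate inputs.**  A factor whose level profiles coincide has a
  degenerate cloud: the fit returns zero axes and empty score matrices with
  a warning rather than an error, since the partition half of the output is
  still meaningful.  Version 2 refuses to run when the species space has no
  more axes than the co-factor subspace (the complement would be empty).
  Species with zero global proportion would make the weighted metric
  singular; they are dropped with a warning when the table is built.
* **Nodal distances** count the degree-2 root of a rooted tree as a real
  node (paths through it count two edges), which is the strict reading of
  an edge count on the drawn tree; `collapse_root = TRUE` merges the two
  root edges for the unrooted reading.  Nodal distances are checked for
  embeddability rather than silently square-root transformed, because the
  transform changes the metric being analysed.
* **Taxonomic distances** place species sharing none of the `L` listed
  ranks at `L + 1` (the implicit root), computed as `L + 1` minus the
  number of trailing coarse-side rank matches — ultrametric for any
  labelling, nested or not.

## What the generator emulates — and what it does not

`simulate_table()` mirrors the structure of a factorial field survey: a
random phylogeny (`ape::rtree`), i.i.d. normal baseline log-abundances,
additive clade-level shifts for each level of each factor (and per-cell
shifts for the interaction), a softmax onto proportions, and optionally a
multinomial sample of finite depth per community.  Defaults — 40 species,
`r = 5` crossed with `m = 6`, unit main effects, a half-unit interaction,
infinite depth — give a realistically dominant within-community component
(SSW around 95% of SST) comparable to abundance surveys along habitat
gradients.  Clades are contiguous leaf blocks in cladewise order:
`"disjoint"` separates A-clades from B-clades (so an A-only configuration
has exactly zero SSB and SSAB at infinite depth), `"overlapping"` draws
them independently, and `"collinear"` reuses the B patterns for A, the
regime version 2 is designed to expose.

The generator does *not* emulate several features of real data: log-series
abundance distributions with many rare species, spatial or temporal
autocorrelation between communities, detection error, unbalanced or
replicated designs, or correlation between a species' abundance and its
phylogenetic position beyond the block-clade shifts.  Passing tests
therefore demonstrate the *identities and mechanics* of the method under
controlled conditions, not its ecological power on any particular real
system.

Determinism: each run consumes one seed, from which fixed sub-seeds for the
tree, the abundances and the sampling stage are derived, and the caller's
RNG state is restored afterwards.

## Validation design and problem sizes

The test suite checks every identity at small-to-moderate sizes chosen so
the whole suite runs in well under a minute: 100 random datasets with
`S ∈ [8, 24]`, `r, m ∈ [2, 4]` for the partition and duality identities
(tolerance `1e-8`); exact 2 × 2 single-species fixtures for the closed-form
values (tolerance `1e-10` or better); 3-species × 4-community random tables
against a directly coded non-symmetrical correspondence analysis, which the
equidistant case must reproduce axis by axis; and a 5-point effect grid ×
20 seeds at sampling depth 1000 for the stochastic check that the
version-1 eigenvalue sum rises with the simulated A effect.  Exactly
orthogonal and exactly collinear 2 × 2 proportion-space fixtures probe the
two regimes where versions 1 and 2 must coincide and must diverge; the
collinear fixture is built directly in proportion space because the softmax
generator is only first-order collinear.

## Known limitations

* Only complete balanced crossings with one community per cell are
  supported; replicated or unbalanced designs require aggregation before
  entry (the community-weight hook is the only concession).
* No significance testing is provided; the outputs are descriptive
  decompositions and ordinations.
* Non-product community weights break the exactness of the three-way
  among-community split (warned).
* The published avian case study (5 locations × 6 seral stages) is
  distributed as a binary supplementary archive and is not shipped here;
  the corresponding check in the test suite documents the expected axis
  shares and runs whenever a plain-text export is placed under
  `inst/extdata/case-study/`.
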