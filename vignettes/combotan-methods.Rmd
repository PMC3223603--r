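---
title: "Gaussian shape and color Tanimoto similarity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian shape and color Tanimoto similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combotan)
```

## The scoring model

`combotan` scores the 3-D similarity of conformer pairs the way ROCS-style
shape methods do. Each heavy atom is a spherical Gaussian density
$\rho_i(r) = p\,e^{-\kappa_i |r - r_i|^2}$ with amplitude $p = 2.7$ and a
width calibrated so that an isolated atom's integral equals its hard-sphere
volume $\tfrac43 \pi R^3$ at the uniform heavy-atom radius $R = 1.70$ Å:

$$\kappa = \pi \left( \frac{3p}{4\pi R^3} \right)^{2/3} \approx 0.8112\ \text{Å}^{-2}.$$

Hydrogens are excluded everywhere; every heavy atom uses the carbon-like
radius. The overlap volume of two conformers is the analytic density-overlap
integral

$$V_{AB} = \sum_{i \in A}\sum_{j \in B} p^2
\left(\frac{\pi}{\kappa_i + \kappa_j}\right)^{3/2}
\exp\!\left(-\frac{\kappa_i \kappa_j}{\kappa_i + \kappa_j} d_{ij}^2\right),$$

and the **shape-Tanimoto** is $ST = V_{AB} / (V_{AA} + V_{BB} - V_{AB})$,
which is exactly 1 for a conformer against itself and decays to 0 with
separation. The choice of the *density product* (rather than an
inclusion–exclusion volume) inside the Tanimoto is deliberate: it keeps the
identity case exact and the objective smooth and differentiable.

Pharmacophore features — donor, acceptor, cation, anion, hydrophobe, ring —
are "color atoms": fictitious Gaussians of radius 1.0 Å at the feature
position (the centroid of the member atoms). Only same-type features
overlap; the six types are independent. The **color-Tanimoto** is the
Tanimoto of the type-summed overlaps,

$$CT = \frac{\sum_f V^f_{AB}}{\sum_f V^f_{AA} + \sum_f V^f_{BB} - \sum_f V^f_{AB}},$$

with $CT = 0$ by convention when both conformers are featureless, so that a
pair of plain hydrocarbons reports no feature similarity. An alternative
reading — averaging six per-type Tanimotos — was considered and rejected: it
is undefined for types absent from both molecules and does not reduce to the
standard color force-field score. The **combo-Tanimoto** is the plain sum
$ComboT = ST + CT \in [0, 2]$, never rescaled.

## Superposition optimization

Two rigid-body alignments are computed per pair: one maximizing $V_{AB}$
(ST-optimized) and one maximizing $\sum_f V^f_{AB}$ (CT-optimized). All
three scores are evaluated at each optimal pose, giving six measures per
pair: $ST^{ST\text{-}opt}$, $CT^{ST\text{-}opt}$, $ComboT^{ST\text{-}opt}$,
$ST^{CT\text{-}opt}$, $CT^{CT\text{-}opt}$, $ComboT^{CT\text{-}opt}$.

The optimizer is a deterministic multi-start local search:

* **Starts.** Both conformers are placed in their principal (inertial)
  frames of the shape density; the four proper axis-flip combinations give
  four relative poses. The CT-optimization adds one start per shared
  feature type, translating the type centroids onto each other. Axis signs
  follow a fixed convention (largest component positive, third axis a cross
  product), so the start set is reproducible; ties between equally scoring
  finals go to the first start in this fixed order.
* **Local refinement.** BFGS on a rotation-vector + translation
  parameterization with analytic gradients of the Gaussian overlap
  (the rotation gradient is the cross-product form chained through the
  SO(3) left Jacobian), relative tolerance $10^{-10}$, at most 200
  iterations. Overlap terms with exponent below $-30$ are skipped; the
  dropped mass is below $10^{-13}$ per term.
* **Cross-seeding.** Inside `score_pair()` each optimum is offered as an
  extra start to the other search. This enforces the defining argmax
  property ($ST^{ST\text{-}opt} \ge ST^{CT\text{-}opt}$ and
  $CT^{CT\text{-}opt} \ge CT^{ST\text{-}opt}$) even when one basin would
  otherwise be missed.
* Only proper rotations are searched; mirror images are never considered.

Identical inputs therefore give bitwise-identical records, and the reported
optimum is never below the objective at any start pose.

## Descriptors

`monopole_volume()` is the *first-order inclusion–exclusion* Gaussian
volume $\sum_i v_i - \sum_{i<j} v_{ij}$ — a size descriptor, distinct from
the self-overlap used in the Tanimoto. Two caveats are intentional and
documented: at $p = 2.7$ two fully coincident atoms give $1.046\times$ a
single atom's volume (the amplitude is the field's standard approximation
to $2\sqrt2$, at which the relation would be exact), and the first-order
truncation deviates a few percent from the exact product-form volume on
small chains. Tests therefore check the volume against a term-enumeration
oracle and closed forms, while grid quadrature (which is spectrally
accurate for Gaussians) validates the density-defined quantities: pairwise
overlaps and the quadrupole.

`shape_quadrupole()` reports the eigenvalues of the *unnormalized* second
central moment of the shape density,
$Q_a = \int \rho(r)\,(a\cdot(r - c))^2\,dr$ (units Å⁵), sorted
$Q_x \ge Q_y \ge Q_z$ — squared length, width and height weighted by
volume. The absolute normalization of published Å⁵-scale quadrupoles is
not recoverable from their reported values alone, so these descriptors are
internally consistent (rigid-motion invariant, grid-validated) but may
differ from other software by a constant factor.

Eligibility mirrors the standard conformer-model restrictions: single
covalent component, organic elements (H, C, N, O, F, P, S, Cl, Br, I),
at most 50 heavy atoms, 15 effective rotors, 5 undefined stereocenters.
Rotor and stereocenter counts are metadata: the generator supplies them
explicitly, and SDF ingest estimates rotors as acyclic non-terminal single
bonds between heavy atoms (bridges of the bond graph), which is an
approximation to "effective rotors", not a redefinition.

## The assay statistics

Within one assay, every tested compound is either *inactive* or
*noninactive* — anything not explicitly reported inactive (active,
inconclusive, probe, unspecified) counts as noninactive, because "active"
is not consistently defined across depositors. Compound pairs are then
partitioned into NN (noninactive–noninactive) and NI
(noninactive–inactive); inactive–inactive pairs are never used. Assays
need at least 6 NN and 6 NI pairs to enter the analysis; below that the
per-assay averages are dominated by a handful of pairs.

Per assay and measure the package reports $\mu(XT_{NN})$,
$\sigma(XT_{NN})$, $\mu(XT_{NI})$, $\sigma(XT_{NI})$, and the separation
$\mu(XT_{NN-NI}) = \mu(XT_{NN}) - \mu(XT_{NI})$, which equals exactly the
mean over all $n_{NN}\times n_{NI}$ cross differences. Its spread is
$\sigma(XT_{NN-NI}) = \sqrt{\sigma_{NN}^2 + \sigma_{NI}^2}$, the population
SD of that full cross-difference set; a pooled standard-error variant is
available via `sd_diff = "pooled"`. All SDs use the population divisor
$n$: the pair set of an assay is a complete finite population, not a
sample from one. Conflicting outcomes for one compound resolve to
noninactive (one non-inactive report suffices), with a warning.

Across assays, bracketed moments $\mu[\cdot]$ and $\sigma[\cdot]$ summarize
the per-assay quantities by category (screening, confirmatory, summary,
other, unspecified) and overall. An assay is an **outlier** for a measure
when its $\mu(XT_{NN-NI})$ falls outside $\mu[\mu] \pm k\,\sigma[\mu]$
(default $k = 1$): upper-bound outliers separate actives from inactives
more strongly than typical; lower-bound outliers show the reverse, the
signature of activity-cliff-like series where a 3-D-similar family is
mostly inactive. `rank_outliers()` orders assays by the ComboT separation
averaged over the two optimization types, and `outlier_report()` adds the
cross-measure and cross-optimization overlap counts.

Reporting conventions: histograms bin scores at width 0.01 using
round-half-to-even (the C `rint` convention); report tables round to 2
decimals; score files serialize at 4 decimals; internal arithmetic is
never rounded. The chance-neighbor arithmetic in `neighbor_probability()`
follows the reporting convention used with these distributions — the plain
product of the two percentage tails, capped at 100, with the "1 in N"
reciprocal taken as $100/p$.

## The synthetic generator

Real conformer corpora are far too large to re-score at desk scale, so the
generator emulates the two properties the statistics depend on:

* **Population realism in the descriptor sense.** Heavy-atom counts are
  truncated-normal 24.6 ± 6.4 on [5, 50]; per-type feature counts use the
  rates acceptor 2.9 ± 1.6, donor 1.1 ± 1.0, anion 0.2 ± 0.4, cation
  0.6 ± 0.8, hydrophobe 0.3 ± 0.6, ring 3.0 ± 1.2 (about 8 features per
  molecule), matching the descriptor profile of large biologically tested
  collections. Geometry is a self-avoiding chain: 1.54 Å bonds,
  tetrahedral angles with 5° jitter, uniform dihedrals, 2.0 Å minimum
  non-bonded distance by rejection. Elements are carbon with 25% N/O
  substitution — enough chemical flavor for feature placement without any
  perception chemistry, which stays out of scope by design (features are
  generator-assigned or file-supplied, never perceived).
* **Controllable 3-D relatedness of the noninactive set.** Null-mode
  assays sample all compounds i.i.d. from the population, so NN and NI
  scores share one distribution and the expected separation is zero —
  the pipeline's null calibration. Clustered-mode assays build their
  noninactives by perturbing one template conformer (two templates when
  the set has ≥ 8 members, modeling a pair of congeneric series) with
  i.i.d. Gaussian coordinate noise (default σ = 0.25 Å) and draw
  inactives from the background; these assays must surface as upper-bound
  ComboT outliers. Generated rotor metadata is sampled within the
  eligibility limits, so synthetic populations are 100% eligible.

What the generator does *not* emulate — torsional ensembles, real
pharmacophore chemistry, potency values, 2-D structure — bounds what
passing tests show: the pipeline's arithmetic and its ability to recover
injected structure, not the biology of any particular assay corpus.

## Problem sizes and numerical choices

The shipped studies use a 120-compound population with 50 assays of 6
noninactives and 8 inactives each (15 NN + 48 NI pairs per assay, roughly
2,500–3,500 unique scored pairs per study); these sizes give Monte-Carlo
standard errors small enough for the 3-SE null check while each study
completes in a couple of minutes on one core. The null-calibration
tolerance is 3 Monte-Carlo standard errors of the across-assay mean; the
recovery experiment requires ≥ 0.9 sensitivity for flagging the five
clustered assays among 45 null ones.

Degenerate inputs are handled by convention, not error, wherever a
convention is defensible: single atoms take the identity principal
rotation; featureless pairs return the shape pose with $CT = 0$;
both-empty color denominators yield $CT = 0$; zero across-assay variance
yields empty outlier sets with a warning. Genuine impossibilities (empty
conformers, self-pairs, non-organic elements, missing score records)
are errors that name the offender.

## Known limitations

* Scores are computed for one conformer per compound; selecting the best
  pair over multi-conformer ensembles is explicitly out of scope.
* No numeric parity with any particular commercial shape toolkit is
  promised: the Gaussian amplitude, radii and the color chemistry of
  those implementations are not public. The contracts promised here are
  the mathematical ones (identity = 1, symmetry, argmax dominance,
  oracle agreement).
* The outlier rule is the descriptive $\mu \pm \sigma$ heuristic, not a
  hypothesis test; no multiple-testing correction is applied.
* The local optimizer guarantees a local maximum not below any start
  pose; global optimality on adversarial shapes is not guaranteed
  (mitigated by the inertial multi-start set plus cross-seeding).
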