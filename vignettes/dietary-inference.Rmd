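---
title: "Inferring platyrrhine diet from molar shearing and occlusal topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring platyrrhine diet from molar shearing and occlusal topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`molardiet` reconstructs broad diet categories — folivore, frugivore, and
hard-object feeder — of New World monkeys from the occlusal morphology of
their upper and lower first molars. Three functional indices carry the
signal: the Shearing Quotient (SQ) from linear crest measurements, and two
surface-topography indices, the Relief Index (RFI) and Occlusal Relief
(OR), from triangle meshes of crown scans. The indices feed non-parametric
and phylogenetic group comparisons and an equal-prior linear discriminant
classification with leave-one-out cross-validation. This vignette explains
the models, the tunable parameters, and the design choices; every number
quoted here is computed by the package's tests, analysis scripts, or
acceptance script.

## The shearing quotient

Molar shearing is measured as *total shear* `S`, the sum of the lengths of
six homologous shearing crests on a first molar (mm). Because `S` does not
scale isometrically with tooth size, a simple ratio to molar length is not
size-free; instead the expected shear for a tooth of mesiodistal length
`L` is obtained from a regression fitted **on frugivorous species only**:

    log10 S = a + b log10 L

fitted to species means by phylogenetic generalized least squares (PGLS),
so shared evolutionary history does not masquerade as a dietary signal.
Expected and observed shear are then compared in real space:

    E = 10^(a + b log10 L),    SQ = 100 (S - E) / E

A frugivore of typical build has SQ near 0; folivores (long crests for
leaf shredding) are positive; hard-object feeders (blunt, crushing crowns)
are negative.

Two resolved questions the sources left open:

* **Expected value per individual.** The calibration line is always fitted
  to species means, but the expected shear for an individual can be
  evaluated at the individual's own `L` (default, `expected_from =
  "individual"`) or at its species-mean `L` (`"species"`). Both are exact
  algebraic variants of the same line; outputs record which was used.
* **λ inside the PGLS.** The calibration defaults to λ fixed at 1 (pure
  Brownian errors) because the SQ residuals in this clade carry strong
  phylogenetic signal (λ̂ = 1 on the real species means) and fixed-1 is the
  common default of comparative-methods tooling; `lambda = "ml"` profiles
  λ jointly by maximum likelihood when the user prefers to estimate it.

## Phylogenetic machinery

The Brownian covariance `C` of a rooted tree with branch lengths has
`C[i, j]` equal to the root-to-MRCA path length of species `i` and `j`.
Pagel's λ rescales only the off-diagonal of `C`; λ = 0 is a star phylogeny
(no signal), λ = 1 pure Brownian motion. `fit_lambda_ml()` profiles the
one-trait likelihood over λ ∈ [0, 1] with the mean and rate maximized in
closed form, and reports a χ²(1) likelihood-ratio test against λ = 0.

Numerical choices: λ is optimized by a 21-point grid followed by
golden-section refinement (a bounded, derivative-free 1-D problem), with
ties broken toward the larger λ for reproducibility. GLS fits whiten with
the Cholesky factor of `C`; the reported R² is `1 − RSS/TSS` computed on
the whitened variables with TSS about the GLS mean, i.e. in the same
metric the fit minimizes. Trees need not be ultrametric and are never
rescaled; multifurcations are handled directly by the edge-wise Brownian
simulation. A matrix that fails its Cholesky factorization aborts with the
condition number rather than silently regularizing.

The phylogenetic ANOVA compares the ordinary F statistic of species means
across diet groups with a null distribution of F values from traits
simulated under Brownian motion on the same tree, with the rate σ²
estimated from the pooled data by maximum likelihood. The p-value is
`(1 + #{F_sim ≥ F_obs}) / (1 + n_sim)`, exactly reproducible under the
mandatory seed; `n_sim` defaults to 1,000.

## Topographic indices from meshes

Crown meshes are assumed pre-oriented (occlusal plane horizontal; the up
axis is configurable, default `z`) and pre-cropped at the cemento-enamel
junction — both steps are landmark judgements made on the scan, not
automated here.

* **TSA** is the summed 3-D triangle area; degenerate and duplicated faces
  are kept as stored (area 0 for degenerate) because mesh repair is out of
  scope and determinism matters more.
* **PSA** is the area of the planar **union** of all faces projected along
  the up axis — overlap is counted once, so folded sidewalls cannot
  inflate the occlusal outline. The default algorithm is exact: the
  projected arrangement is cut into vertical slabs at every projected
  vertex and every interior edge crossing; within a slab the union
  cross-section is linear in x, so a midpoint evaluation integrates it
  exactly. A rasterization estimator (default 2048 pixels on the longer
  side) backs it up for very large or pathological meshes, and the two
  methods are required to agree within the pixel-area bound in the test
  suite.
* **RFI** = `ln sqrt(TSA/PSA)`: 0 for a flat surface, 0.5 ln 2 ≈ 0.347 for
  a hemisphere.
* **OR** divides the 3-D by the projected area of the crown **above the
  talonid-basin plane**: 1 for a flat table, 2 for a hemisphere cropped at
  its equator. The crop plane passes through the lowest point of the
  talonid basin; triangles straddling the plane are split exactly. When no
  basin point is supplied, the package proposes one: cusp tips are local
  height maxima above the 75th height percentile, and the candidate basin
  is the lowest vertex whose projection falls strictly inside the convex
  hull of the tips (between the two tips, for a two-cusp tooth); ties go
  to the lowest vertex index. Manual specification remains the primary
  path — the automatic rule merely operationalizes the manual procedure.
  OR is intended for lower molars (upper-molar cingulum variation defeats
  a consistent crop) and must be requested explicitly otherwise.

## Group statistics and classification

Diet categories follow a fixed rule: over 50% recorded leaf-feeding time
makes a folivore; otherwise a substantial hard-seed/nut component makes a
hard-object feeder; otherwise fruit as the primary component makes a
frugivore. Group summaries report means with two-sided t-based 95%
confidence intervals over individuals (the CI construction of the
published summaries is unstated; t-intervals are the conventional choice).
A sample-size-weighted mode reconstructs group means from species means.
Kruskal–Wallis (tie-corrected, χ² approximation) tests overall differences;
pairwise Wilcoxon rank-sum tests use the exact distribution when both
groups have ≤ 10 tie-free observations and the normal approximation with
tie and continuity corrections otherwise, recording which ran. The
family-wise criterion is α divided by the number of pairs actually tested
(0.05/3 ≈ 0.0167 for three groups), computed exactly and rounded only for
display.

Classification is classic pooled-covariance LDA with equal priors — equal
priors deliberately ignore the unequal group sizes so that prevalence does
not leak into the morphology signal. Features enter together (no stepwise
selection). Posterior ties break by alphabetical group order,
deterministically. No regularization is applied by default; a ridge on the
pooled covariance is available behind a flag for near-singular synthetic
cases. Reported rates are leave-one-out cross-validated; resubstitution is
available as the optimistic reference. Canonical variate scores come from
the whitened between-group eigenproblem, each function labelled with its
percent of between-group variance.

## The synthetic generator

`simulate_study()` produces the full input bundle with known ground truth:
a unit-depth pure-birth tree; species means for the five indices as
Brownian deviations plus per-diet offsets; specimen values as species
means plus independent normal noise; molar lengths log-normal around a
species mean; and total shear placed on a true frugivore line
(`log10 S = a + b log10 L`) shifted by each species' SQ deviation, then
split across six crests in fixed proportions.

Its defaults are the study conditions, fixed once: 13 species in a
3 folivore / 7 frugivore / 3 hard-object multiset; ~7 specimens per
species; diet offsets patterned on the observed group means (e.g. upper
SQ 34.5 / 2.3 / −12.3); within-species SDs patterned on the medians of the
observed per-species SDs (upper SQ 6.28, lower SQ 5.43, OR 0.09, RFI
0.02); between-species Brownian SDs at unit depth patterned on the
observed within-group scatter of species means; true shearing lines
(0.30, 0.91) lower and (0.45, 0.74) upper, matching the observed
negative-allometry shape; and a small per-diet offset on log length
(folivores +0.08, hard-object −0.04) reflecting that the folivores in the
sample are the larger-bodied species, which is what makes molar length
alone informative.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: wear and breakage, cingulum shelves and
enamel crenulation, undercut sidewalls (fixture crowns are single-valued
height fields, so TSA ≥ PSA is provable rather than empirical),
measurement error correlated across crests, and any diet structure beyond
three clean categories.

## Problem sizes and runtime posture

The test and acceptance workloads are sized for quick, repeated runs:
recovery and null-calibration studies use 15–30-species trees with 20–60
replicates, phylogenetic ANOVAs use 200–1,000 simulations, and analytic
mesh oracles use ~2,000–9,000-triangle tessellations, where the
hemisphere's area ratios are within 1% of their closed forms. These sizes
were chosen so each property is measured well inside its Monte-Carlo
noise floor.

## Known limitations

* PSA's exact union is O(E²) in edge crossings in the worst case; the
  rasterization fallback (triggered above 30,000 edges by default) trades
  exactness for a pixel-area error bound.
* The basin auto-detector assumes cusps are local height maxima of a
  reasonably clean mesh; scan noise can introduce spurious tips, and the
  manual basin point should be preferred for real scans.
* λ is bounded to [0, 1]; implementations that allow λ slightly above 1
  (to the PD limit of the transformed covariance) can return marginally
  higher likelihoods on strongly Brownian traits.
* Weighted group summaries carry no confidence interval, since
  within-species spread is not recoverable from species means alone.
* Only first molars are modelled; the six-crest schema is fixed, and
  crests 7–8 (hypocone/trigonid margins) are not representable.
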