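# molardiet

Dietary inference from upper and lower first-molar morphology in
platyrrhine (New World monkey) primates — for paleontologists and
comparative morphologists who want to read diet off teeth, including teeth
of extinct taxa known only from a molar or two.

The package implements three functional indices of the occlusal surface
and the statistical pipeline that turns them into diet-category
assignments (folivore, frugivore, hard-object feeder):

* **Shearing Quotient (SQ).** Total shear *S* is the summed length of six
  shearing crests. Expected shear for a molar of mesiodistal length *L*
  comes from a frugivore-only phylogenetic generalized least-squares
  regression of species means, `log10 S = a + b·log10 L`, and

  `SQ = 100·(S − E)/E`, with `E = 10^(a + b·log10 L)`.

  Positive SQ = more shear than a typical frugivore (folivores), negative
  = less (hard-object feeders).
* **Relief Index (RFI)** `= ln(√TSA/√PSA)` and **Occlusal Relief (OR)**
  `= TSA/PSA` above the talonid-basin plane, where TSA is the 3-D crown
  surface area of a triangle-mesh scan and PSA the area of its occlusal
  projection (an exact polygon-union computation, with plane-splitting
  basin crops).
* **Comparative statistics & classification.** Pagel's λ by profile
  maximum likelihood, PGLS, a simulation phylogenetic ANOVA with
  Brownian-motion nulls, Kruskal–Wallis and pairwise Wilcoxon tests with
  Bonferroni correction, and equal-prior linear discriminant analysis with
  leave-one-out cross-validation over feature subsets.

A first-class synthetic-data generator (`simulate_study()`) emulates the
study's structure — 13 species on a pure-birth tree, Brownian species
means with diet offsets, within-species noise, and parametric cusp-on-base
tooth meshes — so every stage is testable against known ground truth.

## Worked example

```r
library(molardiet)

study <- simulate_study(synthetic_config(seed = 42))
cal <- calibrate_shear(study$specimens, "M1_lower", study$tree, lambda = 1)
print(cal)
#> Frugivore shearing calibration (M1_lower), 7 species
#> PGLS fit, n = 7 species
#>   y = 0.32949 + 0.85290 x   (lambda = 1, R^2 = 0.925)

sq <- compute_sq(study$specimens, cal)
round(tapply(sq$sq_percent, sq$diet, mean), 2)
#>    folivore   frugivore hard_object
#>       17.68       -2.03      -13.76

f <- study$features
f$sq_lower <- sq$sq_percent[match(f$specimen_id, sq$specimen_id)]
X <- as.matrix(f[c("sq_lower", "or_lower", "rfi_lower", "length_lower_mm")])
loo_classify(X, f$diet)
#> Classification report (leave_one_out), n = 91
#>   overall correct: 86.8%
```

The calibration recovers the generator's true frugivore line (a = 0.30,
b = 0.91) up to Brownian scatter; diet-group mean SQs order folivore >
frugivore > hard-object around the frugivore zero; and the lower-molar
feature set classifies 86.8% of specimens correctly under leave-one-out —
the diagnostic pattern the indices are designed to produce.

The reference species tables shipped with the package reconstruct the
published diet-group summaries by sample-size weighting:

```r
subset(reconstruct_group_means(), variable == "sq_upper")
#>        group variable weighted_mean  n
#>     folivore sq_upper     34.536667 21
#>    frugivore sq_upper      2.444182 55
#>  hard_object sq_upper    -12.249259 27
```

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

1. `01_simulate.R` — synthetic study bundle (specimens, features, tree).
2. `02_shearing.R` — frugivore PGLS calibrations and per-specimen SQ.
3. `03_topography.R` — RFI/OR on parametric crowns with analytic anchors.
4. `04_group_stats.R` — reconstruction of the published group means from
   the reference tables, plus λ / Kruskal–Wallis / Wilcoxon /
   phylogenetic-ANOVA battery.
5. `05_classify.R` — LOO classification-rate grid and canonical scores.
6. `06_full_run.R` — the orchestrated `run_full()` report bundle
   (table2–table5, scores, run.log).

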