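---
title: "Methods: GA-driven QSAR modelling, validation and applicability domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-driven QSAR modelling, validation and applicability domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaqsar)
```

## The modelling problem

Small-series QSAR studies relate a bioactivity endpoint — here pIC50 =
−log10 IC50(M) of enzyme inhibitors — to numeric molecular descriptors.
The regime this package targets is the classical and statistically
treacherous one: a few dozen compounds against a descriptor pool that is one
to two orders of magnitude larger, heavily redundant, and partly
uninformative. Every stage of the workflow exists to manage that imbalance:

1. **Reduction** removes descriptors that cannot carry signal (constant,
   near-constant) or that duplicate other descriptors (pairwise |r| above a
   cut, resolved in favour of the member better correlated with activity).
2. **Splitting** holds out a structurally dispersed test set via
   hierarchical clustering, rather than a plain random draw, so the test
   compounds interpolate the training chemistry.
3. **Subset selection** searches the reduced pool for a fixed-size
   descriptor combination by a genetic algorithm scored with leave-one-out
   Q² — a wrapper criterion that directly penalizes overfitting.
4. **Modelling** fits an interpretable linear equation (MLR with
   coefficient ± SE reporting) and a nonlinear RBF ε-SVR on the *same*
   subset, so the linear/nonlinear comparison is apples-to-apples.
5. **Validation** computes the full battery a reviewer of such a study
   expects: R², RMSE, F, adjusted R², Q²(LOO), bootstrap Q²,
   Y-randomization, Lin's CCC, Roy's rm², the Golbraikh–Tropsha conditions,
   and VIFs.
6. **Applicability domain** bounds where predictions may be trusted, by
   leverage (Williams plot) and by normalized Euclidean mean distance.

## Models

### MLR

Ordinary least squares of pIC50 on the selected descriptors, on their raw
scale, so the equation prints directly as
`pIC50 = b0 (± se0) + b1 (± se1) X1 + …`. Standard errors come from the
unbiased residual variance and the inverse normal matrix. A rank-deficient
design is a hard error, not a silent pseudo-inverse.

### RBF ε-SVR

Support vector regression with kernel `k(u,v) = exp(−γ‖u−v‖²)` and
ε-insensitive loss. Descriptors **and** activity are autoscaled on the
training set before fitting: the RBF kernel and the ε tube are meaningless
across incommensurate descriptor units (this is a documented choice — the
convention is not fixed in the field; ε and γ are therefore expressed on the
autoscaled scale). Predictions are back-transformed to pIC50. The dual QP is
solved by an in-package SMO routine with second-order working-set selection
(no R SVM backend is assumed to be installed); a gap tolerance of 1e−6 on
the scaled problem leaves the dual solution far more precise than any
statistic computed from it, and the test suite checks the solver against an
independent projected-gradient solve of the same QP and against exact
analytic cases.

Hyperparameters (C, γ, ε) are chosen by leave-one-out RMSE over a grid whose
default spans C ∈ {1, 10, 50, 100}, γ ∈ {0.1, 1, 5, 10},
ε ∈ {0.001, 0.01, 0.1} — a decade bracket around the values typically
reported as optimal for autoscaled small-series data (C = 50, γ = 5,
ε = 0.01), which the default grid contains. Ties break toward the smallest
C, then γ, then ε: prefer the least complex model among equals.
Autoscaling constants are computed once on the full training set and held
fixed across the LOO folds; refitting the scaler inside each fold would
change the hyperparameter meaning fold-to-fold for a negligible gain at
n ≈ 28.

## Parameters that matter

| Parameter | Default | Units / scale | Why this default |
|---|---|---|---|
| `near_constant_fraction` | 0.95 | mode frequency | Dragon-era practice; 1.0 disables the frequency rule |
| `r_cut` | 0.9 | Pearson r | the conventional collinearity cut for descriptor matrices |
| `test_fraction` | 0.2 | fraction | 7 of 35 compounds in the canonical small-series design |
| `linkage` | complete | — | compact, homogeneous clusters; ward/average/single selectable |
| `subset_size` | 5 | descriptors | the model size small-series equations typically carry |
| GA population / generations | 50 / 100 | — | comfortably exceeds convergence on pools of a few hundred descriptors |
| crossover / mutation / elitism | 0.8 / 0.1 / 2 | prob. / prob. / count | standard GA settings; elitism ≥ 1 makes best fitness monotone |
| GA fitness | Q²(LOO) | — | penalizes overfitting where training R² would reward it |
| `n_boot` | 5000 | resamples | the customary repetition count for bootstrap Q² |
| `n_yrand` | 10 | permutations | the customary Y-randomization count |
| SVR tolerance | 1e−6 | dual gap | see above |
| `noise_sd` (generator) | 0.2 | pIC50 | a realistic replicate error for IC50 assays (~1.6× in concentration) |

## The synthetic-data generator

No real descriptor matrix ships with the package, so the generator is the
test bed for the whole pipeline. It emulates the *statistical* structure the
workflow assumes — not the chemistry:

* standard-normal descriptor marginals (matching the autoscaled-descriptor
  assumption downstream);
* a small informative subset driving pIC50 linearly, with the noiseless
  signal affine-mapped to span exactly 4–8 pIC50 units, the potency range a
  usable inhibitor series covers;
* exactly constant columns, near-constant columns (mode frequency ≥ 0.95),
  and collinear pairs built as x₂ = x₁ + noise with population r ≈ 0.95
  (the noise draw is repeated, seeded and bounded, until the *sample*
  correlation exceeds 0.9, so planted pairs are always detectable at the
  standard cut);
* optionally a product interaction between two informative descriptors,
  scaled to 20% of the linear signal variance — enough nonlinearity for the
  SVR to have a measurable edge over MLR without drowning the linear signal;
* Gaussian activity noise with configurable SD.

What it does **not** emulate: heavy-tailed or discrete descriptor
distributions (atom counts, fragment indicators), block correlation among
descriptor families, activity cliffs, or measurement error in the
descriptors. A green recovery test therefore establishes that the pipeline
finds planted structure of the stated kind at the stated noise level — not
that it would rank descriptors correctly on any real Dragon matrix.

## Numerical choices and degenerate inputs

* **LOO for OLS** uses the exact hat-matrix identity
  e(i) = e/(1−h) instead of n refits; the test suite pins it to an explicit
  refit loop at 1e−10. SVR LOO is a true refit loop.
* **Bootstrap Q²** pools out-of-bag squared errors over all resamples
  (denominator: deviations of out-of-bag activities from the resample
  mean). The estimator is not standardized in the literature; pooling was
  chosen over per-resample averaging because single resamples can have
  near-degenerate out-of-bag denominators at n ≈ 28. Resamples with no
  out-of-bag compound, or singular refits, are redrawn.
* **rm²** uses Roy's formulation with predicted-on-observed as the default
  origin regression; the axis convention is an argument because the
  literature is inconsistent.
* **Collinearity filter order**: pairs above the cut are resolved greedily
  by descending |r| with skip-if-dropped, which makes chained collinearity
  (A~B~C) deterministic; survivors are guaranteed pairwise ≤ r_cut.
* **Cluster split**: the dendrogram is cut into round(n·test_fraction)
  clusters and one test compound drawn per cluster, giving 7 test compounds
  from 35 at the default fraction with each test compound from a distinct
  cluster. The compounds carrying the global activity minimum and maximum
  are always assigned to training, which enforces the range-coverage rule
  by construction (a bounded retry loop guards the invariant anyway).
* **Ties in the GA** between equal-fitness subsets rank lexicographically
  by descriptor name; GA run r of a multi-run search uses seed + r − 1.
* **Degenerate inputs** error early and loudly: missing/non-finite values,
  all columns (near-)constant, activity absent where required, singular
  designs, identical training rows in the Euclidean AD (zero spread), test
  vectors too short for external statistics.
* Constant activity is a supported edge: the SVR predicts the constant and
  every hyperparameter triple ties at LOO-RMSE 0 (the smallest triple wins).

## Applicability domains

The leverage domain uses h\* = 3p′/n with p′ = descriptors + 1 and
standardizes residuals by the training residual SD for training and query
compounds alike (a documented convention — the query-side denominator is
ambiguous in the source tradition). The Euclidean domain excludes
self-distances when averaging training distances, otherwise every training
score would be systematically deflated; scores are anchored so the training
set spans exactly [0, 1], and query compounds outside that interval are
flagged. Scores are invariant to descriptor permutations and sign flips
(the orthogonal transforms that commute with autoscaling); a general
rotation changes per-column scales and therefore, deliberately, the
autoscaled geometry.

## Known limitations

* The GA is a stochastic search: on pools of hundreds of descriptors a
  single run can settle on a near-optimal subset; multi-run mode
  (`n_runs > 1`) is the intended usage, exactly as alternative-model tables
  are produced in practice.
* The SMO solver is pure R; tuning over the default 48-point grid with LOO
  on ~30 compounds takes tens of seconds, not milliseconds.
* VIFs computed from a *rounded, printed* correlation matrix need not match
  VIFs computed by the original authors from raw data — the package's two
  computation routes (inverse-matrix diagonal and per-descriptor
  regression) agree to 1e−9, but published VIF columns can be irreproducible
  from published correlation tables.
* External-set statistics (rm², CCC, Golbraikh–Tropsha) are only as
  meaningful as the test set is in-domain; run both AD analyses first.

## A worked run

```{r pipeline, eval = FALSE}
run <- qsar_pipeline(
  synth = list(n_compounds = 35, n_descriptors = 150, k_informative = 5,
               n_constant = 6, n_near_constant = 4, n_collinear_pairs = 5,
               noise_sd = 0.2, seed = 1),
  ga = list(n_runs = 10, n_generations = 50),
  n_boot = 5000, n_yrand = 10, seed = 1)
print(run)
plot(run, model = "svr")
plot(run$leverage_ad)     # Williams plot
plot(run$euclidean_ad)
```

The printed report carries the linear equation with ± standard errors, the
MLR/SVM comparison on the shared subset, the Y-randomization block, the four
Golbraikh–Tropsha conditions and both applicability-domain summaries; the
same run is what `scripts/acceptance.R` executes.
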