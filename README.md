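# attrnoise

Simulation toolkit for measuring how **attribute noise** — random or
structured errors in binary predictor features — degrades clinical
prediction models and, more insidiously, the stability of their
per-feature effect estimates.

The motivating setting is EHR-based case-control modelling: ~180 binary
comorbidity indicators ("ICD code blocks") predicting a binary diagnosis
in a balanced cohort of several thousand patients. Recorded indicators
disagree with true patient state for many reasons (coding variation,
ambiguous notes, terminology drift), and the noise level of real data is
unknowable. `attrnoise` therefore builds a synthetic cohort whose ground
truth is exact, corrupts it under controlled mechanisms, and measures what
breaks.

## What it computes

* **Synthetic cohorts** — `generate_cohort()`: balanced 1:1 case-control
  data (default n = 6,794, 180 features), feature prevalences from a
  Beta(1, 9) prior truncated at a 1% support floor, and a sparse logistic
  ground truth: ten planted
  log-odds effects (0.98, 0.876, 0.856, 0.826, 0.745, 0.728, 0.691,
  0.608, 0.599, 0.579 on blocks 117, 63, 34, 2, 106, 175, 9, 71, 67,
  171), intercept calibrated so the population case rate matches the
  case fraction.
* **Noise injection** — `inject_noise()`: three mechanisms patterned on
  the missing-data taxonomy, each spending an exact cell budget
  `B = round(p·n·m)` and returning the flip mask:
  * `NCAR`: uniformly chosen cells toggled;
  * `NAR`: changeable features flipped for the instances with the highest
    unchangeable-feature sums;
  * `NNAR`: zeros set to one (flip depends on the hidden value).
* **Model harness** — `fit_model()` / `evaluate()`: unpenalized logistic
  regression, linear SVM and gradient boosting, with stratified k-fold
  cross-validated AUC and accuracy.
* **Impact scores** — `impact_scores()`: for feature *j*, the mean change
  in decision score when *x<sub>j</sub>* is toggled 0→1, on the log-odds /
  margin scale — equal to the coefficient for linear models, and a
  coefficient-like quantity for boosting. Plus `percent_change()`,
  `top_k_table()` and `dispersion_trajectory()` for the stability
  summaries, and `rm_anova()` (features as subjects, noise proportion as
  the within-subject factor).
* **The full grid** — `run_grid()` / `report()`: every mechanism ×
  proportion (0–30% in 5% steps; 18 noisy datasets by default) × model
  cell, with tables, figures, RM-ANOVA summaries and a seed manifest.

The headline phenomenon the package reproduces: **discrimination declines
monotonically with noise, while the variance of impact scores collapses
even though their means barely move** — so noisy covariates quietly erase
the ability to tell important risk factors from unimportant ones.

## Worked example

```r
library(attrnoise)

coh <- generate_cohort(generator_config(seed = 1))
coh
#> <cohort> 6794 instances x 180 features; 3397 cases / 3397 controls

out <- inject_noise(coh$features, noise_spec("NCAR", 0.05, seed = 1))
sum(out$mask)                              # exact budget: round(0.05 * 6794 * 180)
#> [1] 61146
realized_noise(coh$features, out$noisy)
#> [1] 0.05

spec <- model_spec("logistic_regression")
evaluate(coh, spec, folds = 5, seed = 1)
#> <eval_result> logistic_regression: mean AUC 0.6285, mean accuracy 0.5994 over 5 folds
noisy <- coh; noisy$features <- out$noisy
evaluate(noisy, spec, folds = 5, seed = 1)
#> <eval_result> logistic_regression: mean AUC 0.5979, mean accuracy 0.5695 over 5 folds

fit <- fit_model(coh, spec)
round(coef(fit)[c("117", "63", "34", "2", "106")], 3)
#>   117    63    34     2   106
#> 0.955 0.838 0.494 0.888 0.691
round(coef(fit_model(noisy, spec))[c("117", "63", "34", "2", "106")], 3)
#>   117    63    34     2   106
#> 0.714 0.570 0.011 0.603 0.511
```

Five percent cell noise already costs ~3 AUC points and attenuates every
planted effect (the clean fit recovers the planted values 0.98, 0.876,
0.856, 0.826, 0.745 up to sampling error; block 34's prevalence is near the
support floor under this seed, hence its wide-but-honest estimate). A full
`run_grid()` extends this to all mechanisms, proportions and models; see
`vignette("attribute-noise-simulation")` for the methods.

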