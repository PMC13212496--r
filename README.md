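# cartkin

Kinetic modeling of CAR-T cell cytotoxicity from real-time impedance
assays.

## What problem this solves

Before a CAR-T product is infused, its function is profiled *in vitro*
with an impedance (cell-index, CI) cytotoxicity assay: adherent tumor
targets grow alone for 24 h, the effector product is added at several
effector-to-target (E:T) ratios, and CI is read every 15 minutes for
72 h (289 readings/well). Those curves contain far more than an endpoint
percent-kill number — they encode how fast a product kills, how its
killing scales with the E:T ratio, and how strongly it expands in
response to its own cytotoxicity. `cartkin` is for quantitative
immunologists and pharmacometricians who want to extract those
quantities per product, check which of them the data actually pins down,
and relate them to clinical outcomes.

The core is a three-compartment ODE model of tumor cells `T`,
CAR-expressing effectors `CART`, and inert untransduced T cells `TC`:

```
dT/dt    = kp1 * T * (1 - T/CT) - FC
dCART/dt = FP * ln(CE / (TC + CART)) - kd * CART
dTC/dt   = -kd * TC

FC = kc * (CART/T)^n / (Kmr^n + (CART/T)^n) * T     (ratio-dependent Hill killing)
FP = kp2 * FC^2 / (Kmp^2 + FC^2) * CART             (cytolysis-driven expansion)
```

Around the model the package provides, as tidyverse-style functions
returning tibbles:

- **Impedance preprocessing and calibration** — collective 0–4 CI
  normalization, effector-addition detection, the 1-CI presentation
  shift, and per-product linear calibration between cells and CI
  (`normalize_product()`, `resolve_addition_time()`, `fit_calibration()`,
  `ci_from_cells()`).
- **Staged multi-start estimation** — tumor growth from target controls,
  effector decay from effector controls, then the six effector
  parameters from all co-culture wells jointly by bounded multi-start
  Levenberg-Marquardt least squares in CI units (`fit_product()`, with
  broom-style `tidy()`/`glance()` methods).
- **Sensitivity and identifiability** — one-at-a-time error sensitivity,
  global parameter × E:T sweeps, Fisher-information parameter
  correlations with 0.80/0.93 flags, and E:T sweeps reporting saturation
  and negligible-cytolysis ratios (`error_sensitivity()`,
  `global_sensitivity()`, `parameter_correlation()`, `et_sweep()`).
- **Cohort statistics** — outcome grouping (response, relapse among
  responders, toxicity, disease subsets), exact/corrected two-sided
  Wilcoxon rank-sum tests, rank-biserial effect sizes with bootstrap
  CIs, and Spearman composition correlations (`run_cohort_analysis()`).
- **A synthetic cohort generator** — complete, seed-deterministic
  cohorts (traces, metadata, outcome labels statistically linked to the
  ground-truth parameters) so the whole pipeline is testable with no
  external data (`generate_cohort()`, `cd4cd8_scenario()`).
- **File-based workflow** — `run_generate()` / `run_fit()` /
  `run_analyze()` read and write tidy CSV + JSON with seeds and config
  hashes recorded.

See the methods vignette (`vignettes/cartkin-methods.Rmd`) for the model
assumptions, numerical choices and known limitations.

## Worked example

Generate one synthetic product under the standard protocol, fit it, and
sweep the fitted model across E:T ratios:

```r
library(cartkin)

cfg     <- cohort_config(n_products = 1, seed = 7)
product <- emit_traces(draw_product(cfg, 1), cfg)
fit     <- fit_product(product, fit_config(n_starts = 100, seed = 7))
fit
#> <cart_fit> P001
#>       kp1        CT        kc       Kmr         n       kp2       Kmp        CE
#> 4.513e-02 5.767e+05 1.117e-01 2.418e+00 1.407e+00 4.338e-02 5.345e+02 1.762e+06
#>        kd
#> 1.291e-02
#> SSR 2.318 | overall R2 0.999 | 95/100 starts converged (best #37, seed 7)
```

The product's ground truth was `kc = 0.110`, `Kmr = 2.30`, `n = 1.42`,
`kd = 0.0129`: the staged fit recovers the growth, decay and
cytotoxicity parameters within a few percent at the generator's 2%
reading noise (the proliferation half-saturation `Kmp` is the least
identifiable quantity and lands within ~25% here). `tidy(fit)` returns
the nine estimates with their estimating stage; `glance(fit)` the SSR,
overall R², and multi-start provenance.

```r
et_sweep(fit$params)
#> # A tibble: 7 × 3
#>   et_ratio pct_cytolysis final_ci
#>      <dbl>         <dbl>    <dbl>
#> 1     0.25         0.129       NA
#> 2     0.5          0.349       NA
#> 3     1            1.03        NA
#> 4     2           34.7         NA
#> 5     6.25        88.5         NA
#> 6    12.5         94.5         NA
#> 7    25           97.2         NA
attr(, "saturation_ratio")   # 12.5
```

Read: this product's predicted killing 48 h after effector addition is
negligible at and below 1:2, transitions steeply between 1:1 and 6.25:1,
and saturates near the 12.5:1 ratio — additional effectors beyond that
buy almost nothing, which is the kind of statement that matters when
choosing assay ratios or interpreting *in vivo* E:T.

For a cohort: `generate_cohort(cohort_config(n_products = 45))`, fit
each product with `run_fit()`, then
`run_cohort_analysis(params_table, outcomes)` tests each effector
parameter across outcome groups and reports p-values with effect sizes.

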