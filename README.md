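# tlcqsar

QSAR modelling of serotoninergic ligands from biopartitioning thin-layer
chromatography.

## What this package is for

Medicinal chemists screening candidate ligands of serotonin (5-HT)
receptors can approximate the drug–receptor interaction on a TLC plate:
silanized silica plates are impregnated with small-molecule analogues of
the binding-site amino acids (propionic acid for aspartate, ethylbenzene
for phenylalanine, 4-ethylphenol for tyrosine, propionamide for
asparagine, and mixtures of these with ethanol / isopropyl alcohol),
giving seven biochromatographic model environments S1–S7 next to an
unimpregnated control plate C. How much a compound's retention changes
between the control and an impregnated plate reflects its affinity for
that binding-site element, and regression on those changes predicts
pharmacological activity.

`tlcqsar` implements that workflow end to end for a 20-compound panel of
5-HT ligands (tiapride through propranolol) whose activities, retention
data and 19 calculated molecular descriptors ship with the package as
plain-text tables:

1. **Retention transform** — retardation factors are linearized with the
   Bate-Smith–Westall parameter `R_M = log10(1/R_f − 1)`, and the
   interaction variables `C−Sk = R_M(C) − R_M(Sk)` and
   `Sk/C = R_M(Sk)/R_M(C)` are derived per mobile phase (DS_A, DS_B).
2. **Model building** — ordinary least squares of an activity (pK_i,
   pD_2 or pA_2) on interaction variables and/or molecular descriptors,
   with the classical statistics suite (R, R², adjusted R², variance
   ratio F, standard error of estimate s, overall p), a pairwise
   collinearity filter (|r| > 0.5 drops the member less correlated with
   the response) and forward-stepwise selection with backward checks.
3. **Internal validation** — leave-one-out and repeated leave-N-out
   cross-validation: `PRESS = Σ(y_i − ŷ_(i))²`, `Q² = 1 − PRESS/TSS`,
   `S_PRESS = sqrt(PRESS/n)`, plus the reliability battery
   (R² > 0.6, Q² > 0.5, R² ≥ Q², Q²_LOO ≈ Q²_LNO, R²_adj < R²).
4. **Synthetic data** — a seeded generator that emits tables in the same
   fixture format with known coefficients, configurable predictor
   correlation, noise and missingness, for parameter-recovery and
   selection-level experiments.

## Worked example

The final agonist-potency model regresses pD_2 on the propionamide
(`C-S4`, asparagine mimic) and propionic acid + ethanol (`C-S5`,
aspartate/serine mimic) interaction variables of the DS_A phase:

```r
library(tlcqsar)

d <- load_tables() |>
  assemble_dataset("pD2", c("C-S4", "C-S5"), phase = "DS_A")

fit <- fit_qsar(d, label = "agonist")
fit
#> <qsar_fit agonist> pD2 ~ C-S4 + C-S5  [phase DS_A]
#>   n = 13, R = 0.92, R2 = 0.84, R2adj = 0.81, F = 26.7346, s = 0.3648, p = 0.0001
#> # A tibble: 3 × 5
#>   term        estimate std.error statistic p.value
#>   <chr>          <dbl>     <dbl>     <dbl>   <dbl>
#> 1 (Intercept)     7.69     0.108     71.5   0
#> 2 C-S4          -15.9      2.18      -7.31  0
#> 3 C-S5            8.01     2.36       3.40  0.0068

glance(loo_crossval(d))
#> # A tibble: 1 × 9
#>   kind      n    Q2 PRESS S_PRESS  SDEP SDEP_df     N repetitions
#>   <chr> <int> <dbl> <dbl>   <dbl> <dbl>   <dbl> <int>       <int>
#> 1 LOO      13 0.724  2.33   0.423 0.423   0.483    NA          NA

reliability_check(fit, loo_crossval(d),
                  lno_crossval(d, N = 3, repetitions = 1000, seed = 1))
#> <qsar_reliability> overall: PASS
```

Reading: only 13 of the 20 compounds have a measured agonist potency;
on those, the two interaction variables explain 84% of the variance
(R² = 0.84) with a residual standard error of 0.36 log units. A compound
retained more strongly on the propionamide plate than on the control
(negative `C-S4`, hence a positive contribution via the −15.9
coefficient) is predicted more potent. Leave-one-out validation keeps
72% of the variance (Q² = 0.72, PRESS = 2.33), and the model passes
every reliability criterion, so it is usable for ranking new compounds
of this class. `autoplot(fit)` draws the observed-versus-predicted
scatter; `tidy()`, `glance()` and `augment()` return the usual tibbles.

`reproduce_study(out_dir = "reports")` runs all fifteen model structures
of the study, validates the three final ones, and writes each result
table plus a printed-versus-recomputed comparison file with absolute
differences.

A thin command-line front end with subcommands `transform`, `correlate`,
`fit`, `validate`, `predict`, `simulate` and `reproduce` is installed at
`system.file("cli", "tlcqsar.R", package = "tlcqsar")`; the exit status
of `fit` reflects the reliability verdict.

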