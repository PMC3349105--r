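---
title: "Biopartitioning TLC to activity models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biopartitioning TLC to activity models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlcqsar)
```

This vignette is the package's account of the science it implements: the
retention model, the regression and validation machinery, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the underlying procedure leaves room.

## The measurement model

Thin-layer chromatography reports, per compound and plate, a retardation
factor $R_f \in (0,1)$. The Bate-Smith–Westall parameter

$$R_M = \log_{10}\!\left(\frac{1}{R_f} - 1\right)$$

linearizes retention: $R_M$ is 0 at $R_f = 0.5$, positive for stronger
retention, and additive in the free-energy contributions of the
stationary-phase chemistry, which is what makes it suitable as a linear
regressor. `rf_to_rm()` and `rm_to_rf()` implement the transform and its
inverse; they are mutual inverses to $10^{-12}$ over the working range.

The plates come in eight variants: an unimpregnated control `C` and
seven biochromatographic models `S1`–`S7` impregnated with analogues of
serotonin-receptor binding-site amino acids (propionic acid ≈ aspartate,
ethylbenzene ≈ phenylalanine, 4-ethylphenol ≈ tyrosine, propionamide ≈
asparagine, and three mixtures adding ethanol / isopropyl alcohol as
serine / threonine stand-ins). Two developing-solvent systems `DS_A`
(acetonitrile/methanol/buffer) and `DS_B` (adding methylene chloride)
give two independent retention tables.

`derive_features()` computes the interaction variables

$$\mathrm{C{-}S_k} = R_M(C) - R_M(S_k), \qquad
  \mathrm{S_k/C} = \frac{R_M(S_k)}{R_M(C)},$$

the difference being the specific retention shift caused by the
amino-acid analogue and the ratio the same shift on a relative scale.

**Orientation of the difference.** Nothing in the raw data forces
control-minus-model rather than the reverse. The package fixes the
orientation by requiring that the fitted two-variable agonist model
reproduce the observed/predicted table of the source data: with
$C - S_k$, compound 1 (tiapride) is predicted at pD$_2$ 7.27 against an
observed 7.97, agreeing with the published table to a unit in the last
digit; the opposite orientation does not come close. This check is part
of the test suite.

**Near-zero controls.** Three compounds have $|R_M(C)|$ close to zero,
where the ratio variable blows up. Ratios with $|R_M(C)| < 10^{-9}$ are
carried as explicit missing values rather than ±∞; using such a feature
as a model term raises an error at dataset-assembly time rather than
silently dropping compounds. Difference features are unaffected.

## Data and assembly

The packaged tables cover 20 compounds: activities (pK$_i$, $n=19$;
pD$_2$, $n=13$; pA$_2$, $n=16$ — the gaps are real, not errors),
complete retention tables for both phases, and 19 calculated molecular
descriptors. Missing activities are encoded by an em dash in the
fixture files, never by zero, and the typographic minus of the source
tables is normalized at read time. Compound names are metadata; all
joins are by integer id. `assemble_dataset()` restricts rows to
compounds with a non-missing response, validates every term against the
descriptor set and the derived-feature registry of the requested phase,
and preserves the given column order, so a fit is reproducible from the
call alone.

## Regression and statistics

`fit_qsar()` is ordinary least squares with intercept via `lm()`, and
reports the classical suite:
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$,
$R^2_\mathrm{adj} = 1 - (1-R^2)\frac{n-1}{n-p-1}$,
$F = \frac{R^2/p}{(1-R^2)/(n-p-1)}$,
$s = \sqrt{\mathrm{RSS}/(n-p-1)}$, with the overall $p$ from the $F$
distribution. $R$ is reported as $+\sqrt{R^2}$, the multiple
correlation, which is why it is always positive. The test suite checks
the fitted coefficients against an independent normal-equations solve
and the internal consistency of the statistics to $10^{-8}$.

**Collinearity filter.** Before selection, candidate predictors are
pruned so that no surviving pair has $|r| > 0.5$ over the modelling
subset. The procedure is deterministic: the most-correlated offending
pair is resolved first, dropping the member with the smaller $|r|$
against the response; exact ties keep the earlier candidate in the
supplied order. The threshold 0.5 is deliberately strict — with 13–19
compounds, even moderately correlated predictors make coefficients
unstable.

**Stepwise selection.** Forward selection with backward checks: the
candidate with the smallest partial-$F$ p-value below
$\alpha_\mathrm{enter} = 0.05$ enters; after each entry, terms whose
p-value has drifted above $\alpha_\mathrm{remove} = 0.10$ leave again.
The defaults are conventional and reproduce the published model sizes
on the packaged data; both levels are arguments. The term cap defaults
to $\lfloor n/5 \rfloor + 1$, at most 4 — at $n = 13$ that allows three
terms, reflecting the usual one-predictor-per-five-compounds rule of
thumb. Note that per-term entry testing controls the per-candidate, not
the family-wise, error: with five null candidates, some candidate
enters in roughly $1 - 0.95^5 \approx 23\%$ of datasets. The test suite
measures exactly that behaviour (≈0.78 empty-selection rate on pure
noise) rather than pretending the procedure is more conservative than
it is.

## Cross-validation

`loo_crossval()` refits the model — term set frozen, coefficients
re-estimated — on each leave-one-out subset and predicts the held-out
compound:

$$\mathrm{PRESS} = \sum_i (y_i - \hat y_{(i)})^2, \qquad
  Q^2 = 1 - \frac{\mathrm{PRESS}}{\mathrm{TSS}},$$

with TSS about the full-sample mean. Freezing the term set matches the
purpose of validating a *final* equation; re-selecting per fold would
validate the selection procedure instead. For OLS the explicit refit
equals the hat-matrix identity
$\mathrm{PRESS} = \sum_i \left(e_i/(1-h_{ii})\right)^2$; the package
keeps the explicit refit as the implementation and uses the identity as
an independent oracle in the tests (agreement to $10^{-9}$ over random
datasets). Because $|e_i/(1-h_{ii})| \ge |e_i|$, PRESS ≥ RSS and hence
$Q^2 \le R^2$ always; this is asserted on every fit the suite touches.

`lno_crossval()` generalizes to random groups of size $N$ (last group
smaller): each repetition partitions the compounds uniformly at random
(seeded), and the reported $Q^2_\mathrm{LNO}$ is the mean over
repetitions — with 13–19 compounds a single partition is far too noisy
to report. Defaults $N = 3$ and 1000 repetitions; $N = 1$ reduces to
leave-one-out exactly, whatever the seed, which the suite asserts. All
randomness goes through an explicit seed argument and leaves the global
RNG untouched.

**Dispersion statistics.** $S_\mathrm{PRESS} = \sqrt{\mathrm{PRESS}/n}$
reproduces all three published values exactly from the published PRESS
and $n$, so that formula is adopted. The published SDEP values match
neither $\sqrt{\mathrm{PRESS}/n}$ nor any degrees-of-freedom variant we
could recover, so `SDEP` is reported with the $\sqrt{\mathrm{PRESS}/n}$
formula and a $\sqrt{\mathrm{PRESS}/(n-p-1)}$ alternative is written
alongside as `SDEP_df`; neither is used as an acceptance quantity.

**Reliability battery.** A model passes if $R^2 > 0.6$,
$Q^2_\mathrm{LOO} > 0.5$, $R^2 \ge Q^2_\mathrm{LOO}$,
$R^2 \ge Q^2_\mathrm{LNO}$, $|Q^2_\mathrm{LOO} - Q^2_\mathrm{LNO}| \le
0.1$ and $R^2_\mathrm{adj} < R^2$. The 0.1 agreement tolerance
operationalizes "approximately equal"; the observed gaps on the three
final models are 0.02–0.07, and the tolerance is an argument.

## The synthetic-data generator

`simulate_tables()` exists so every stage is testable without the study
tables and so parameter recovery can be asserted against a known truth.
It draws predictors from a Gaussian copula with a requested correlation
matrix, maps them to normal or bounded-uniform marginals at requested
location/scale, builds the response as the true linear predictor plus
Gaussian noise, and *encodes* feature terms back into a retention table
(control RM uniform on $[-0.5, 0.55]$, $S_k = C - x$) so that the full
pipeline — file round-trip, feature derivation, assembly — runs on
synthetic data unchanged.

The defaults mirror the study conditions: 20 compounds, pD$_2$
generated from `C-S4` and `C-S5` with coefficients
$(7.69, -15.89, 7.97)$, feature scale 0.05 (the observed spread of the
difference variables), feature correlation 0.48, noise SD 0.37 (the
fitted residual error), and the observed missing-activity pattern
(5%/35%/20%). What the generator does **not** emulate: the physics of
plate impregnation, systematic measurement error in densitometry,
non-Gaussian activity noise, and any structure–retention relationship —
retention columns other than the encoded ones are unstructured noise
around the control. Passing recovery tests therefore demonstrates the
statistical machinery, not the chromatographic science.

## Problem sizes and runtime

All study computations are desk-scale: $n \le 20$ and at most four
predictors, so a full fit-plus-LOO runs in well under a second. The
suite uses 1000 leave-3-out repetitions where a published value is
compared, 25–50 repetitions in structural tests, 50 random datasets for
the oracle-equivalence property, 200 replicates for selection-level
estimates and 25 replicates per point of the noise grid — sizes chosen
to keep Monte-Carlo error comfortably below the asserted tolerances.

## Known limitations

* The packaged retention values carry 3 decimal places. Statistics that
  amplify small input changes — the variance ratio $F$
  ($\partial F/\partial R^2 \approx 200$ for the agonist model) and
  regression coefficients on features of spread ~0.05 — can differ from
  the source print by more than their last printed digit even when the
  fit is exactly right; $R^2$, $s$, PRESS, $Q^2$ and the predictions are
  stable. The reproduction report therefore always writes absolute
  differences rather than claiming digit-exact agreement.
* The three descriptor-only model structures in the registry (eq3, eq8,
  eq13) do not reproduce their published $R^2$ from the packaged
  descriptor table (recomputed 0.40/0.53/0.57 against published
  0.69/0.57/0.69), although the same table reproduces the published
  descriptor correlation matrix and the mixed
  chromatography-plus-descriptor models closely. The discrepancy is in
  the source data, not the fitting; the comparison file reports it as
  found.
* The published four-predictor binding-affinity equation prints an HD
  coefficient (−12.96) that is inconsistent with its own predicted
  activities; the package reports its own fitted coefficients (HD
  ≈ −0.34, which does reproduce the published predictions) and treats
  only that model's fit statistics as comparable.
* With $\le 20$ compounds, external validation is impossible by
  construction; leave-one-out and leave-N-out measure interpolation
  within the chemical series, and nothing here estimates an
  applicability domain.
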