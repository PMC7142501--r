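---
title: "Methods: herbage energy evaluation from digestibility trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: herbage energy evaluation from digestibility trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbenergy)
```

## The problem

A digestibility trial feeds fresh-cut herbage to housed sheep at the
maintenance level and measures, per animal, the apparent digestibility
of dry matter, organic matter, nitrogen, fibre fractions and gross
energy, together with the energy lost in faeces, urine and methane.
From these one obtains the digestible energy (DE = GE − fecal energy)
and metabolizable energy (ME = DE − urine energy − methane energy)
concentration of the herbage, both in MJ/kg DM. Because full balance
trials are slow and costly, practice relies on linear prediction
equations that estimate DE or ME from digestibility coefficients and/or
chemical composition. This package implements the whole evaluation
cycle: a registry of published equations, an engine to develop new
ones, a validation harness to score them, and a synthetic trial
generator that provides ground truth.

## Units and record layout

One record is one sheep × trial observation. Internally all mass
fractions are kg/kg DM, digestibilities are fractions, and energies are
MJ/kg DM; delimited files use the conventional g/kg columns and are
converted at the I/O boundary (`read_trial_records()`,
`write_trial_records()`). Equation terms carry explicit units and
evaluation converts each predictor before multiplying, so registries
whose footnotes use g/kg or % DM coexist with fraction-based ones.

Two derivation conventions deserve note:

* **Crude protein** is 6.25 × N. The reference study's printed N
  column (35–124 g/kg DM) is implausibly high for true nitrogen — at
  face value it implies up to 78% crude protein — and is almost
  certainly already CP. We store it as printed under `n` and apply no
  silent rescaling; consequences are handled per consumer (below).
* **Total digestible nutrients.** `tdcp` and `tdndf` are concentration
  × digestibility on the g/kg DM scale (`tdcp = N[g/kg] × ND`). The
  published table that uses these predictors nominally labels them
  "g/100 g DM", but subtracting its DE and ME forms shows the fitted
  coefficients are only consistent with a g/kg-scale pair summing to
  roughly 485 at the mean record — exactly what N[g/kg] × ND (35.6)
  plus NDF[g/kg] × NDFD (451) give. The g/kg derivation is therefore
  the one the package uses; with the 6.25-factor "g/100 g" derivation
  those equations would evaluate several MJ/kg below the plausible DE
  range.

## The equation registry

Registries are tibbles with one row per equation and a list column of
terms (predictor, coefficient, SE, unit, source column). The built-ins
freeze the published tables of the source study — univariate
digestibility forms, multivariate digestibility + composition forms,
ME-from-DE forms, total-digestible-nutrient forms, the two-thirds-data
refits used for internal validation, and thirteen literature equations
— at full printed precision, with MD5 checksums asserted in the test
suite. `serialize_registry()`/`parse_registry()` give a lossless JSON
round trip for user-authored registries.

Three transcription policies apply where the printed source is
internally inconsistent:

* A lost minus sign is restored only where the publication's own
  arithmetic proves it: the ME/GE-from-DOMD intercept (its published
  refit twin and validation means are negative) and the NDF slope of
  one literature equation (no unit makes a positive slope reproduce the
  published predicted mean).
* Rows that, as printed, evaluate outside the published response range
  at the published mean record are kept verbatim but flagged
  `advisory:` in their `note`; range assertions exclude them.
* Literature equations get a per-row unit resolution chosen so that
  evaluation at the published mean record lands nearest the published
  predicted mean. For three equations taking crude protein this means
  reading CP from the printed N column directly (consistent with that
  column already being CP); one equation resolves to % DM with
  CP = 6.25 × N. Each row's `note` documents the choice.

## Model development

Equations are developed as linear mixed models: fixed terms from the
registry vocabulary, candidate random intercepts for sheep, season and
year, estimated by REML (`lme4::lmer`). The package reports, per fit,
coefficients with SEs, Wald statistics `(b̂/SE)²` referred to χ²₁,
variance components, the REML deviance (−2 restricted log-likelihood),
and R² as the squared Pearson correlation between response and
fixed-effect fitted values (0 when fitted values are constant, 1 for a
saturated fit).

`develop_equation()` reproduces the study's "random effects …
removed" procedure explicitly: fit with all candidates, then backward
eliminate. At each step the component whose removal changes the
deviance least is dropped if the χ² test (df = number of components
removed) is non-significant at α = 0.05, and the model is refitted;
the surviving fixed coefficients become a registry row with source
`"refit"`. The χ² reference ignores the boundary-at-zero problem, so
the test is conservative — the null simulation in the test suite
verifies a type-I rate below nominal.

When every random term is dropped, the fit is ordinary least squares
and its restricted deviance is computed in closed form,

`d = log|XᵀX| + (n − p)·(1 + log(2π·RSS/(n − p)))`,

which equals `lme4::REMLcrit` exactly at zero variance (verified in
the tests), so mixed-versus-fixed deviance comparisons are on one
scale. Degenerate inputs are handled without special casing: an
exactly collinear response yields R² = 1 and zero SEs; rank-deficient
designs are refused naming the collinear columns; convergence and
singular-fit checks at the boundary are silenced because a zero
variance estimate is a legitimate outcome here.

Numerical tolerances: the deviance-ordering invariant (full model ≤
any nested reduction) is asserted to 1e−6; fixed-effect invariance to
record/predictor reordering to 1e−5 (optimizer path dependence);
exact-recovery tests to 1e−6.

## Validation

The harness follows the mean-square-prediction-error technique.
`MSPE = (1/n)Σ(P−A)²`; the mean prediction error is implemented as
`MPE = √MSPE / mean(A)`. The source text prints MPE without the
radical, but the square-root form is the standard definition in the
validation literature it cites, is the only form that is dimensionless
and scale-invariant, and is the only one consistent with the printed
MPE magnitudes (0.01–0.08) against residual SDs of 0.6–1.0 MJ/kg. This
choice is deliberate and surfaced here prominently.

Lin's concordance uses population (1/n) moments, the standard
definition; with that convention `|R_c| ≤ |r|` holds exactly, with
equality precisely when the two series share mean and variance. The
"SE" column of the validation reports is the standard error of the
paired differences, the least ambiguous reading of the published
column. Display rounding follows the published tables: MPE and
ratio-scale means to 3 decimals, energy concentrations to 2, fold
ratios to 1.

`split_trial_data()` draws the 2/3–1/3 internal-validation split. The
source does not state how its split was drawn; the default here is a
seeded, trial-stratified draw (each 6-sheep trial contributes 4
development and 2 validation animals), which preserves seasonal
balance in both subsets. Fraction and seed are configurable.

## The synthetic generator

`generate_trial_data()` emulates the study conditions: 11 trials (two
June, five August, four December, 2011–2016) of 6 sheep. Season
profiles (`seasonal_profiles("qtp_default")`) are anchored to the
published per-variable extremes: June herbage is young (N ≈ 118 g/kg,
DMD ≈ 0.78), December herbage dormant (N ≈ 43 g/kg, DMD ≈ 0.56,
fresh-DM ≈ 790 g/kg), with design-weighted grand means matching the
published means. A single latent trial-level quality score shifts
composition and digestibility coherently (+ for N, EE, digestibility;
− for fibre, ash, fresh DM), reproducing the documented seasonal
confounding from marginal information alone — the published data give
no covariance matrix, and one latent factor is the most parsimonious
structure that yields the right sign pattern (digestibility rising
with N, falling with NDF).

The energy chain is built exactly: DE = GED × GE; urine and methane
fractions of DE are drawn per sheep around 4.8% and 9.5% (so
ME/DE ≈ 0.86, the value implied by the published ME-from-DE regression
at the mean DE — the study reports no direct partition values);
ME = DE − urine − methane, hence ME < DE and
GE = fecal + urine + methane + ME to machine precision. Measurement
noise is then added to the *recorded* GED and DOMD columns only,
mimicking the small DE/GE-versus-GED and DOMD-versus-OMD(1−ash)
discrepancies real assay data show. Truncated-normal draws keep every
fraction inside plausibility bounds; truncation is a documented
deviation from exact normality and the mean-convergence test allows a
small bias floor for it.

Two deliberate departures from the study's literal design:

* The study used 66 distinct sheep (6 per trial), under which a
  between-sheep variance component is confounded with the residual.
  The generator reuses a stable flock of six sheep identities across
  trials so that the sheep component its configuration exposes is
  estimable.
* Methane was measured only in the study's first year and extrapolated;
  how is unstated, so the generator applies the energy partition
  uniformly across trials.

`generate_from_equation()` overwrites a response with a known
equation's value plus Gaussian noise and configurable
sheep/season/year intercept variances — the parameter-recovery
harness. With zero noise and zero variances a refit recovers the
generating coefficients to 1e−6.

What passing tests on this generator do *not* show: real herbage data
have assay error in every column, non-normal seasonal mixtures,
sheep-by-season interactions and intake-level effects that the single
latent factor does not represent. Recovery results certify the fitting
and validation machinery, not field performance of any equation.

## Problem sizes

The simulation-based checks use 60 replicates for the season-effect
power check, 200 for the null conservatism of the deviance test, 200
per form for coefficient recovery (within 3 reported SEs, ≥95%
required), and 1000 for the Wald type-I rate (required inside
[0.03, 0.07] at nominal 0.05); the acceptance script runs the full
39-form study replica once and a 100-replicate recovery for the
ME-from-DE form. These sizes give Monte-Carlo error comfortably inside
the asserted margins.

## Known limitations

* The registry reproduces printed coefficients; where the source
  tables are internally inconsistent (three advisory rows) no
  correction is attempted beyond the documented sign restorations.
* No MSPE decomposition into bias/slope/random components, no
  external-dataset validation, and no model selection over fixed
  terms: predictor sets are taken as given.
* Only random intercepts are supported — no heteroscedastic or
  correlated-residual structures; season and year enter as separate
  factors by default (the source is silent on whether they were
  combined into one trial factor; both are expressible).
* Coefficient SEs from other REML implementations can differ in the
  third decimal on identical data owing to parameterization; tests
  compare against properties, not against another package's output.
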