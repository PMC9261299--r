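---
title: "Movement-based biological age: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based biological age: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most biological-age clocks (DNA methylation, blood biomarkers, metabolomics)
require a tissue sample. Movement does not: a week of minute-level
accelerometer counts from a wearable device is cheap, non-invasive and
already collected at population scale — the NHANES 2003–2004 and 2005–2006
cycles asked thousands of participants to wear an ActiGraph device on the
thigh for seven days. `actage` implements a complete pipeline that

1. reduces each participant's 7 × 1440 grid of minute intensity counts to
   336 hourly summary features,
2. trains a random-forest regressor of chronological age on those features,
3. converts predictions into a *deltaAge* aging-acceleration statistic via a
   peer-median normalization,
4. relates deltaAge-derived aging classes to linked mortality, and
5. screens dietary components and prescription drugs for association with
   decelerated aging.

Because the real survey tables cannot be redistributed, the package ships a
synthetic-cohort generator that emulates all five tables with planted,
configurable effects; every pipeline stage is exercised against it.

## Feature construction and quality control

A week is retained only if the device was calibrated, all seven days are
complete (1440 minutes each), every day has at least 10% of minutes with a
strictly positive count (≥ 144 of 1440, evaluated per day), and the
participant is an adult (≥ 18 years). The 10% rule is deliberately read
per-day rather than per-week; the exclusion log (`qc_exclusions()`) records
which rule fired for every dropped week so the alternative reading remains
auditable.

Each retained week is summarized per (day, hour) cell by the **maximum**
(capturing peak vigor) and the **sample variance** (capturing diversity of
movement) of the 60 minute counts, yielding 7 × 24 × 2 = 336 features.
Sample variance (denominator *n* − 1) is used and documented so the trained
model is reproducible; population variance differs by the constant factor
59/60 and would not change feature ranks. Hours are clock hours of the wear
day (minute-of-day `[60h, 60h + 60)`), not hours since wear start.

## The age model

A random-forest regressor (500 trees, `mtry = p/3 = 112`, minimum node size
5) is trained on features centered and scaled with training-set statistics;
those statistics are frozen into the model object and reapplied unchanged to
any prediction data, so no information leaks from validation data into the
standardization. The train/test split (70/30) is stratified on age-quantile
bins so both subsets cover the full 18–85+ range. No pre-installed R random
forest was available in the build environment, so the package carries a
compact CART forest in C++ (bootstrap resampling, per-node feature
subsampling, variance-reduction splits, out-of-bag error); its behaviour is
pinned by tests against closed-form and planted-signal oracles
(constant-target reproduction, null-feature correlation bounds,
planted-feature importance ranking, duplicate-feature importance dilution).

Feature importance is the percent increase in held-out MSE when one
feature's column is permuted (averaged over 10 permutations). The classic
implementation computes this out-of-bag; the held-out variant was chosen
because it is model-agnostic and uses exactly the data on which the model is
evaluated. Both satisfy the same "%IncMSE" contract.

## Normalization and deltaAge

Raw forest predictions compress the age range (young people predicted too
old, old people too young — an inherent property of averaging regressors).
The correction divides each raw prediction by the median raw prediction of
*peers of similar chronological age* and multiplies by the participant's own
chronological age:

```
age_pred_norm_i = age_pred_raw_i / median({age_pred_raw_j : |age_j - age_i| <= w}) * age_i
deltaAge_i      = age_pred_norm_i - age_i
```

Positive deltaAge means accelerated aging. The default peer window is
`w = 0`: peers are participants of the *same* integer chronological age
(the participant included). This choice makes the per-age median deltaAge
exactly zero — a structural identity the acceptance suite asserts — whereas
any sliding window (`w > 0`, available as an option) only approximates it
near the edges of the age range. With dozens of participants per integer
age in survey-sized cohorts, same-age peer sets are comfortably large.

A note on sign conventions: the deltaAge definition used here (normalized
predicted minus chronological; positive = accelerated) is the one consistent
with "high deltaAge ⇒ more likely deceased", and is applied throughout.

## Mortality analysis

Aging classes are quartiles of deltaAge among participants aged ≥ 60
(linear-interpolation quantiles; ties at a cutpoint go to the extreme class
so the extreme classes are never empty): top quartile *accelerated*, bottom
quartile *decelerated*, middle half *normal*. Death proportions across the
three classes are compared with a 3-sample test for equality of proportions
without continuity correction — equivalently a Pearson chi-square on the
3 × 2 table with df = 2, which the test suite verifies against a hand-written
oracle. Participants with unknown vital status are excluded and counted.
Per-decade and per-cause comparisons use two-sample Student's t-tests
(equal variances, as printed; a Welch switch exists). Decade bins are
half-open — `[18,30), [30,40), …, [80,85+]` — with `[30,40)` the
"4th decade of life".

## Nutrient and drug screens

**Nutrients.** For each dietary component and each decade bin, the Pearson
correlation between daily intake and deltaAge is computed (≥ 3 nonmissing
intakes required per cell; zero-variance cells are left missing, never
imputed). BH correction is applied *within each bin* across nutrients — the
correction scope is not dictated by the method statement, so it is a config
option (`bh_scope`). Correlation profiles across bins are clustered with
hierarchical clustering (Euclidean distance, complete linkage, `cutree` at
k = 5). A supplementary extreme-group contrast compares intake between
participants with deltaAge < −10 and > +10 years by Student's t-test.

**Drugs.** The screen restricts to ages ≥ 70 (the 85+ top-code included).
For each drug, users' deltaAges are compared against *all* participants in
the subset — users included, exactly as the method is usually stated; this
is conservative because the users sit in both samples (a users-vs-nonusers
switch exists). The two-sample Kolmogorov–Smirnov test is used with its
asymptotic p-value (the user sample appears in both samples, so ties are
structural and an exact small-sample p is unavailable). The rank score is
`log10(p) × sign(median shift)`; since `log10(p) < 0`, *decelerating* drugs
(negative median shift) receive *positive* scores, and "most decelerating"
means the largest rank score. Each participant contributes their deltaAge
once per distinct drug (salt forms such as "DOXAZOSIN MESYLATE" are
collapsed to the parent compound on read).

## The synthetic cohort

One latent variable ties every planted effect together: a per-person
frailty `f ~ N(0, 5)` years, which shifts the *effective movement age* to
`age + f` (plus a smaller age-independent "lifestyle" offset,
`N(0, 2)` years, that blurs movement without feeding mortality). The
generator then draws:

* **Activity** — per minute, a zero-inflated negative binomial: the
  probability of an active minute follows a circadian profile (near-zero at
  night, peaking through the day) and the active-minute mean count decays
  with effective age from its age-18 level to 20% of it at effective age
  95, afternoon hours decaying fastest. This reproduces the qualitative
  pattern that old participants show lower hourly maxima and variance,
  especially in the afternoon, which is exactly where the model's
  importance concentrates.
* **Mortality** — death at follow-up with probability
  `plogis(-8.5 + 0.105 × (age + f))`, giving death proportions around
  0.1–0.6 between ages 60 and 85+, and a respiratory cause group whose
  weight grows with frailty.
* **Diet** — log-normal intakes; planted nutrients mix in `−f` with a
  per-decade weight profile. The default plants fiber (and, weaker,
  magnesium) with a profile peaking in the 50–59 bin, mirroring the
  late-peaking cluster the method is designed to detect.
* **Prescriptions** — age-weighted usage of 30 common drugs; exactly one
  planted geroprotector (doxazosin, 2% usage among 70+) whose users have
  `f` reduced by 6 years *before* any downstream table is drawn, so the
  drug's signature propagates through movement, mortality and the screen.

Each table draws from its own RNG stream derived from the master seed, so
adding or regenerating one table never perturbs the others, and identical
seeds give byte-identical CSVs.

**What the generator does not emulate.** Real actigraphy is far noisier:
device non-wear, survey weighting, non-uniform age structure, seasonal and
weekday effects, and biological heterogeneity far beyond one latent frailty
dimension. Consequently the synthetic age signal is much cleaner than real
data (held-out r ≈ 0.96 versus ≈ 0.7–0.75 reported on real cohorts), and a
green recovery test establishes that the *pipeline machinery* is correct —
not that real-world effect sizes would be detectable at these sample sizes.
The planted nutrient correlation (≈ −0.4 at its peak bin) is likewise
stronger than the ≈ −0.18 seen in real data, chosen so that recovery is a
sharp pass/fail signal rather than a coin flip.

**Scale choices in the tests.** The default cohort is n = 1500
(model-building scale); the end-to-end drug-screen recovery runs at
n = 2505 — the size of the real validation cohort — because the screen's
power is set by the count of users among the 70+ subset (about 10–13 at
these settings, matching the n = 10 doxazosin users in the motivating
analysis). Recovery tests use 150–500 trees depending on what the assertion
measures; forest size beyond ~150 trees changes held-out correlations by
well under 0.01 on these cohorts, and the reduced sizes keep the whole
suite inside a desk-scale time budget.

**A caveat on latent-shift recovery.** Averaging regressors compress
individual deviations: on the default cohort the fitted slope of deltaAge
on true frailty is ≈ 0.4, so a −6-year latent shift surfaces as roughly
−2.5 years of deltaAge. With only ~10–13 drug users, their *baseline*
frailty luck (SD ≈ 5/√12 ≈ 1.4 years) is a material fraction of the
surfaced effect, and an unlucky user draw can mask the plant in an
end-to-end run. The multi-seed recovery guarantee is therefore stated at
the screen level (users' deltaAge itself shifted −6 years), while the
end-to-end generate→screen recovery is asserted at a fixed seed; the same
attenuation applies to real-data screens and is one reason such screens
rank rather than estimate effects.

## Numerical details and edge cases

* Quantiles everywhere are R's default type 7 (linear interpolation).
* Constant features at training time get scale 1 (with a warning) instead
  of dividing by zero.
* `r = ±1` correlation cells produce `p = 0`, which is clamped to the
  smallest positive double before BH adjustment (BH requires p ∈ (0, 1]).
* A peer median ≤ 0 of raw predictions aborts normalization as degenerate.
* Aging classes require ≥ 8 participants above the age threshold and a
  non-degenerate deltaAge distribution.
* Untestable cells (a decade bin with one death, an empty extreme group, a
  drug with no users in the subset) are flagged or omitted, never errors.

## Known limitations

* The movement-age signal may capture "patterns of life" (work schedules,
  habits) in addition to biological vitality; the pipeline measures
  association with mortality, not mechanism.
* The screens are associational. The package deliberately stops short of
  causal claims; dose–response and interaction modelling are out of scope.
* The KS comparison against the pooled population is conservative; the
  users-vs-nonusers switch gives slightly more power at the cost of
  matching the stated method less literally.
* Survey weights are not implemented; all statistics are unweighted.
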