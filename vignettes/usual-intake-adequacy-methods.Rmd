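---
title: "Estimating usual intake and the probability of dietary adequacy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual intake and the probability of dietary adequacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietadequacy)
```

This vignette documents the statistical models behind `dietadequacy`, the
assumptions they make, the package's own resolutions of genuinely open
design questions, and what validation on synthetic data does and does not
demonstrate.

## The measurement problem

A single 24-h recall measures one day of a child's diet, and day-to-day
variability in young children's intakes is large — typically larger than
the true differences between children. Classifying a child as "adequate"
or "inadequate" from one day would therefore be mostly noise. The pipeline
instead treats each child's *usual* (long-run average) intake as the
quantity of interest, estimated from 4–5 recalls per child within each
four-month age band, and evaluates adequacy probabilistically against the
requirement distribution of the child's age group.

A second measurement gap is breast milk: intake volume is not observable
in field studies. On breastfed child-days the pipeline assumes breast milk
fills the gap between the predicted energy requirement (per-kg FAO/WHO-style
coefficients × body weight; shipped as an editable YAML table because the
coefficients are data, not code) and the energy already eaten from
complementary foods, converted to grams at 0.63 kcal/g and to nutrients via
an editable mature-milk composition table. Days with no reported
breastfeeding contribute complementary foods only. Negative gaps (a child
who already exceeded the requirement from food) are floored at zero milk —
negative milk is meaningless, and flooring preserves `total = CF`. We do
not cap the share of energy from breast milk below 100 %: on a recall day
with no complementary food the whole requirement is attributed to milk.

## The usual-intake model

Within each site × age bin × nutrient cell with repeated child-days:

1. **Zero handling.** If any intake in the cell is zero, a constant
   `c = 1e-6` is added to every intake in the cell (and subtracted again
   after back-transformation). This keeps the power transform defined
   while leaving non-zero intakes essentially untouched.
2. **Box-Cox normalisation.** `g(x) = ((x+c)^λ − 1)/λ` (log at `λ = 0`).
   The power is selected by grid search over `λ ∈ [−2, 2]` in steps of
   0.01, maximising the profile log-likelihood of the *fixed-effects*
   model `g(x) ~ sex + weekday + month`. Selecting λ before the mixed
   model keeps the choice independent of random-effect convergence; the
   unit test cross-checks the criterion against `MASS::boxcox`. Ties on
   the grid resolve to the smallest maximising λ (`which.max`). Selection
   is per cell — the most granular reading of fitting "by age group and
   site" — so episodic nutrients may get different powers in different
   cells.
3. **Random-intercept model.** `g(x)_ij = X_ij β + b_i + ε_ij` with
   `b_i ~ N(0, σ²_b)` (between-child) and `ε_ij ~ N(0, σ²_w)`
   (within-child, day-to-day), fitted by REML through `lme4::lmer`.
   Weekday enters as a 7-level factor, month as 12-level, sex binary; no
   functional form is assumed. Covariates with a single observed level are
   dropped with a warning; negative variance estimates are truncated at
   zero by the estimator itself.
4. **Prediction and back-transformation.** Each child-day is predicted as
   BLUE + BLUP, `m_ij = X_ij β̂ + b̂_i`, where
   `b̂_i = k_i (ȳ_i − X̄_i β̂)` shrinks by
   `k_i = σ²_b / (σ²_b + σ²_w / n_i)`. The intake-scale value uses a
   second-order Taylor correction of the inverse transform,
   `x = g⁻¹(m) + ½ g⁻¹″(m) · v`, then subtracts `c` and floors at zero
   (the subtraction can produce tiny negatives). Predictions outside the
   image of the transform (`λm + 1 ≤ 0`) return zero with a warning
   counter. The child's estimated usual intake (EUI) is the mean of their
   back-transformed child-day predictions.

**Choice of the correction variance.** The correction variance `v` is the
variability the prediction does *not* carry:
`v_i = σ²_w + (1 − k_i) σ²_b`. Using the within-person variance alone is
common, but it is incomplete for shrunken predictions: the BLUP carries
only a fraction `k_i` of the between-child variance, and omitting the
remainder leaves the back-transformed mean ≈ 2.5 % below the observed mean
under realistic variance ratios (σ²_w = 0.25, 4 recalls/child). With the
conditional-variance form the recovered mean sits within ~1 % of the
observed mean (the residual gap is the third-order Taylor remainder). At
`λ = 1` the inverse is affine and the correction is exactly zero; at
`σ²_b = 0` it reduces to the within-only form.

**Unstable cells.** Cells with fewer than 10 children or a median below 2
recalls per child are not identifiable for the variance decomposition;
they fall back to observed per-child means and are flagged `unstable` in
every downstream table, rather than failing or silently extrapolating.

## Probability of adequacy

PA is the mass of the requirement distribution below the EUI; it is a
property of the *requirement's* distribution across children, not a
confidence statement about the estimate. Three requirement kinds are
supported:

- **Normal** from published RNI and CV: `EAR = RNI/(1 + 2 CV)`,
  `SD = CV · EAR` (the RNI = EAR + 2 SD convention), `PA = Φ((EUI−EAR)/SD)`.
- **Tabulated quantiles** for iron, whose requirement distribution in
  these ages is strongly skewed. Tabulated intakes are scaled by
  (reference bioavailability / 5 %) — all these diets are treated as 5 %
  iron bioavailability — and PA is monotone piecewise-linear interpolation
  of percentile against scaled intake, clamped to 0/1 outside the table
  rather than extrapolated. The shipped grid is a *synthetic* lognormal
  approximation anchored at the published EAR (median) and RNI (97.5th
  percentile) for 9–12 months and 1–3 years; it is explicitly an editable
  placeholder for the authoritative tables.
- **AI threshold** for vitamin E at 9–12 months, where no EAR exists:
  PA is 1 at or above the AI (boundary inclusive) and 0 below.

**Zinc bioavailability.** The child-period mean phytate:zinc molar ratio
(molar masses 660, 65.38, 55.845 g/mol for phytate, zinc, iron —
configurable) selects the requirement class: > 15 low, 5–15 moderate
(closed interval, so exactly 15 and exactly 5 are moderate), < 5 high.
Ratios are computed on the complementary-food intakes: phytate binds the
minerals ingested with it in food, and breast-milk zinc — phytate-free and
highly available — should not dilute the classification of the diet.
Because the source studies' diets were only low/moderate, no high-class
EAR is printed there; we ship the published high-bioavailability
requirement values so the class is still usable. Days with zero mineral
intake have an undefined ratio and are excluded from the period mean with
a log entry. Iron is always treated as low bioavailability (the
phytate:iron classification threshold of 1 is exceeded essentially
everywhere in such diets); the iron ratio is still computed and reported.

MPA is the exact arithmetic mean of the fourteen PA values; the nutrient
set is configurable (one source summary counts thirteen, but the analysis
itself tracks fourteen, which is what we implement). Nutrient densities
per 100 kcal use each child's *observed* mean complementary-food intakes,
not EUIs, matching their descriptive role. Summary tables use the
median-unbiased quantile definition (type 8), stated here because the
choice is not standardised across software.

## The synthetic-study generator

The generator is first-class, tested code: it is the only way to validate
the pipeline absent public raw data. It emulates: staggered monthly
enrolment over a year; per-child logistic breastfeeding-cessation ages
(median 18 months, scale 2.5 by default, no relactation); weights growing
~0.17 kg/month from a 9-month baseline of 8.9 kg; daily intakes built on
the transformed scale as child mean + day deviation (configurable σ²_b,
σ²_w or CVs; transformed-scale variances from CVs use `log(1+cv²)` at
λ = 0 and a delta-method approximation otherwise), multiplied by weekend
(+5 %) and sinusoidal seasonal (±5 %) factors; episodic zero days for
vitamins A/B12/D (probabilities 0.10/0.15/0.20), which exercise the
zero-shift branch; per-bin multipliers (0.75, 0.95, 1.10, 1.20) emulating
growing complementary-food quantities; and diet scenarios placing the
phytate:zinc ratio distribution either above the low-bioavailability
threshold (lognormal day ratios, median 30) or inside the moderate band
(median 8), with `mixed` assigning half the children to each. Default
geometric-mean intakes sit near or below the 1–3-year EARs, as is typical
of complementary diets in low-resource settings, so adequacy is
informative rather than saturated.

Children are simulated from substreams keyed by a stable hash of the child
id and the seed, so enlarging a cohort never perturbs existing children.
The food composition table uses single-nutrient *marker foods*, making the
recall ↔ FCT join exactly invertible; this is deliberately unrealistic
(real foods carry correlated nutrient bundles) and means the generator
does not test robustness to composition error, only to sampling
variability. Ground truth stores each child's true usual intake — the
analytic long-run day mean including noise, calendar factors and zero
days (calendar factors averaged uniformly, a <1 % approximation) — plus
the analytic PA/MPA of those true intakes under the shipped requirements.

## Validation scope and known limitations

The packaged validation (test suite and `scripts/acceptance.R`) uses a
500-child, 4-recall single-bin study at σ²_b = 0.09, σ²_w = 0.25 on the
log scale for recovery checks; a 60-child fully-followed cohort breastfed
essentially throughout for the breast-milk and sensitivity-mode checks;
and 200-child single-bin scenario studies for the bioavailability
extremes. These sizes give Monte-Carlo noise well below the tolerances
tested while keeping the default run under a few minutes.

What passing shows — and does not:

- Variance components are recovered within a few percent, and on balanced
  designs the REML fit coincides with the closed-form one-way ANOVA
  estimator to numerical precision. This validates the estimator, not the
  model: real intake data need not be Box-Cox normal with a pure random
  intercept.
- The bias-corrected back-transformation recovers the observed mean within
  ~1 %. The *distribution* of EUIs is, by design, narrower than the true
  usual-intake distribution: BLUP shrinkage trades tail accuracy for
  child-level precision, so EUI-based population percentiles are
  conservative (outer percentiles pulled toward the centre by roughly
  `1 − sqrt(k)`), and the rank correlation between EUI and truth is capped
  at `corr(ȳ_i, b_i) = sqrt(σ²_b/(σ²_b + σ²_w/n))` ≈ 0.77 at these
  variances with n = 4 recalls — no estimator can exceed this from the
  same data. More recalls per child, not a better estimator, is the only
  way up.
- The energy closure and classification checks are exact by construction
  and guard against regressions, not against mis-specified energy
  requirement tables.
- Percent of days breastfed is computed from recall-day flags in the
  summaries; with surveillance-style daily flags the same function applies
  to the full window.

The shipped requirement, milk-composition and energy tables are sensible
editable defaults, not authoritative reproductions; analyses intended for
publication should substitute the study's own tables. Two-part
episodic-consumption models (probability × amount) are out of scope — the
zero-shift constant plus single-part model is the implemented approach.
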