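# dietadequacy

Estimating the usual micronutrient intake and the probability of dietary
adequacy of infants and young children (9–24 months) from repeated 24-h
dietary recalls.

In low-resource settings, complementary feeding is the period when growth
faltering emerges, and quantifying what children actually eat — and whether
it can meet their nutrient requirements — requires more than a single recall
per child: day-to-day variability must be separated from true between-child
differences, and breast-milk intake, which is rarely measured, must be
accounted for. `dietadequacy` implements that full analysis pipeline for
epidemiologists and nutrition researchers working with longitudinal recall
data and a food composition table, and ships a synthetic-study generator
with known ground truth so every stage can be validated end to end.

## The method

Given a long-format recall table (one row per food per child-day) and a food
composition table per 100 g, the pipeline:

1. **Joins recalls to composition**: complementary-food (CF) intake on each
   child-day is `Σ amount_g/100 × per_100g` for energy, fourteen
   micronutrients (thiamine, riboflavin, niacin, B6, folate, B12, vitamins
   A, C, D, E, Ca, Mg, Fe, Zn) and phytate.
2. **Imputes breast milk by the energy gap**: on each breastfed child-day,
   milk is assumed to fill the gap to the predicted energy requirement
   (FAO/WHO-style, sex × age × weight):
   `bm_grams = max(0, requirement − CF energy) / 0.63 kcal/g`, with milk
   nutrients proportional to grams. Total intake = CF + breast milk.
3. **Estimates usual intake**: within each site × age bin (9–12, 13–16,
   17–20, 21–24 months) and nutrient, intakes are Box-Cox transformed
   (`g(x) = ((x+c)^λ − 1)/λ`, λ chosen by profile likelihood, `c = 1e-6`
   when the cell contains zeros) and modelled with a random intercept per
   child: `g(x)_ij = Xβ + b_i + ε_ij`, `b_i ~ N(0, σ²_b)`,
   `ε ~ N(0, σ²_w)`, with sex, weekday and month as covariates (REML via
   lme4). Each child-day is predicted as BLUE + BLUP and back-transformed
   with a second-order bias correction; the mean over a child's days is
   their estimated usual intake (EUI).
4. **Computes adequacy**: the probability of adequacy (PA) of a nutrient is
   the mass of its requirement distribution below the EUI —
   `Φ((EUI − EAR)/SD)` with `EAR = RNI/(1 + 2·CV)` for normal requirements,
   a tabulated quantile distribution scaled to 5 % bioavailability for
   iron, an adequate-intake step for vitamin E at 9–12 months, and
   class-specific EAR/SD for zinc, where the class (high/moderate/low
   bioavailability) comes from the child-period mean phytate:zinc molar
   ratio (> 15 low, 5–15 moderate). The mean PA (MPA) across the fourteen
   nutrients summarises overall dietary adequacy, and CF nutrient densities
   per 100 kcal describe diet quality independent of quantity.

A sensitivity mode (`cf_only = TRUE`) repeats the analysis on complementary
foods alone.

## Worked example

```r
library(dietadequacy)

study <- simulate_study(simulation_config(n_children = 40, seed = 2024))
res   <- run_pipeline(study$recalls, study$fct)

res$summaries$mpa
#> # A tibble: 4 × 6
#>   site_code age_bin n_children    q1 median    q3
#>   <chr>     <fct>        <int> <dbl>  <dbl> <dbl>
#> 1 SYN       9-12            40 0.436  0.558 0.627
#> 2 SYN       13-16           40 0.254  0.329 0.442
#> 3 SYN       17-20           40 0.299  0.366 0.433
#> 4 SYN       21-24           40 0.311  0.380 0.446
```

Median MPA is highest at 9–12 months (0.56) and drops at 13–16 months:
several EARs roughly double at 12 months while complementary-food amounts
rise only gradually, after which MPA recovers slowly — the age pattern this
class of analysis is designed to expose.

```r
res$summaries$energy[, c("age_bin", "cf_energy_median", "pct_energy_bm_median", "pct_days_bf_median")]
#> # A tibble: 4 × 4
#>   age_bin cf_energy_median pct_energy_bm_median pct_days_bf_median
#>   <fct>              <dbl>                <dbl>              <dbl>
#> 1 9-12                536.                32.3               100
#> 2 13-16               615.                21.6               100
#> 3 17-20               631.                 6.58               37.5
#> 4 21-24               709.                 0                   0
```

Complementary-food energy grows with age while the imputed share of energy
from breast milk declines from 32 % to 0 as children wean.

```r
f <- fit_usual_intake(res$child_days, nutrients = "zinc_mg")$fit[[1]]
glance(f)
#> # A tibble: 1 × 7
#>   lambda shift sigma2_between sigma2_within n_children n_days unstable
#>    <dbl> <dbl>          <dbl>         <dbl>      <int>  <int> <lgl>
#> 1 0.0200     0          0.106         0.228         40    160 FALSE
```

The selected Box-Cox power (~0) says zinc intakes are lognormal-like; the
variance components show day-to-day noise (0.23) about twice the
between-child variance (0.11), which is why repeated recalls and BLUP
shrinkage are needed before locating a child on the requirement
distribution.

`plot_pa()`, `plot_mpa()` and `plot_nutrient_density()` draw the standard
summary figures, and `inst/scripts/dietadequacy` exposes `simulate` and
`run` subcommands for shell use.

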