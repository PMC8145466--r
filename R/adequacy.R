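#' Molar masses used for phytate ratios
#'
#' Defaults: phytate 660 g/mol, zinc 65.38 g/mol, iron 55.845 g/mol. All are
#' configurable wherever a ratio is computed.
#' @return named numeric vector.
#' @export
default_molar_masses <- function() {
  c(phytate = 660, zinc = 65.38, iron = 55.845)
}

#' Phytate-to-mineral molar ratio
#'
#' `(phytate_mg / M_phytate) / (mineral_mg / M_mineral)`. High ratios mark
#' poor absorption of the mineral. Days with zero mineral intake have an
#' undefined ratio and return `NA` (callers exclude them from period means).
#'
#' @param phytate_mg phytate mass (mg).
#' @param mineral_mg mineral mass (mg).
#' @param mineral `"zinc"` or `"iron"`.
#' @param masses named molar masses, see [default_molar_masses()].
#' @return dimensionless molar ratio; 0 when phytate is 0, `NA` when the
#'   mineral is 0.
#' @examples
#' molar_ratio(660, 65.38, "zinc") # 1
#' @export
molar_ratio <- function(phytate_mg, mineral_mg, mineral = c("zinc", "iron"),
                        masses = default_molar_masses()) {
  mineral <- match.arg(mineral)
  out <- (phytate_mg / masses[["phytate"]]) / (mineral_mg / masses[[mineral]])
  out[mineral_mg <= 0] <- NA_real_
  out[phytate_mg == 0 & mineral_mg > 0] <- 0
  unname(out)
}

#' Classify zinc bioavailability from the mean phytate:zinc molar ratio
#'
#' Ratio > 15: low bioavailability; 5-15 (closed interval): moderate;
#' < 5: high.
#'
#' @param mean_ratio child-period mean phytate:zinc molar ratio (>= 0).
#' @return factor with levels high/moderate/low.
#' @examples
#' classify_zinc(c(16, 15, 10, 4))
#' @export
classify_zinc <- function(mean_ratio) {
  stopifnot(all(mean_ratio >= 0, na.rm = TRUE))
  cls <- ifelse(mean_ratio > 15, "low",
    ifelse(mean_ratio >= 5, "moderate", "high")
  )
  factor(cls, levels = c("high", "moderate", "low"))
}

#' Derive a normal requirement distribution from RNI and CV
#'
#' The recommended nutrient intake is defined as EAR + 2 SD with
#' SD = CV x EAR, so `ear = rni / (1 + 2 cv)` and `sd = cv * ear`.
#'
#' @param rni recommended nutrient intake (> 0).
#' @param cv coefficient of variation of the requirement, in (0, 1).
#' @return list with `ear` and `sd`.
#' @examples
#' derive_normal_requirement(1.2, 0.10) # ear 1, sd 0.1
#' @export
derive_normal_requirement <- function(rni, cv) {
  if (any(rni <= 0)) abort("`rni` must be positive.")
  if (any(cv <= 0 | cv >= 1)) abort("`cv` must be in (0, 1).")
  ear <- rni / (1 + 2 * cv)
  list(ear = ear, sd = cv * ear)
}

#' Probability of adequacy under a normal requirement distribution
#'
#' PA is the mass of the requirement distribution below the child's estimated
#' usual intake: `pnorm((eui - ear) / sd)`.
#'
#' @param eui estimated usual intake.
#' @param ear estimated average requirement (distribution median).
#' @param sd requirement standard deviation (> 0).
#' @return probability in \[0, 1\].
#' @examples
#' pa_normal(1, 1, 0.1) # 0.5
#' @export
pa_normal <- function(eui, ear, sd) {
  if (any(sd <= 0)) abort("`sd` must be positive.")
  pnorm((eui - ear) / sd)
}

#' Probability of adequacy against a tabulated requirement distribution (iron)
#'
#' Iron requirements in these age ranges are non-normal; PA is read off a
#' percentile table of the requirement distribution. Tabulated intakes are
#' first multiplied by `scale` (reference-table bioavailability divided by the
#' 5 % bioavailability assumed for these diets), then PA is the monotone
#' piecewise-linear interpolation of percentile against scaled intake,
#' clamped to 0 below the table and 1 above it.
#'
#' @param eui estimated usual intake (mg/d).
#' @param quantiles data frame with columns `percentile` (in (0,1), strictly
#'   increasing) and `intake` (strictly increasing, mg/d at the reference
#'   bioavailability).
#' @param scale multiplier applied to tabulated intakes
#'   (reference bioavailability / assumed bioavailability).
#' @return probability in \[0, 1\].
#' @export
pa_iron <- function(eui, quantiles, scale = 1) {
  stopifnot(scale > 0)
  q <- as.data.frame(quantiles)
  if (nrow(q) < 3 || is.unsorted(q$percentile, strictly = TRUE) ||
    is.unsorted(q$intake, strictly = TRUE) ||
    any(q$percentile <= 0 | q$percentile >= 1)) {
    abort(paste0(
      "Iron quantile table must have >= 3 rows with strictly increasing ",
      "percentiles in (0,1) and strictly increasing intakes."
    ))
  }
  approx(
    x = q$intake * scale, y = q$percentile, xout = eui,
    method = "linear", yleft = 0, yright = 1, ties = "ordered"
  )$y
}

#' Probability of adequacy against an adequate intake (AI) threshold
#'
#' Used where no EAR exists (vitamin E at 9-12 months): PA is 1 at or above
#' the AI and 0 below it.
#'
#' @param eui estimated usual intake.
#' @param ai adequate intake threshold (> 0).
#' @return 0 or 1.
#' @export
pa_ai <- function(eui, ai) {
  if (any(ai <= 0)) abort("`ai` must be positive.")
  as.numeric(eui >= ai)
}

#' Mean probability of adequacy (MPA)
#'
#' Arithmetic mean of the per-nutrient PAs for one child; errors if any
#' configured nutrient is missing.
#'
#' @param pa named vector of PAs.
#' @param nutrients nutrient set the mean is taken over.
#' @return probability in \[0, 1\].
#' @export
mean_pa <- function(pa, nutrients = micronutrients()) {
  missing_n <- setdiff(nutrients, names(pa))
  if (length(missing_n)) {
    abort(paste0("PA missing for nutrient(s): ", paste(missing_n, collapse = ", ")))
  }
  mean(pa[nutrients])
}

#' Nutrient density per 100 kcal
#'
#' @param mean_intake mean daily nutrient amount.
#' @param mean_energy_kcal mean daily energy (kcal, > 0).
#' @return amount per 100 kcal; `NA` (flagged) when energy is zero.
#' @export
nutrient_density <- function(mean_intake, mean_energy_kcal) {
  out <- 100 * mean_intake / mean_energy_kcal
  bad <- mean_energy_kcal <= 0
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d record(s) with zero energy; density undefined (NA).", sum(bad)))
    out[bad] <- NA_real_
  }
  out
}
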