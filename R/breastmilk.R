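#' Predicted energy requirement of a child
#'
#' Looks up the per-kg requirement for the child's sex and age band and scales
#' by body weight.
#'
#' @param sex `"M"`/`"F"` vector.
#' @param age_days age in days.
#' @param weight_kg body weight (> 0).
#' @param table energy-requirement table, see [default_energy_requirements()].
#' @return kcal/d, strictly positive.
#' @examples
#' tab <- tibble::tibble(sex = "M", lo_months = 9, hi_months = 25, kcal_per_kg = 80)
#' energy_requirement("M", 9 * 30.4375, 9, tab) # 720
#' @export
energy_requirement <- function(sex, age_days, weight_kg, table = default_energy_requirements()) {
  if (any(weight_kg <= 0, na.rm = TRUE)) abort("weight_kg must be positive.")
  months <- age_days / DAYS_PER_MONTH
  per_kg <- rep(NA_real_, length(sex))
  for (i in seq_len(nrow(table))) {
    hit <- sex == table$sex[i] & months >= table$lo_months[i] & months < table$hi_months[i]
    per_kg[hit] <- table$kcal_per_kg[i]
  }
  if (anyNA(per_kg)) {
    abort("Energy-requirement table does not cover some sex/age combinations.")
  }
  per_kg * weight_kg
}

#' Impute breast-milk intake by the energy-gap method
#'
#' On each breastfed child-day the amount of breast milk consumed is assumed
#' to fill the gap between the predicted energy requirement and the energy
#' already supplied by complementary foods:
#' `bm_grams = max(0, requirement - cf_energy) / energy_density`
#' (default density 0.63 kcal/g). Breast-milk nutrients are `bm_grams / 100`
#' times the milk composition, and `total_* = cf_* + bm_*`. Non-breastfed
#' days get zero breast milk (total = CF). A negative gap (CF energy already
#' above the requirement) is floored to zero milk.
#'
#' @param child_days tibble from [compute_child_days()].
#' @param composition breast-milk composition, see
#'   [default_breastmilk_composition()].
#' @param er_table energy-requirement table, see
#'   [default_energy_requirements()].
#' @return `child_days` with `energy_requirement_kcal`, `bm_grams`, `bm_*`,
#'   `total_*` and `pct_energy_bm` (share of total energy from breast milk,
#'   in \[0, 1\]) filled in.
#' @export
impute_breastmilk <- function(child_days,
                              composition = default_breastmilk_composition(),
                              er_table = default_energy_requirements()) {
  req <- energy_requirement(
    child_days$sex, child_days$age_days, child_days$weight_kg, er_table
  )
  gap <- pmax(0, req - child_days$cf_energy_kcal)
  bm_g <- ifelse(child_days$breastfed_today, gap / composition$energy_kcal_per_g, 0)
  out <- child_days
  out$energy_requirement_kcal <- req
  out$bm_grams <- bm_g
  for (nc in nutrient_cols()) {
    out[[paste0("bm_", nc)]] <- bm_g / 100 * composition$nutrients_per_100g[[nc]]
    out[[paste0("total_", nc)]] <- out[[paste0("cf_", nc)]] + out[[paste0("bm_", nc)]]
  }
  # energy from milk uses the density (gap), not the per-100g energy entry,
  # so total energy on gap days closes exactly on the requirement
  out$bm_energy_kcal <- bm_g * composition$energy_kcal_per_g
  out$total_energy_kcal <- out$cf_energy_kcal + out$bm_energy_kcal
  out$pct_energy_bm <- ifelse(
    out$total_energy_kcal > 0, out$bm_energy_kcal / out$total_energy_kcal, 0
  )
  out
}
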