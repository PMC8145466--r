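#' Nutrient vocabulary
#'
#' The pipeline tracks energy plus fourteen micronutrients on every child-day.
#' All tables use these column names with fixed units (suffix): kcal/d for
#' energy, mg/d or ug/d per the suffix. Vitamin A is in ug retinol
#' equivalents, folate in ug dietary folate, vitamin D in ug.
#'
#' @return `nutrient_cols()` returns the 15 intake column names (energy
#'   first); `micronutrients()` the 14 micronutrient names (no energy).
#' @examples
#' nutrient_cols()
#' micronutrients()
#' @export
nutrient_cols <- function() {
  c("energy_kcal", micronutrients())
}

#' @rdname nutrient_cols
#' @export
micronutrients <- function() {
  c(
    "thiamine_mg", "riboflavin_mg", "niacin_mg", "vitB6_mg",
    "folate_ug", "vitB12_ug", "vitA_ug", "vitC_mg", "vitD_ug", "vitE_mg",
    "calcium_mg", "magnesium_mg", "iron_mg", "zinc_mg"
  )
}

#' Convert kilocalories to kilojoules
#'
#' @param kcal numeric vector of energies in kcal.
#' @return energies in kJ (`kcal * 4.184`).
#' @examples
#' kcal_to_kj(100) # 418.4
#' @export
kcal_to_kj <- function(kcal) {
  stopifnot(is.numeric(kcal))
  4.184 * kcal
}

#' Percentage of days breastfed over a window
#'
#' Longitudinal breastfeeding surveillance gives a daily breastfed flag; the
#' summary used throughout is the percentage of days in a window on which the
#' child was breastfed.
#'
#' @param flags logical (or 0/1) vector, one element per day of the window.
#' @return percentage in \[0, 100\].
#' @examples
#' percent_days_breastfed(c(TRUE, TRUE, FALSE, FALSE)) # 50
#' @export
percent_days_breastfed <- function(flags) {
  if (length(flags) == 0) {
    abort("`flags` must cover a non-empty window of days.")
  }
  if (anyNA(flags)) abort("`flags` must be defined on every day of the window.")
  100 * mean(as.logical(flags))
}

#' Default age bins (9-24 months as four periods)
#'
#' Bin labels follow the month groupings used for analysis; membership is by
#' completed months, `age_days / 30.4375`, with bin "9-12" meaning age in
#' \[9, 13) months and so on.
#'
#' @return tibble with columns `age_bin`, `lo_months`, `hi_months` (inclusive
#'   month labels).
#' @export
default_age_bins <- function() {
  tibble::tibble(
    age_bin   = c("9-12", "13-16", "17-20", "21-24"),
    lo_months = c(9, 13, 17, 21),
    hi_months = c(12, 16, 20, 24)
  )
}

DAYS_PER_MONTH <- 30.4375

#' Assign age bins by completed months
#'
#' @param age_days numeric vector of ages in days.
#' @param bins tibble as returned by [default_age_bins()].
#' @return character vector of bin labels, `NA` for out-of-range ages (these
#'   are flagged with a warning, never silently dropped).
#' @export
assign_age_bin <- function(age_days, bins = default_age_bins()) {
  months <- age_days / DAYS_PER_MONTH
  lab <- rep(NA_character_, length(age_days))
  for (i in seq_len(nrow(bins))) {
    in_bin <- months >= bins$lo_months[i] & months < bins$hi_months[i] + 1
    lab[in_bin] <- bins$age_bin[i]
  }
  if (anyNA(lab)) {
    warn(sprintf(
      "%d record(s) fall outside the configured age bins and are flagged NA.",
      sum(is.na(lab))
    ))
  }
  factor(lab, levels = bins$age_bin)
}
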