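#' Median and quartiles with the median-unbiased definition
#'
#' All summary tables use quantile type 8 (median-unbiased linear
#' interpolation of order statistics).
#'
#' @param x numeric vector.
#' @return named vector `q1`, `median`, `q3`.
#' @export
iqr_summary <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 8, names = FALSE, na.rm = TRUE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Summarise probability of adequacy by site and age period
#'
#' Median and IQR of per-child PA for each nutrient within site x age bin;
#' zinc is additionally reported separately by bioavailability class. Empty
#' groups are omitted with a log message.
#'
#' @param adequacy tibble from [compute_adequacy()].
#' @param pa_nutrients nutrients to summarise.
#' @return long tibble: `site_code`, `age_bin`, `nutrient`,
#'   `zinc_class` (`NA` except for the class-stratified zinc rows), `n`,
#'   `q1`, `median`, `q3`.
#' @export
summarize_pa <- function(adequacy, pa_nutrients = micronutrients()) {
  long <- adequacy |>
    select("child_id", "site_code", "age_bin", "zinc_class",
      all_of(paste0("pa_", pa_nutrients))
    ) |>
    tidyr::pivot_longer(
      starts_with("pa_"),
      names_to = "nutrient", names_prefix = "pa_", values_to = "pa"
    )
  overall <- long |>
    group_by(.data$site_code, .data$age_bin, .data$nutrient) |>
    summarise(
      zinc_class = factor(NA, levels = levels(adequacy$zinc_class)),
      n = dplyr::n(),
      q1 = iqr_summary(.data$pa)[["q1"]],
      median = iqr_summary(.data$pa)[["median"]],
      q3 = iqr_summary(.data$pa)[["q3"]],
      .groups = "drop"
    )
  by_class <- long |>
    filter(.data$nutrient == "zinc_mg") |>
    group_by(.data$site_code, .data$age_bin, .data$nutrient, .data$zinc_class) |>
    summarise(
      n = dplyr::n(),
      q1 = iqr_summary(.data$pa)[["q1"]],
      median = iqr_summary(.data$pa)[["median"]],
      q3 = iqr_summary(.data$pa)[["q3"]],
      .groups = "drop"
    )
  dplyr::bind_rows(overall, by_class) |>
    arrange(.data$site_code, .data$age_bin, .data$nutrient)
}

#' Percentage of child-days (and children) with low zinc bioavailability
#'
#' @param child_days tibble from [impute_breastmilk()].
#' @param adequacy tibble from [compute_adequacy()] (for the per-child
#'   period-mean classification).
#' @param masses molar masses for the day-level ratios.
#' @param mode intake basis for the ratios.
#' @return tibble per site x age bin: `n_child_days`,
#'   `pct_days_low` (day-level ratio > 15), `n_children`,
#'   `pct_children_low` (period-mean classification).
#' @export
summarize_bioavailability <- function(child_days, adequacy,
                                      masses = default_molar_masses(),
                                      mode = c("cf", "total")) {
  mode <- match.arg(mode)
  zn_col <- paste0(if (mode == "total") "total_" else "cf_", "zinc_mg")
  days <- child_days |>
    filter(!is.na(.data$age_bin)) |>
    mutate(ratio = molar_ratio(.data$phytate_mg, .data[[zn_col]], "zinc", masses)) |>
    filter(!is.na(.data$ratio)) |>
    group_by(.data$site_code, .data$age_bin) |>
    summarise(
      n_child_days = dplyr::n(),
      pct_days_low = 100 * mean(.data$ratio > 15),
      .groups = "drop"
    )
  children <- adequacy |>
    group_by(.data$site_code, .data$age_bin) |>
    summarise(
      n_children = dplyr::n(),
      pct_children_low = 100 * mean(.data$zinc_class == "low"),
      .groups = "drop"
    )
  inner_join(days, children, by = c("site_code", "age_bin"))
}

#' Summarise energy intake and the breast-milk share by site and age period
#'
#' Median/IQR of complementary-food energy and of the percentage of energy
#' from breast milk (per-child period means), plus the median percentage of
#' days breastfed.
#'
#' @param child_days tibble from [impute_breastmilk()].
#' @return tibble per site x age bin.
#' @export
summarize_energy <- function(child_days) {
  child_days |>
    filter(!is.na(.data$age_bin)) |>
    group_by(.data$child_id, .data$site_code, .data$age_bin) |>
    summarise(
      cf_energy = mean(.data$cf_energy_kcal),
      pct_energy_bm = 100 * mean(.data$pct_energy_bm),
      pct_days_bf = percent_days_breastfed(.data$breastfed_today),
      .groups = "drop"
    ) |>
    group_by(.data$site_code, .data$age_bin) |>
    summarise(
      n_children = dplyr::n(),
      cf_energy_q1 = iqr_summary(.data$cf_energy)[["q1"]],
      cf_energy_median = iqr_summary(.data$cf_energy)[["median"]],
      cf_energy_q3 = iqr_summary(.data$cf_energy)[["q3"]],
      pct_energy_bm_q1 = iqr_summary(.data$pct_energy_bm)[["q1"]],
      pct_energy_bm_median = iqr_summary(.data$pct_energy_bm)[["median"]],
      pct_energy_bm_q3 = iqr_summary(.data$pct_energy_bm)[["q3"]],
      pct_days_bf_median = iqr_summary(.data$pct_days_bf)[["median"]],
      .groups = "drop"
    )
}

#' Summarise MPA by site and age period
#'
#' @param adequacy tibble from [compute_adequacy()].
#' @return tibble per site x age bin with median and IQR of child MPA.
#' @export
summarize_mpa <- function(adequacy) {
  adequacy |>
    group_by(.data$site_code, .data$age_bin) |>
    summarise(
      n_children = dplyr::n(),
      q1 = iqr_summary(.data$mpa)[["q1"]],
      median = iqr_summary(.data$mpa)[["median"]],
      q3 = iqr_summary(.data$mpa)[["q3"]],
      .groups = "drop"
    )
}
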