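#' Child-period bioavailability from phytate molar ratios
#'
#' Computes phytate:zinc and phytate:iron molar ratios for every child-day
#' and averages them per child x age bin (days with zero mineral intake are
#' excluded from the mean with a log message). The mean phytate:zinc ratio
#' classifies zinc bioavailability (> 15 low, 5-15 moderate, < 5 high). Iron
#' is always treated as low bioavailability — the phytate:iron ratios in
#' these diets exceed 1 (the classification threshold) essentially
#' everywhere — but the ratio is reported for transparency.
#'
#' @param child_days tibble from [impute_breastmilk()].
#' @param masses molar masses, see [default_molar_masses()].
#' @param mode intake columns used for the mineral: `"cf"` (default — the
#'   phytate:mineral ratio characterises the food-based diet; breast-milk
#'   minerals carry no phytate) or `"total"`.
#' @return tibble: `child_id`, `site_code`, `age_bin`, `mean_phytate_zinc`,
#'   `mean_phytate_iron`, `zinc_class`, `n_days_ratio`.
#' @export
bioavailability_by_child <- function(child_days, masses = default_molar_masses(),
                                     mode = c("cf", "total")) {
  mode <- match.arg(mode)
  zn_col <- paste0(if (mode == "total") "total_" else "cf_", "zinc_mg")
  fe_col <- paste0(if (mode == "total") "total_" else "cf_", "iron_mg")
  cd <- child_days |>
    filter(!is.na(.data$age_bin)) |>
    mutate(
      pz = molar_ratio(.data$phytate_mg, .data[[zn_col]], "zinc", masses),
      pf = molar_ratio(.data$phytate_mg, .data[[fe_col]], "iron", masses)
    )
  n_undef <- sum(is.na(cd$pz)) + sum(is.na(cd$pf))
  if (n_undef > 0) {
    inform(sprintf(
      "%d child-day ratio(s) undefined (zero mineral intake); excluded from period means.",
      n_undef
    ))
  }
  cd |>
    group_by(.data$child_id, .data$site_code, .data$age_bin) |>
    summarise(
      mean_phytate_zinc = mean(.data$pz, na.rm = TRUE),
      mean_phytate_iron = mean(.data$pf, na.rm = TRUE),
      n_days_ratio = sum(!is.na(.data$pz)),
      .groups = "drop"
    ) |>
    mutate(zinc_class = classify_zinc(.data$mean_phytate_zinc))
}

pa_one_nutrient <- function(eui, nutrient, age_bin, zinc_class, requirements) {
  specs <- requirements$specs
  if (nutrient == "iron_mg") {
    q <- requirements$iron[requirements$iron$age_bin == age_bin[1] &
      requirements$iron$nutrient == "iron_mg", ]
    if (nrow(q) == 0) abort(sprintf("No iron quantile table for age bin %s", age_bin[1]))
    return(pa_iron(eui, q[, c("percentile", "intake")], scale = q$scale[1]))
  }
  if (nutrient == "zinc_mg") {
    out <- rep(NA_real_, length(eui))
    for (cl in unique(as.character(zinc_class))) {
      row <- specs[specs$nutrient == "zinc_mg" & specs$age_bin == age_bin[1] &
        specs$bioavailability == cl, ]
      if (nrow(row) == 0) {
        abort(sprintf("No zinc requirement for class '%s', age bin %s", cl, age_bin[1]))
      }
      sel <- as.character(zinc_class) == cl
      out[sel] <- pa_normal(eui[sel], row$ear, row$sd)
    }
    return(out)
  }
  row <- specs[specs$nutrient == nutrient & specs$age_bin == age_bin[1] &
    is.na(specs$bioavailability), ]
  if (nrow(row) == 0) {
    abort(sprintf("No requirement spec for %s, age bin %s", nutrient, age_bin[1]))
  }
  if (row$kind == "ai_threshold") pa_ai(eui, row$ai) else pa_normal(eui, row$ear, row$sd)
}

#' Probability of adequacy, MPA and nutrient densities per child x age bin
#'
#' For each child and age period: locates the estimated usual intake on the
#' requirement distribution of each of the fourteen micronutrients (normal
#' EAR/SD distributions; the tabulated iron distribution scaled to 5 %
#' bioavailability; an AI threshold for vitamin E at 9-12 months; zinc using
#' the EAR/SD of the child's phytate:zinc bioavailability class), averages
#' the PAs into the MPA, and adds complementary-food nutrient densities per
#' 100 kcal (from observed mean CF intakes) and the mean share of energy
#' from breast milk.
#'
#' @param eui long EUI table from [estimate_usual_intake()].
#' @param child_days tibble from [impute_breastmilk()].
#' @param requirements requirement configuration, see
#'   [default_requirements()].
#' @param masses molar masses for the phytate ratios.
#' @param pa_nutrients nutrient set for PA/MPA (default the 14
#'   micronutrients).
#' @param ratio_mode intake basis for the phytate molar ratios (`"cf"` by
#'   default: bioavailability is a property of the food-based diet).
#' @return wide tibble per child x age bin: bioavailability ratios and class,
#'   `pa_<nutrient>` columns, `mpa`, `density_<nutrient>` columns,
#'   `pct_energy_bm`.
#' @export
compute_adequacy <- function(eui, child_days,
                             requirements = default_requirements(),
                             masses = default_molar_masses(),
                             pa_nutrients = micronutrients(),
                             ratio_mode = c("cf", "total")) {
  ratio_mode <- match.arg(ratio_mode)
  bio <- bioavailability_by_child(child_days, masses, ratio_mode)

  pa_long <- eui |>
    filter(.data$nutrient %in% pa_nutrients) |>
    left_join(
      select(bio, "child_id", "age_bin", "zinc_class"),
      by = c("child_id", "age_bin")
    ) |>
    group_by(.data$site_code, .data$age_bin, .data$nutrient) |>
    mutate(pa = pa_one_nutrient(
      .data$eui, .data$nutrient[1], as.character(.data$age_bin),
      .data$zinc_class, requirements
    )) |>
    ungroup()

  pa_wide <- pa_long |>
    select("child_id", "site_code", "age_bin", "nutrient", "pa") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "pa", names_prefix = "pa_")

  mpa <- pa_long |>
    group_by(.data$child_id, .data$site_code, .data$age_bin) |>
    summarise(
      mpa = if (all(pa_nutrients %in% .data$nutrient)) mean(.data$pa) else NA_real_,
      .groups = "drop"
    )
  if (anyNA(mpa$mpa)) {
    abort("MPA undefined for some children: PA missing for part of the nutrient set.")
  }

  dens <- child_days |>
    filter(!is.na(.data$age_bin)) |>
    group_by(.data$child_id, .data$site_code, .data$age_bin) |>
    summarise(
      across(all_of(paste0("cf_", nutrient_cols())), mean),
      pct_energy_bm = mean(.data$pct_energy_bm),
      .groups = "drop"
    )
  for (nu in micronutrients()) {
    dens[[paste0("density_", nu)]] <-
      nutrient_density(dens[[paste0("cf_", nu)]], dens$cf_energy_kcal)
  }
  dens <- select(dens, -all_of(paste0("cf_", nutrient_cols())))

  bio |>
    inner_join(pa_wide, by = c("child_id", "site_code", "age_bin")) |>
    inner_join(mpa, by = c("child_id", "site_code", "age_bin")) |>
    left_join(dens, by = c("child_id", "site_code", "age_bin"))
}
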