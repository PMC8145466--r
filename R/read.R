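#' Read a 24-h recall table
#'
#' Long format, one row per food per recall day: UTF-8 CSV with ISO dates and
#' columns `child_id, site_code, recall_date, age_days, sex, weight_kg,
#' breastfed_today, food_code, amount_g`.
#'
#' @param path CSV file.
#' @return tibble of recall records.
#' @export
read_recalls <- function(path) {
  if (!file.exists(path)) abort(sprintf("Recall file not found: %s", path))
  req <- c(
    "child_id", "site_code", "recall_date", "age_days", "sex", "weight_kg",
    "breastfed_today", "food_code", "amount_g"
  )
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0(
      "Recall file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df <- df |>
    mutate(
      child_id = as.character(.data$child_id),
      site_code = as.character(.data$site_code),
      recall_date = as.Date(.data$recall_date),
      breastfed_today = as.logical(.data$breastfed_today),
      food_code = as.character(.data$food_code)
    )
  bad <- which(df$amount_g < 0)
  if (length(bad)) {
    abort(sprintf(
      "Negative amount_g in recall row(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  if (anyNA(df$recall_date)) {
    abort(sprintf(
      "Unparseable recall_date in row(s): %s",
      paste(head(which(is.na(df$recall_date)), 10), collapse = ", ")
    ))
  }
  df
}

#' Read a food composition table
#'
#' One row per food, nutrient values per 100 g edible portion:
#' `food_code, description, <energy + 14 nutrient columns>, phytate_mg`.
#'
#' @param path CSV file.
#' @return tibble keyed by `food_code`.
#' @export
read_fct <- function(path) {
  if (!file.exists(path)) abort(sprintf("FCT file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("food_code", nutrient_cols(), "phytate_mg")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0(
      "FCT is missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  df <- mutate(df, food_code = as.character(.data$food_code))
  if (anyDuplicated(df$food_code)) {
    abort("FCT food_code values must be unique.")
  }
  vals <- as.matrix(df[, c(nutrient_cols(), "phytate_mg")])
  if (any(vals < 0, na.rm = TRUE)) abort("FCT nutrient values must be >= 0.")
  df
}

#' Requirement configuration
#'
#' `default_requirements()` loads the requirement table shipped with the
#' package; `read_requirements()` loads one from a YAML file with the same
#' layout (see `inst/extdata/requirements.yaml`).
#'
#' @param path YAML file.
#' @return a list of class `"requirement_config"` with `specs` (tibble:
#'   `nutrient, age_bin, bioavailability, kind, ear, sd, ai`) and `iron`
#'   (tibble: `age_bin, percentile, intake, scale` with intakes at the
#'   reference bioavailability and `scale` the multiplier to the assumed 5 %
#'   bioavailability).
#' @export
read_requirements <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$nutrients)) abort("requirements.yaml must have a `nutrients:` map.")
  specs <- list()
  iron <- list()
  as_spec <- function(nutrient, bin, class, node) {
    kind <- node$kind %||% abort(sprintf("Missing kind for %s/%s", nutrient, bin))
    if (kind == "normal") {
      if (!is.null(node$ear) && !is.null(node$sd)) {
        ear <- node$ear
        sdv <- node$sd
      } else {
        d <- derive_normal_requirement(node$rni, node$cv)
        ear <- d$ear
        sdv <- d$sd
      }
      if (ear <= 0 || sdv <= 0) abort(sprintf("Invalid normal spec for %s/%s", nutrient, bin))
      tibble::tibble(
        nutrient = nutrient, age_bin = bin, bioavailability = class,
        kind = "normal", ear = ear, sd = sdv, ai = NA_real_
      )
    } else if (kind == "ai_threshold") {
      if (is.null(node$ai) || node$ai <= 0) {
        abort(sprintf("ai_threshold spec for %s/%s needs ai > 0", nutrient, bin))
      }
      tibble::tibble(
        nutrient = nutrient, age_bin = bin, bioavailability = class,
        kind = "ai_threshold", ear = NA_real_, sd = NA_real_, ai = node$ai
      )
    } else {
      abort(sprintf("Unknown requirement kind '%s' for %s/%s", kind, nutrient, bin))
    }
  }
  for (nutrient in names(raw$nutrients)) {
    bins <- raw$nutrients[[nutrient]]
    for (bin in names(bins)) {
      node <- bins[[bin]]
      if (!is.null(node$kind) && node$kind == "quantile_table") {
        q <- dplyr::bind_rows(lapply(node$quantiles, tibble::as_tibble))
        if (nrow(q) < 3 || is.unsorted(q$percentile, strictly = TRUE) ||
          is.unsorted(q$intake, strictly = TRUE) ||
          any(q$percentile <= 0 | q$percentile >= 1)) {
          abort(sprintf("Invalid quantile table for %s/%s", nutrient, bin))
        }
        ref <- node$reference_bioavailability %||% 1
        assumed <- node$assumed_bioavailability %||% 0.05
        iron[[length(iron) + 1]] <- mutate(q,
          age_bin = bin, nutrient = nutrient,
          scale = ref / assumed, .before = 1
        )
      } else if (!is.null(node$kind)) {
        specs[[length(specs) + 1]] <- as_spec(nutrient, bin, NA_character_, node)
      } else {
        # one level deeper: bioavailability classes
        for (class in names(node)) {
          specs[[length(specs) + 1]] <- as_spec(nutrient, bin, class, node[[class]])
        }
      }
    }
  }
  structure(
    list(specs = dplyr::bind_rows(specs), iron = dplyr::bind_rows(iron)),
    class = "requirement_config"
  )
}

#' @rdname read_requirements
#' @export
default_requirements <- function() {
  read_requirements(
    system.file("extdata", "requirements.yaml", package = "dietadequacy", mustWork = TRUE)
  )
}

#' Breast-milk composition configuration
#'
#' @param path YAML file with `energy_kcal_per_g` and a `nutrients_per_100g`
#'   map over the standard nutrient columns.
#' @return list with `energy_kcal_per_g` (default 0.63 kcal/g) and
#'   `nutrients_per_100g` (named numeric over [nutrient_cols()]).
#' @export
read_breastmilk_composition <- function(path) {
  raw <- yaml::read_yaml(path)
  dens <- raw$energy_kcal_per_g
  if (is.null(dens) || dens <= 0) abort("energy_kcal_per_g must be > 0.")
  nut <- unlist(raw$nutrients_per_100g)
  missing_n <- setdiff(nutrient_cols(), names(nut))
  if (length(missing_n)) {
    abort(paste0(
      "breastmilk composition missing: ", paste(missing_n, collapse = ", ")
    ))
  }
  nut <- nut[nutrient_cols()]
  if (any(nut < 0)) abort("breast-milk nutrient values must be >= 0.")
  list(energy_kcal_per_g = dens, nutrients_per_100g = nut)
}

#' @rdname read_breastmilk_composition
#' @export
default_breastmilk_composition <- function() {
  read_breastmilk_composition(
    system.file("extdata", "breastmilk.yaml", package = "dietadequacy", mustWork = TRUE)
  )
}

#' Energy-requirement table
#'
#' Per-kg energy requirements by sex and age band (months, `[lo, hi)`).
#'
#' @param path YAML file with a `rows:` list of
#'   `{sex, lo_months, hi_months, kcal_per_kg}`.
#' @return tibble with those columns.
#' @export
read_energy_requirements <- function(path) {
  raw <- yaml::read_yaml(path)
  df <- dplyr::bind_rows(lapply(raw$rows, tibble::as_tibble))
  stopifnot(all(c("sex", "lo_months", "hi_months", "kcal_per_kg") %in% names(df)))
  if (any(df$kcal_per_kg <= 0)) abort("kcal_per_kg must be positive.")
  for (s in c("M", "F")) {
    bands <- df[df$sex == s, ]
    cover <- seq(9, 24.9, by = 0.1)
    hit <- vapply(cover, function(m) any(m >= bands$lo_months & m < bands$hi_months), logical(1))
    if (!all(hit)) abort(sprintf("Energy table does not cover 9-25 months for sex %s.", s))
  }
  df
}

#' @rdname read_energy_requirements
#' @export
default_energy_requirements <- function() {
  read_energy_requirements(
    system.file("extdata", "energy_requirements.yaml", package = "dietadequacy", mustWork = TRUE)
  )
}

#' Build per-child-day intakes from recalls and a food composition table
#'
#' Joins each recall row to the FCT and accumulates complementary-food (CF)
#' nutrient intakes per child-day: `cf_<nutrient> = sum(amount_g/100 *
#' per_100g)`, phytate likewise. Assigns age bins by completed months and
#' derives weekday/month from the recall date. Breast-milk columns are
#' initialised to zero and filled by [impute_breastmilk()].
#'
#' @param recalls tibble as from [read_recalls()] or [simulate_study()].
#' @param fct tibble as from [read_fct()].
#' @param unresolved `"error"` (default) or `"skip"`: what to do with food
#'   codes absent from the FCT (skipping drops those rows with a warning).
#' @param age_bins bin definitions, see [default_age_bins()].
#' @return tibble with one row per child-day: identifiers, `age_bin`, `sex`,
#'   `weight_kg`, `breastfed_today`, `weekday` (1-7, Monday = 1), `month`,
#'   `cf_*` intake columns, `phytate_mg`, `bm_grams` and `bm_*`/`total_*`
#'   columns (zero / equal to CF until imputation).
#' @export
compute_child_days <- function(recalls, fct, unresolved = c("error", "skip"),
                               age_bins = default_age_bins()) {
  unresolved <- match.arg(unresolved)
  unknown <- setdiff(unique(recalls$food_code), fct$food_code)
  if (length(unknown)) {
    if (unresolved == "error") {
      abort(paste0(
        "Food code(s) not in FCT: ", paste(head(unknown, 20), collapse = ", "),
        " (use unresolved = \"skip\" to drop them with a warning)"
      ))
    }
    warn(paste0(
      "Dropping recall rows with unresolved food code(s): ",
      paste(head(unknown, 20), collapse = ", ")
    ))
    recalls <- filter(recalls, .data$food_code %in% fct$food_code)
  }
  comp_cols <- c(nutrient_cols(), "phytate_mg")
  joined <- recalls |>
    inner_join(fct[, c("food_code", comp_cols)], by = "food_code") |>
    mutate(across(all_of(comp_cols), ~ .x * .data$amount_g / 100))

  cd <- joined |>
    group_by(
      .data$child_id, .data$site_code, .data$recall_date, .data$age_days,
      .data$sex, .data$weight_kg, .data$breastfed_today
    ) |>
    summarise(across(all_of(comp_cols), sum), .groups = "drop") |>
    rename_with(~ paste0("cf_", .x), all_of(nutrient_cols())) |>
    mutate(
      age_bin = assign_age_bin(.data$age_days, age_bins),
      weekday = as.integer(format(.data$recall_date, "%u")),
      month = as.integer(format(.data$recall_date, "%m")),
      bm_grams = 0
    )
  for (nc in nutrient_cols()) {
    cd[[paste0("bm_", nc)]] <- 0
    cd[[paste0("total_", nc)]] <- cd[[paste0("cf_", nc)]]
  }
  arrange(cd, .data$child_id, .data$recall_date)
}
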