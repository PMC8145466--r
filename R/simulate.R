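#' Configuration for a synthetic study
#'
#' Builds the parameter set for [simulate_study()]. Defaults emulate a
#' single-site longitudinal cohort of children followed 9-24 months with
#' monthly 24-h recalls: staggered enrolment over a year, breastfeeding
#' cessation drawn per child from a logistic distribution, lognormal-type
#' usual intakes (Box-Cox power 0 by default) with between-child and
#' within-child (day-to-day) variability on the transformed scale, mild
#' weekend and seasonal effects, episodic zero-intake days for vitamins
#' A/B12/D, and per-age-bin multipliers emulating the growth of
#' complementary-food quantities with age.
#'
#' @param n_children number of children.
#' @param recalls_per_bin recall days per child per age bin (default 4).
#' @param seed integer seed (mandatory); child-level streams are derived by
#'   stable hashing of the child id, so adding children never perturbs
#'   existing ones.
#' @param site_scenario `"mixed"` (default), `"phytate_rich"` or
#'   `"fortified"`: sets the phytate:zinc molar-ratio level of the diets
#'   (per-child lognormal day ratios with median 30 for phytate-rich diets,
#'   8 — squarely in the moderate 5-15 band — for fortified ones; `"mixed"`
#'   assigns half the children to each).
#' @param bf_cessation_median_months,bf_cessation_scale median (months) and
#'   scale of the per-child logistic breastfeeding-cessation age.
#' @param geo_mean named geometric-mean daily complementary-food intakes
#'   (units of [nutrient_cols()]).
#' @param between_cv,within_cv between-child / within-child coefficients of
#'   variation (scalar or named per nutrient).
#' @param sigma2_between,sigma2_within optional direct transformed-scale
#'   variances (scalar or named); override the CVs when given.
#' @param transform_lambda Box-Cox power of the generating scale (scalar or
#'   named; 0 = lognormal).
#' @param weekday_effect,month_effect multiplicative day factors (length 7 /
#'   12).
#' @param zero_day_prob probability of a zero-intake day (named per
#'   nutrient; unnamed nutrients get 0).
#' @param bin_multiplier per-age-bin multiplier on the geometric means.
#' @param site_code site label for the generated study.
#' @param age_bins age-bin table, see [default_age_bins()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_children = 50,
                              recalls_per_bin = 4,
                              seed,
                              site_scenario = c("mixed", "phytate_rich", "fortified"),
                              bf_cessation_median_months = 18,
                              bf_cessation_scale = 2.5,
                              geo_mean = default_geo_mean(),
                              between_cv = 0.3,
                              within_cv = 0.5,
                              sigma2_between = NULL,
                              sigma2_within = NULL,
                              transform_lambda = 0,
                              weekday_effect = c(1, 1, 1, 1, 1, 1.05, 1.05),
                              month_effect = 1 + 0.05 * cospi((0:11) / 6),
                              zero_day_prob = c(vitA_ug = 0.10, vitB12_ug = 0.15, vitD_ug = 0.20),
                              bin_multiplier = c(0.75, 0.95, 1.10, 1.20),
                              site_code = "SYN",
                              age_bins = default_age_bins()) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  site_scenario <- match.arg(site_scenario)
  nut <- nutrient_cols()
  expand_named <- function(x, default = 0) {
    out <- setNames(rep(default, length(nut)), nut)
    if (is.null(names(x)) && length(x) == 1) out[] <- x else out[names(x)] <- x
    out
  }
  cfg <- list(
    n_children = n_children, recalls_per_bin = recalls_per_bin,
    seed = as.integer(seed), site_scenario = site_scenario,
    bf_cessation_median_months = bf_cessation_median_months,
    bf_cessation_scale = bf_cessation_scale,
    geo_mean = expand_named(geo_mean),
    between_cv = expand_named(between_cv),
    within_cv = expand_named(within_cv),
    transform_lambda = expand_named(transform_lambda),
    weekday_effect = weekday_effect, month_effect = month_effect,
    zero_day_prob = expand_named(zero_day_prob),
    bin_multiplier = bin_multiplier,
    site_code = site_code, age_bins = age_bins
  )
  # explicit transformed-scale variances override the CVs
  cfg$sigma2_between_given <- if (!is.null(sigma2_between)) expand_named(sigma2_between) else NULL
  cfg$sigma2_within_given <- if (!is.null(sigma2_within)) expand_named(sigma2_within) else NULL
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_children < 1 || recalls_per_bin < 1) abort("n_children and recalls_per_bin must be >= 1.")
    if (any(geo_mean <= 0)) abort("geo_mean values must be positive.")
    if (any(between_cv < 0) || any(within_cv < 0)) abort("CVs must be >= 0.")
    if (any(zero_day_prob < 0 | zero_day_prob >= 1)) abort("zero_day_prob must be in [0, 1).")
    if (length(weekday_effect) != 7 || length(month_effect) != 12) {
      abort("weekday_effect must have length 7 and month_effect length 12.")
    }
    if (length(bin_multiplier) != nrow(age_bins)) {
      abort("bin_multiplier must have one value per age bin.")
    }
  })
  invisible(cfg)
}

#' Default geometric-mean complementary-food intakes
#'
#' Daily geometric means typical of complementary diets of children 9-24
#' months in low-resource settings: modest energy and low density of
#' vitamins A/D/E, calcium, iron and zinc, so that adequacy is mixed rather
#' than saturated.
#' @return named vector over [nutrient_cols()].
#' @export
default_geo_mean <- function() {
  c(
    energy_kcal = 550,
    thiamine_mg = 0.25, riboflavin_mg = 0.35, niacin_mg = 3.5, vitB6_mg = 0.35,
    folate_ug = 60, vitB12_ug = 0.5, vitA_ug = 150, vitC_mg = 25,
    vitD_ug = 1.0, vitE_mg = 1.8,
    calcium_mg = 250, magnesium_mg = 60, iron_mg = 4, zinc_mg = 2.5
  )
}

# marker foods: one food per nutrient so the FCT join is exactly invertible
synthetic_fct <- function() {
  per100 <- c(
    energy_kcal = 120, thiamine_mg = 0.5, riboflavin_mg = 0.7, niacin_mg = 6,
    vitB6_mg = 0.6, folate_ug = 120, vitB12_ug = 1.0, vitA_ug = 300,
    vitC_mg = 50, vitD_ug = 2, vitE_mg = 4, calcium_mg = 500,
    magnesium_mg = 120, iron_mg = 8, zinc_mg = 5
  )
  nut <- nutrient_cols()
  fct <- tibble::tibble(
    food_code = paste0("SYN_", nut),
    description = paste("synthetic marker food:", nut)
  )
  for (nc in nut) fct[[nc]] <- ifelse(nut == nc, per100[[nc]], 0)
  fct$phytate_mg <- 0
  phy <- tibble::tibble(
    food_code = "SYN_phytate", description = "synthetic marker food: phytate"
  )
  for (nc in nut) phy[[nc]] <- 0
  phy$phytate_mg <- 800
  dplyr::bind_rows(fct, phy)
}

hash_child <- function(child_id, seed) {
  h <- 0
  for (ch in utf8ToInt(child_id)) h <- (h * 131 + ch) %% 1000000007
  as.integer((h + seed * 7919) %% 2147483647)
}

mu_transformed <- function(gm, lambda) boxcox_transform(gm, lambda)

sd_transformed <- function(cv, gm, lambda) {
  if (abs(lambda) < 1e-8) sqrt(log(1 + cv^2)) else cv * gm^lambda
}

# E[g^-1(mu + b + e)] over e ~ N(0, sd_w^2), by quadrature for lambda != 0
expected_backtransformed <- function(mu_plus_b, lambda, sd_w) {
  if (abs(lambda) < 1e-8) {
    return(exp(mu_plus_b) * exp(sd_w^2 / 2))
  }
  z <- seq(-6, 6, length.out = 241)
  w <- exp(-z^2 / 2)
  w <- w / sum(w)
  vapply(mu_plus_b, function(m) {
    x <- boxcox_inverse(m + sd_w * z, lambda)
    sum(pmax(x, 0, na.rm = TRUE) * w)
  }, numeric(1))
}

#' Generate a synthetic study with known ground truth
#'
#' Draws children, breastfeeding histories, recall days and daily
#' complementary-food intakes per the configuration, and emits a recall
#' table plus marker-food composition table whose join reproduces the drawn
#' daily totals exactly. Ground truth contains each child's true usual
#' intake (the long-run mean over day-to-day noise, calendar effects and
#' zero days), true bioavailability class, and the analytic PA/MPA of the
#' true usual intakes under the shipped requirement table.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_study`: `recalls`, `fct`, `children`,
#'   and `truth` (list with `usual`, `adequacy`, `mpa`, `children`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  nut <- nutrient_cols()
  bins <- cfg$age_bins
  n_bins <- nrow(bins)
  lam <- cfg$transform_lambda
  sd_b <- vapply(nut, function(n) {
    if (!is.null(cfg$sigma2_between_given)) {
      sqrt(cfg$sigma2_between_given[[n]])
    } else {
      sd_transformed(cfg$between_cv[[n]], cfg$geo_mean[[n]], lam[[n]])
    }
  }, numeric(1))
  sd_w <- vapply(nut, function(n) {
    if (!is.null(cfg$sigma2_within_given)) {
      sqrt(cfg$sigma2_within_given[[n]])
    } else {
      sd_transformed(cfg$within_cv[[n]], cfg$geo_mean[[n]], lam[[n]])
    }
  }, numeric(1))

  ratio_median_for <- function(i) {
    switch(cfg$site_scenario,
      phytate_rich = 30,
      fortified = 8,
      mixed = if (i %% 2 == 1) 30 else 8
    )
  }
  fct <- synthetic_fct()
  per100 <- setNames(
    vapply(nut, function(nc) fct[[nc]][fct$food_code == paste0("SYN_", nc)], numeric(1)),
    nut
  )
  masses <- default_molar_masses()
  wk_mean <- mean(cfg$weekday_effect)
  mo_mean <- mean(cfg$month_effect)

  children <- vector("list", cfg$n_children)
  recall_rows <- vector("list", cfg$n_children)
  truth_rows <- vector("list", cfg$n_children)
  daily_rows <- vector("list", cfg$n_children)

  for (i in seq_len(cfg$n_children)) {
    child_id <- sprintf("C%04d", i)
    set.seed(hash_child(child_id, cfg$seed))
    sex <- if (runif(1) < 0.5) "F" else "M"
    birth_date <- as.Date("2010-01-15") + round(((i - 1) %% 12) * DAYS_PER_MONTH)
    weight_base <- rnorm(1, 8.9, 0.8) # kg at 9 months
    weight_slope <- 0.17 + rnorm(1, 0, 0.03) # kg per month
    cess_months <- rlogis(1, cfg$bf_cessation_median_months, cfg$bf_cessation_scale)
    b_i <- rnorm(length(nut), 0, sd_b)
    names(b_i) <- nut
    rmed <- ratio_median_for(i)

    day_list <- list()
    for (bi in seq_len(n_bins)) {
      lo_d <- ceiling(bins$lo_months[bi] * DAYS_PER_MONTH)
      hi_d <- floor((bins$hi_months[bi] + 1) * DAYS_PER_MONTH) - 1
      ages <- sort(sample(lo_d:hi_d, cfg$recalls_per_bin))
      for (a in ages) {
        date <- birth_date + a
        wd <- as.integer(format(date, "%u"))
        mo <- as.integer(format(date, "%m"))
        e <- rnorm(length(nut), 0, sd_w)
        zero <- rbinom(length(nut), 1, cfg$zero_day_prob[nut]) == 1
        mu <- vapply(
          nut,
          function(n) mu_transformed(cfg$geo_mean[[n]] * cfg$bin_multiplier[bi], lam[[n]]),
          numeric(1)
        )
        x <- vapply(seq_along(nut), function(k) {
          v <- boxcox_inverse(mu[k] + b_i[k] + e[k], lam[[nut[k]]])
          max(v, 0, na.rm = TRUE)
        }, numeric(1))
        x <- x * cfg$weekday_effect[wd] * cfg$month_effect[mo]
        x[zero] <- 0
        names(x) <- nut
        ratio <- rlnorm(1, log(rmed), 0.3)
        phytate <- ratio * x[["zinc_mg"]] * masses[["phytate"]] / masses[["zinc"]]
        day_list[[length(day_list) + 1]] <- list(
          age_days = a, date = date, bin = bins$age_bin[bi],
          weight = weight_base + weight_slope * (a / DAYS_PER_MONTH - 9),
          breastfed = a / DAYS_PER_MONTH < cess_months,
          x = x, phytate = phytate
        )
      }
    }

    rows <- purrr::map(day_list, function(d) {
      present <- nut[d$x > 0]
      amounts <- 100 * d$x[present] / per100[present]
      codes <- paste0("SYN_", present)
      if (d$phytate > 0) {
        codes <- c(codes, "SYN_phytate")
        amounts <- c(amounts, 100 * d$phytate / 800)
      }
      tibble::tibble(
        child_id = child_id, site_code = cfg$site_code,
        recall_date = d$date, age_days = d$age_days,
        sex = sex, weight_kg = d$weight,
        breastfed_today = d$breastfed,
        food_code = codes, amount_g = unname(amounts)
      )
    })
    recall_rows[[i]] <- dplyr::bind_rows(rows)

    daily_rows[[i]] <- purrr::map(day_list, function(d) {
      out <- tibble::tibble(
        child_id = child_id, site_code = cfg$site_code,
        recall_date = d$date, age_days = d$age_days, age_bin = d$bin,
        sex = sex, weight_kg = d$weight, breastfed_today = d$breastfed
      )
      for (nc in nut) out[[nc]] <- d$x[[nc]]
      out$phytate_mg <- d$phytate
      out
    }) |> dplyr::bind_rows()

    true_usual <- purrr::map(seq_len(n_bins), function(bi) {
      mu <- vapply(
        nut,
        function(n) mu_transformed(cfg$geo_mean[[n]] * cfg$bin_multiplier[bi], lam[[n]]),
        numeric(1)
      )
      tu <- vapply(seq_along(nut), function(k) {
        expected_backtransformed(mu[k] + b_i[k], lam[[nut[k]]], sd_w[k])
      }, numeric(1)) * wk_mean * mo_mean * (1 - cfg$zero_day_prob[nut])
      tibble::tibble(
        child_id = child_id, site_code = cfg$site_code,
        age_bin = bins$age_bin[bi], nutrient = nut, true_usual = unname(tu)
      )
    })
    truth_rows[[i]] <- dplyr::bind_rows(true_usual)

    children[[i]] <- tibble::tibble(
      child_id = child_id, site_code = cfg$site_code, sex = sex,
      birth_date = birth_date, weight_9mo_kg = weight_base,
      cessation_months = cess_months,
      ratio_median = rmed,
      true_mean_ratio = rmed * exp(0.3^2 / 2)
    )
  }

  children <- dplyr::bind_rows(children)
  children$true_zinc_class <- classify_zinc(children$true_mean_ratio)
  truth_usual <- dplyr::bind_rows(truth_rows)

  # analytic adequacy of the true usual intakes under the shipped requirements
  req <- default_requirements()
  truth_adequacy <- truth_usual |>
    filter(.data$nutrient %in% micronutrients()) |>
    left_join(
      select(children, "child_id", zinc_class = "true_zinc_class"),
      by = "child_id"
    ) |>
    group_by(.data$age_bin, .data$nutrient) |>
    mutate(true_pa = pa_one_nutrient(
      .data$true_usual, .data$nutrient[1], as.character(.data$age_bin),
      .data$zinc_class, req
    )) |>
    ungroup() |>
    select("child_id", "site_code", "age_bin", "nutrient", "true_pa")
  truth_mpa <- truth_adequacy |>
    group_by(.data$child_id, .data$site_code, .data$age_bin) |>
    summarise(true_mpa = mean(.data$true_pa), .groups = "drop")

  structure(
    list(
      recalls = dplyr::bind_rows(recall_rows),
      daily = dplyr::bind_rows(daily_rows),
      fct = fct,
      children = children,
      truth = list(
        usual = truth_usual, adequacy = truth_adequacy, mpa = truth_mpa,
        children = select(
          children, "child_id", "cessation_months", "true_zinc_class"
        )
      ),
      config = cfg
    ),
    class = "synthetic_study"
  )
}

#' Write a synthetic study to a directory
#'
#' Emits `recalls.csv`, `fct.csv`, `children.csv` and `truth_usual.csv` /
#' `truth_adequacy.csv` / `truth_mpa.csv`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$recalls, file.path(dir, "recalls.csv"))
  readr::write_csv(study$fct, file.path(dir, "fct.csv"))
  readr::write_csv(study$children, file.path(dir, "children.csv"))
  readr::write_csv(study$truth$usual, file.path(dir, "truth_usual.csv"))
  readr::write_csv(study$truth$adequacy, file.path(dir, "truth_adequacy.csv"))
  readr::write_csv(study$truth$mpa, file.path(dir, "truth_mpa.csv"))
  invisible(dir)
}
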