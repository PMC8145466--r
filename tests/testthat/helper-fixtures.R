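# shared fixtures; expensive synthetic studies are built once per run
fixture_env <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (is.null(fixture_env[[name]])) assign(name, maker(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# two-food toy FCT covering all nutrient columns
toy_fct <- function() {
  fct <- tibble::tibble(
    food_code = c("PORRIDGE", "FISH"),
    description = c("maize porridge", "small dried fish")
  )
  vals <- list(
    PORRIDGE = c(
      energy_kcal = 80, thiamine_mg = 0.05, riboflavin_mg = 0.03, niacin_mg = 0.5,
      vitB6_mg = 0.06, folate_ug = 10, vitB12_ug = 0, vitA_ug = 2, vitC_mg = 0,
      vitD_ug = 0, vitE_mg = 0.2, calcium_mg = 10, magnesium_mg = 30,
      iron_mg = 1.2, zinc_mg = 0.9
    ),
    FISH = c(
      energy_kcal = 300, thiamine_mg = 0.1, riboflavin_mg = 0.2, niacin_mg = 5,
      vitB6_mg = 0.3, folate_ug = 20, vitB12_ug = 6, vitA_ug = 30, vitC_mg = 0,
      vitD_ug = 10, vitE_mg = 1, calcium_mg = 2000, magnesium_mg = 200,
      iron_mg = 6, zinc_mg = 4
    )
  )
  for (nc in nutrient_cols()) {
    fct[[nc]] <- c(vals$PORRIDGE[[nc]], vals$FISH[[nc]])
  }
  fct$phytate_mg <- c(150, 0)
  fct
}

toy_recalls <- function() {
  tibble::tibble(
    child_id = c("A", "A", "B"),
    site_code = "T1",
    recall_date = as.Date(c("2011-03-07", "2011-03-07", "2011-05-02")),
    age_days = c(300, 300, 420),
    sex = c("F", "F", "M"),
    weight_kg = c(8.8, 8.8, 10.1),
    breastfed_today = c(TRUE, TRUE, FALSE),
    food_code = c("PORRIDGE", "FISH", "PORRIDGE"),
    amount_g = c(150, 20, 200)
  )
}

# direct lognormal cell generator, independent of simulate_study()
make_cell <- function(n_children, n_days, mu_log, sigma_b, sigma_w, seed) {
  set.seed(seed)
  ids <- sprintf("k%03d", seq_len(n_children))
  b <- rnorm(n_children, 0, sigma_b)
  tibble::tibble(
    child_id = rep(ids, each = n_days),
    truth_b = rep(b, each = n_days),
    intake = exp(mu_log + rep(b, each = n_days) + rnorm(n_children * n_days, 0, sigma_w)),
    sex = rep(sample(c("M", "F"), n_children, replace = TRUE), each = n_days),
    weekday = sample(1:7, n_children * n_days, replace = TRUE),
    month = sample(1:12, n_children * n_days, replace = TRUE)
  )
}

# 500-child single-bin study at the recovery-simulation conditions
recovery_study <- function() {
  cached("recovery_study", function() {
    cfg <- simulation_config(
      n_children = 500, recalls_per_bin = 4, seed = 101,
      site_scenario = "mixed", sigma2_between = 0.09, sigma2_within = 0.25,
      transform_lambda = 0, zero_day_prob = 0, bin_multiplier = 1,
      age_bins = default_age_bins()[1, ]
    )
    st <- simulate_study(cfg)
    st$child_days <- impute_breastmilk(compute_child_days(st$recalls, st$fct))
    st
  })
}

recovery_fit <- function() {
  cached("recovery_fit", function() {
    cd <- recovery_study()$child_days
    fit_intake_cell(tibble::tibble(
      child_id = cd$child_id, intake = cd$cf_zinc_mg,
      sex = cd$sex, weekday = cd$weekday, month = cd$month
    ))
  })
}

# heavily breastfed cohort run in both modes
breastfed_runs <- function() {
  cached("breastfed_runs", function() {
    st <- simulate_study(simulation_config(
      n_children = 60, seed = 202, bf_cessation_median_months = 30
    ))
    list(
      study = st,
      total = run_pipeline(st$recalls, st$fct),
      cf = run_pipeline(st$recalls, st$fct, cf_only = TRUE)
    )
  })
}

scenario_study <- function(scenario) {
  cached(paste0("scenario_", scenario), function() {
    st <- simulate_study(simulation_config(
      n_children = 200, seed = 303, site_scenario = scenario,
      bin_multiplier = 1, age_bins = default_age_bins()[1, ]
    ))
    st$child_days <- impute_breastmilk(compute_child_days(st$recalls, st$fct))
    st
  })
}
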