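test_that("molar ratios follow the definitional unit check", {
  # one mmol of phytate per one mmol of zinc
  expect_equal(molar_ratio(660, 65.38, "zinc"), 1)
  expect_equal(molar_ratio(0, 3, "zinc"), 0)
  expect_equal(molar_ratio(200, 3, "zinc"), 2 * molar_ratio(100, 3, "zinc"))
  expect_true(is.na(molar_ratio(100, 0, "zinc")))
  expect_equal(molar_ratio(660, 55.845, "iron"), 1)
})

test_that("zinc bioavailability classes honour the printed thresholds", {
  expect_equal(as.character(classify_zinc(16)), "low")
  expect_equal(as.character(classify_zinc(15.0001)), "low")
  expect_equal(as.character(classify_zinc(15)), "moderate") # boundary inclusive
  expect_equal(as.character(classify_zinc(10)), "moderate")
  expect_equal(as.character(classify_zinc(5)), "moderate")
  expect_equal(as.character(classify_zinc(4.999)), "high")
  expect_equal(as.character(classify_zinc(0)), "high")
})

test_that("EAR and SD derive from RNI = EAR + 2 SD", {
  d <- derive_normal_requirement(1.2, 0.10)
  expect_equal(d$ear, 1)
  expect_equal(d$sd, 0.1)
  # cv -> 0 limit: ear -> rni, and ear < rni always
  expect_equal(derive_normal_requirement(5, 1e-6)$ear, 5, tolerance = 1e-5)
  for (cv in seq(0.05, 0.9, by = 0.1)) {
    expect_lt(derive_normal_requirement(5, cv)$ear, 5)
  }
  expect_error(derive_normal_requirement(5, 1.2), "cv")
  expect_error(derive_normal_requirement(-1, 0.1), "rni")
})

test_that("normal-requirement PA is the requirement mass below the intake", {
  expect_equal(pa_normal(1, 1, 0.1), 0.5)
  expect_equal(pa_normal(1 + 1.96 * 0.1, 1, 0.1), 0.975, tolerance = 1e-3)
  # sampling oracle at modest size
  set.seed(3001)
  for (i in 1:5) {
    ear <- runif(1, 0.5, 50)
    sd <- ear * runif(1, 0.05, 0.3)
    eui <- ear * runif(1, 0.3, 2)
    mc <- mean(rnorm(2e5, ear, sd) <= eui)
    expect_equal(pa_normal(eui, ear, sd), mc, tolerance = 0.01)
  }
  expect_error(pa_normal(1, 1, 0), "sd")
})

test_that("tabulated iron PA interpolates and clamps", {
  toy <- tibble::tibble(percentile = c(0.25, 0.5, 0.75), intake = c(2, 3, 4))
  # scale 2: scaled intakes 4/6/8
  expect_equal(pa_iron(6, toy, scale = 2), 0.5)
  expect_equal(pa_iron(5, toy, scale = 2), 0.375) # hand interpolation
  expect_equal(pa_iron(1, toy, scale = 2), 0)
  expect_equal(pa_iron(100, toy, scale = 2), 1)
  bad <- tibble::tibble(percentile = c(0.5, 0.25, 0.75), intake = c(3, 2, 4))
  expect_error(pa_iron(5, bad), "increasing")
  # default config: PA at the scaled median quantile is one half
  req <- default_requirements()
  q <- dplyr::filter(req$iron, age_bin == "13-16")
  med <- q$intake[q$percentile == 0.5] * q$scale[1]
  expect_equal(pa_iron(med, q[, c("percentile", "intake")], q$scale[1]), 0.5)
})

test_that("AI threshold PA is a step function, inclusive at the threshold", {
  expect_equal(pa_ai(5, 5), 1)
  expect_equal(pa_ai(0, 5), 0)
  expect_equal(pa_ai(10, 5), 1)
  expect_error(pa_ai(1, 0), "ai")
})

test_that("zinc PA uses the class-specific requirement", {
  req <- default_requirements()
  zn <- dplyr::filter(req$specs, nutrient == "zinc_mg", age_bin == "13-16")
  low <- dplyr::filter(zn, bioavailability == "low")
  mod <- dplyr::filter(zn, bioavailability == "moderate")
  expect_gt(low$ear, mod$ear)
  eui <- 4
  expect_lt(pa_normal(eui, low$ear, low$sd), pa_normal(eui, mod$ear, mod$sd))
  expect_equal(pa_normal(low$ear, low$ear, low$sd), 0.5)
})

test_that("MPA is the exact arithmetic mean over the configured nutrients", {
  full <- setNames(rep(1, 14), micronutrients())
  expect_equal(mean_pa(full), 1)
  expect_equal(mean_pa(full * 0), 0)
  half <- setNames(rep(c(1, 0), 7), micronutrients())
  expect_equal(mean_pa(half), 0.5)
  expect_error(mean_pa(full[-1]), "thiamine_mg")
})

test_that("nutrient density is per 100 kcal and scale invariant", {
  expect_equal(nutrient_density(1.2, 600), 0.2)
  expect_equal(nutrient_density(2 * 1.2, 2 * 600), nutrient_density(1.2, 600))
  # density times energy/100 reconstructs the intake
  expect_equal(nutrient_density(3.3, 480) * 480 / 100, 3.3)
  expect_warning(out <- nutrient_density(1, 0), "zero energy")
  expect_true(is.na(out))
})

test_that("PA is non-decreasing in usual intake for every requirement kind", {
  euis <- seq(0, 20, by = 0.25)
  pn <- pa_normal(euis, 8, 1.5)
  expect_true(all(diff(pn) >= 0))
  toy <- tibble::tibble(percentile = c(0.1, 0.5, 0.9), intake = c(4, 8, 12))
  pi_ <- pa_iron(euis, toy, scale = 1.3)
  expect_true(all(diff(pi_) >= 0))
  pa <- pa_ai(euis, 8)
  expect_true(all(diff(pa) >= 0))
})

test_that("per-child bioavailability and adequacy assemble correctly", {
  runs <- breastfed_runs()
  adq <- runs$total$adequacy
  expect_equal(nrow(adq), 60 * 4)
  expect_true(all(adq$mpa >= 0 & adq$mpa <= 1))
  pa_cols <- paste0("pa_", micronutrients())
  expect_true(all(pa_cols %in% names(adq)))
  # MPA equals the row mean of the fourteen PAs, and is bounded by them
  pam <- as.matrix(adq[, pa_cols])
  expect_equal(adq$mpa, unname(rowMeans(pam)))
  expect_true(all(adq$mpa >= apply(pam, 1, min) & adq$mpa <= apply(pam, 1, max)))
  # densities: reconstructing the mean intake from density x energy
  cd <- runs$total$child_days
  mean_cf <- cd |>
    dplyr::filter(!is.na(age_bin)) |>
    dplyr::group_by(child_id, age_bin) |>
    dplyr::summarise(
      e = mean(cf_energy_kcal), zn = mean(cf_zinc_mg), .groups = "drop"
    )
  j <- dplyr::inner_join(adq, mean_cf, by = c("child_id", "age_bin"))
  expect_equal(j$density_zinc_mg * j$e / 100, j$zn)
})
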