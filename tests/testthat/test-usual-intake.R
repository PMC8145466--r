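test_that("balanced-design REML matches the one-way ANOVA estimator", {
  set.seed(2001)
  J <- 30
  n <- 4
  b <- rnorm(J, 0, 0.4)
  y <- 10 + rep(b, each = n) + rnorm(J * n, 0, 0.6)
  d <- tibble::tibble(
    child_id = rep(sprintf("c%02d", 1:J), each = n), intake = y,
    sex = "F", weekday = 1, month = 1
  )
  f <- suppressWarnings(fit_intake_cell(d, lambda = 1))
  cm <- tapply(y, d$child_id, mean)
  msw <- mean(tapply(y, d$child_id, function(g) sum((g - mean(g))^2) / (n - 1)))
  msb <- n * var(cm)
  expect_equal(f$sigma2_within, msw, tolerance = 1e-6)
  expect_equal(f$sigma2_between, (msb - msw) / n, tolerance = 1e-6)
})

test_that("variance components are recovered from lognormal repeated recalls", {
  d <- make_cell(200, 4, mu_log = 1, sigma_b = 0.3, sigma_w = 0.5, seed = 2002)
  f <- fit_intake_cell(d)
  expect_lt(abs(f$lambda), 0.25)
  expect_equal(f$sigma2_between, 0.09, tolerance = 0.25)
  expect_equal(f$sigma2_within, 0.25, tolerance = 0.25)
})

test_that("child-day predictions are BLUE plus BLUP and linear in covariates", {
  d <- make_cell(40, 4, mu_log = 1, sigma_b = 0.3, sigma_w = 0.4, seed = 2003)
  f <- fit_intake_cell(d)
  nd <- tibble::tibble(
    child_id = d$child_id[1], sex = d$sex[1], weekday = c(1, 3), month = 5
  )
  p <- predict_child_day(f, nd)
  # two days differing only in weekday differ exactly by the coefficient contrast
  expect_equal(unname(p[2] - p[1]), unname(f$beta[["weekday3"]]))
  expect_error(
    predict_child_day(f, dplyr::mutate(nd, child_id = "ghost")),
    "Unknown child"
  )
})

test_that("without heterogeneity all BLUPs vanish and children coincide", {
  set.seed(2004)
  # pure noise around a common mean: between-variance estimate ~ 0
  d <- tibble::tibble(
    child_id = rep(sprintf("c%02d", 1:40), each = 4),
    intake = exp(rnorm(160, 1, 0.4)),
    sex = "F", weekday = rep(1:4, 40), month = 6
  )
  f <- suppressWarnings(fit_intake_cell(d))
  expect_lt(f$sigma2_between, 0.01)
  if (f$sigma2_between == 0) {
    expect_true(all(abs(f$blups) < 1e-10))
    e <- eui_from_fit(f)
    # same covariate mix per child: EUIs essentially equal
    expect_lt(diff(range(e$eui)) / mean(e$eui), 0.05)
  }
})

test_that("EUIs are shrunken relative to observed child means", {
  d <- make_cell(100, 4, mu_log = 1.5, sigma_b = 0.3, sigma_w = 0.5, seed = 2005)
  f <- fit_intake_cell(d)
  e <- eui_from_fit(f)
  raw <- tapply(d$intake, d$child_id, mean)
  expect_lt(var(e$eui), var(raw))
  expect_true(all(e$eui >= 0))
  # ranking of EUIs tracks the true child effects
  truth <- tapply(d$truth_b, d$child_id, mean)
  expect_gt(cor(e$eui, truth[e$child_id], method = "spearman"), 0.5)
})

test_that("small or single-recall cells fall back to observed means and are flagged", {
  d <- make_cell(30, 1, mu_log = 1, sigma_b = 0.3, sigma_w = 0.5, seed = 2006)
  expect_message(f <- fit_intake_cell(d), "Unstable")
  expect_true(f$unstable)
  e <- eui_from_fit(f)
  raw <- tapply(d$intake, d$child_id, mean)
  expect_equal(e$eui, as.numeric(raw[e$child_id]))
  expect_true(all(e$unstable))
  # too few children
  d2 <- make_cell(5, 4, mu_log = 1, sigma_b = 0.3, sigma_w = 0.5, seed = 2007)
  expect_message(f2 <- fit_intake_cell(d2), "Unstable")
  expect_true(f2$unstable)
})

test_that("degenerate covariates are dropped with a warning", {
  d <- make_cell(30, 3, mu_log = 1, sigma_b = 0.2, sigma_w = 0.4, seed = 2008)
  d$sex <- "F"
  d$month <- 7
  expect_warning(f <- fit_intake_cell(d), "sex, month")
  expect_false(f$unstable)
  expect_false(any(grepl("sex|month", names(f$beta))))
})

test_that("constant cells warn and use observed means", {
  d <- tibble::tibble(
    child_id = rep(sprintf("c%02d", 1:20), each = 3), intake = 2.5,
    sex = "F", weekday = 1, month = 1
  )
  w <- capture_warnings(f <- fit_intake_cell(d))
  expect_match(w, "Constant", all = FALSE)
  e <- eui_from_fit(f)
  expect_equal(e$eui, rep(2.5, 20))
})

test_that("study-level estimation returns one EUI per child, cell and nutrient", {
  st <- breastfed_runs()
  e <- st$total$eui
  expect_setequal(unique(e$nutrient), nutrient_cols())
  counts <- dplyr::count(e, site_code, age_bin, nutrient)
  expect_true(all(counts$n == 60))
  expect_true(all(e$eui >= 0))
  expect_true(all(e$n_days >= 1))
})

test_that("tidy and glance expose coefficients and variance components", {
  d <- make_cell(30, 3, mu_log = 1, sigma_b = 0.2, sigma_w = 0.4, seed = 2009)
  f <- fit_intake_cell(d)
  td <- tidy(f)
  expect_true(all(c("sigma2_between", "sigma2_within") %in% td$term))
  gl <- glance(f)
  expect_equal(gl$n_children, 30)
  expect_equal(gl$n_days, 90)
  expect_false(gl$unstable)
  expect_output(print(f), "usual_intake_fit")
})
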