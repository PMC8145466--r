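#' Fit the usual-intake model for one site x age-bin x nutrient cell
#'
#' Repeated child-days within a cell are normalised by a Box-Cox power
#' transformation (power chosen by profile log-likelihood, zero intakes
#' handled by a 1e-6 shift applied to the whole cell) and modelled with a
#' random-intercept model
#' `g(intake) ~ sex + weekday + month + (1 | child)` fitted by REML. The
#' child random-effect variance is the between-person variance and the
#' residual variance the within-person (day-to-day) variance. Covariates
#' with fewer than two observed levels are dropped with a warning.
#'
#' Cells with fewer than `min_children` children or a median of fewer than
#' 2 days per child are not identifiable for the mixed model; they fall back
#' to observed per-child means and are flagged `unstable`.
#'
#' @param data tibble with columns `child_id`, `intake` (>= 0), `sex`,
#'   `weekday` (1-7), `month` (1-12).
#' @param min_children minimum number of children for a mixed-model fit.
#' @param lambda optional fixed Box-Cox power; `NULL` (default) selects it by
#'   profile log-likelihood.
#' @return an object of class `usual_intake_fit`: the Box-Cox power
#'   (`lambda`), shift constant, fixed effects, variance components
#'   (`sigma2_between`, `sigma2_within`), per-child BLUPs and shrinkage
#'   factors, and the fitted data.
#' @export
fit_intake_cell <- function(data, min_children = 10, lambda = NULL) {
  stopifnot(all(c("child_id", "intake", "sex", "weekday", "month") %in% names(data)))
  if (any(data$intake < 0)) abort("Intakes must be non-negative.")
  data <- mutate(data, child_id = as.character(.data$child_id))
  n_per_child <- table(data$child_id)
  n_children <- length(n_per_child)
  unstable <- n_children < min_children || median(n_per_child) < 2

  fallback <- function(reason) {
    means <- tapply(data$intake, data$child_id, mean)
    structure(
      list(
        unstable = TRUE, reason = reason,
        lambda = NA_real_, shift = NA_real_, beta = NULL,
        sigma2_between = NA_real_, sigma2_within = NA_real_,
        blups = NULL, child_means = means,
        n_per_child = setNames(as.integer(n_per_child), names(n_per_child)),
        child_ids = names(n_per_child), data = data
      ),
      class = "usual_intake_fit"
    )
  }
  if (unstable) {
    inform(sprintf(
      "Unstable cell (%d children, median %.0f days/child): falling back to observed child means.",
      n_children, median(n_per_child)
    ))
    return(fallback("unstable cell"))
  }

  sh <- add_zero_shift(data$intake)
  dat <- data |>
    mutate(
      sex = factor(.data$sex),
      weekday = factor(.data$weekday, levels = 1:7),
      month = factor(.data$month, levels = 1:12)
    )
  keep <- c("sex", "weekday", "month")[vapply(
    c("sex", "weekday", "month"),
    function(v) length(unique(dat[[v]])) >= 2, logical(1)
  )]
  dropped <- setdiff(c("sex", "weekday", "month"), keep)
  if (length(dropped)) {
    warn(paste0(
      "Covariate(s) with a single observed level dropped: ",
      paste(dropped, collapse = ", ")
    ))
  }
  dat <- droplevels(dat)
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  X <- model.matrix(stats::as.formula(paste("~", rhs)), dat)

  if (sd(sh$values) < 1e-12) {
    warn("Constant intakes in cell; using observed child means.")
    return(fallback("constant data"))
  }
  lambda <- lambda %||% select_lambda(sh$values, X)
  dat$y <- boxcox_transform(sh$values, lambda)

  fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | child_id)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      fml,
      data = dat, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("Mixed-model fit failed for cell; using observed child means.")
    return(fallback("lmer failure"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_b <- max(0, vc$vcov[vc$grp == "child_id"])
  sigma2_w <- vc$vcov[vc$grp == "Residual"]
  re <- lme4::ranef(fit)$child_id
  blups <- setNames(re[["(Intercept)"]], rownames(re))
  ids <- names(n_per_child)
  n_i <- as.integer(n_per_child)
  k_i <- if (sigma2_b > 0) sigma2_b / (sigma2_b + sigma2_w / n_i) else rep(0, length(ids))

  structure(
    list(
      unstable = FALSE, reason = NULL,
      lambda = lambda, shift = sh$shift,
      beta = lme4::fixef(fit),
      sigma2_between = sigma2_b, sigma2_within = sigma2_w,
      blups = blups[ids],
      shrinkage = setNames(k_i, ids),
      n_per_child = setNames(n_i, ids),
      child_ids = ids,
      formula_rhs = rhs,
      data = dat,
      model = fit
    ),
    class = "usual_intake_fit"
  )
}

#' Transformed-scale prediction for child-days (BLUE + BLUP)
#'
#' Each child-day's intake is predicted on the transformed scale as the sum
#' of the fixed-effect prediction at that day's covariates (BLUE) and the
#' child's shrunken random effect (BLUP).
#'
#' @param fit a `usual_intake_fit`.
#' @param newdata rows with `child_id`, `sex`, `weekday`, `month`; defaults
#'   to the fitted data. Unknown children are an error.
#' @return numeric vector of transformed-scale predictions.
#' @export
predict_child_day <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "usual_intake_fit"))
  if (fit$unstable) abort("Cell used the observed-means fallback; no model predictions.")
  nd <- newdata %||% fit$data
  nd <- mutate(nd,
    child_id = as.character(.data$child_id),
    sex = factor(.data$sex, levels = levels(fit$data$sex)),
    weekday = factor(.data$weekday, levels = levels(fit$data$weekday)),
    month = factor(.data$month, levels = levels(fit$data$month))
  )
  unknown <- setdiff(unique(nd$child_id), fit$child_ids)
  if (length(unknown)) {
    abort(paste0("Unknown child_id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  X <- model.matrix(stats::as.formula(paste("~", fit$formula_rhs)), nd)
  X <- X[, names(fit$beta), drop = FALSE]
  drop(X %*% fit$beta) + fit$blups[nd$child_id]
}

#' Estimated usual intake (EUI) per child from one fitted cell
#'
#' Child-day predictions (BLUE + BLUP) are carried back to the intake scale
#' with the bias-corrected inverse transform, using as correction variance
#' the variability unexplained by the prediction: the within-person residual
#' variance plus the share of between-person variance lost to BLUP shrinkage,
#' `sigma2_w + (1 - k_i) * sigma2_b` with
#' `k_i = sigma2_b / (sigma2_b + sigma2_w / n_i)`. The mean of a child's
#' back-transformed child-day predictions is their EUI. Fallback cells use
#' the observed per-child mean intake.
#'
#' @param fit a `usual_intake_fit`.
#' @return tibble with `child_id`, `eui`, `n_days`, `unstable`.
#' @export
eui_from_fit <- function(fit) {
  stopifnot(inherits(fit, "usual_intake_fit"))
  if (fit$unstable) {
    return(tibble::tibble(
      child_id = fit$child_ids,
      eui = as.numeric(fit$child_means[fit$child_ids]),
      n_days = as.integer(fit$n_per_child),
      unstable = TRUE
    ))
  }
  m <- predict_child_day(fit)
  v_child <- fit$sigma2_within + (1 - fit$shrinkage) * fit$sigma2_between
  v <- v_child[fit$data$child_id]
  x <- backtransform_bias_corrected(m, fit$lambda, v, fit$shift)
  agg <- tapply(x, fit$data$child_id, mean)
  tibble::tibble(
    child_id = fit$child_ids,
    eui = as.numeric(agg[fit$child_ids]),
    n_days = as.integer(fit$n_per_child[fit$child_ids]),
    unstable = FALSE
  )
}

#' Fit usual-intake models for every site x age bin x nutrient cell
#'
#' @param child_days tibble from [impute_breastmilk()] (or
#'   [compute_child_days()] for the complementary-food-only sensitivity mode).
#' @param nutrients intake columns to model (default energy + 14 nutrients).
#' @param mode `"total"` uses `total_*` intakes (breast milk included),
#'   `"cf"` uses `cf_*` (complementary foods only; the sensitivity analysis).
#' @param min_children passed to [fit_intake_cell()].
#' @return tibble with `site_code`, `age_bin`, `nutrient` and a `fit`
#'   list-column of `usual_intake_fit` objects.
#' @export
fit_usual_intake <- function(child_days, nutrients = nutrient_cols(),
                             mode = c("total", "cf"), min_children = 10) {
  mode <- match.arg(mode)
  prefix <- if (mode == "total") "total_" else "cf_"
  bad <- setdiff(paste0(prefix, nutrients), names(child_days))
  if (length(bad)) abort(paste0("Missing intake column(s): ", paste(bad, collapse = ", ")))
  cd <- filter(child_days, !is.na(.data$age_bin))
  cells <- cd |>
    group_by(.data$site_code, .data$age_bin) |>
    tidyr::nest() |>
    ungroup()
  tidyr::expand_grid(cells, nutrient = nutrients) |>
    mutate(fit = purrr::map2(.data$data, .data$nutrient, function(d, nu) {
      fit_intake_cell(
        tibble::tibble(
          child_id = d$child_id, intake = d[[paste0(prefix, nu)]],
          sex = d$sex, weekday = d$weekday, month = d$month
        ),
        min_children = min_children
      )
    })) |>
    select("site_code", "age_bin", "nutrient", "fit")
}

#' Estimated usual intakes for a whole study
#'
#' Convenience wrapper: fits every cell with [fit_usual_intake()] and binds
#' the per-child EUIs of [eui_from_fit()].
#'
#' @inheritParams fit_usual_intake
#' @param fits optional precomputed result of [fit_usual_intake()].
#' @return long tibble: `child_id`, `site_code`, `age_bin`, `nutrient`,
#'   `eui`, `n_days`, `unstable`.
#' @export
estimate_usual_intake <- function(child_days, nutrients = nutrient_cols(),
                                  mode = c("total", "cf"), min_children = 10,
                                  fits = NULL) {
  fits <- fits %||% fit_usual_intake(child_days, nutrients, mode, min_children)
  fits |>
    mutate(eui = purrr::map(.data$fit, eui_from_fit)) |>
    select(-"fit") |>
    tidyr::unnest("eui")
}

#' @export
print.usual_intake_fit <- function(x, ...) {
  if (x$unstable) {
    cat(sprintf(
      "<usual_intake_fit> fallback to observed child means (%s); %d children\n",
      x$reason, length(x$child_ids)
    ))
  } else {
    cat(sprintf(
      "<usual_intake_fit> lambda = %.2f, shift = %g; sigma2_between = %.4g, sigma2_within = %.4g; %d children, %d child-days\n",
      x$lambda, x$shift, x$sigma2_between, x$sigma2_within,
      length(x$child_ids), nrow(x$data)
    ))
  }
  invisible(x)
}

#' Tidy a usual-intake fit
#'
#' `tidy()` returns fixed effects and variance components; `glance()` a
#' one-row model summary.
#'
#' @param x a `usual_intake_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy usual_intake_fit
#' @export
tidy.usual_intake_fit <- function(x, ...) {
  if (x$unstable) {
    return(tibble::tibble(
      term = character(), type = character(), estimate = numeric()
    ))
  }
  dplyr::bind_rows(
    tibble::tibble(term = names(x$beta), type = "fixed", estimate = unname(x$beta)),
    tibble::tibble(
      term = c("sigma2_between", "sigma2_within"), type = "variance",
      estimate = c(x$sigma2_between, x$sigma2_within)
    )
  )
}

#' @rdname tidy.usual_intake_fit
#' @method glance usual_intake_fit
#' @export
glance.usual_intake_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, shift = x$shift,
    sigma2_between = x$sigma2_between, sigma2_within = x$sigma2_within,
    n_children = length(x$child_ids),
    n_days = if (is.null(x$data)) NA_integer_ else nrow(x$data),
    unstable = x$unstable
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
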