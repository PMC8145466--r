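#' Box-Cox power transformation
#'
#' `g(x) = ((x + c)^lambda - 1) / lambda` for `lambda != 0` and
#' `log(x + c)` at `lambda = 0`. The shift constant `c` makes intakes with
#' zero days strictly positive before transformation (see [add_zero_shift()]).
#'
#' @param x numeric vector of intakes (>= 0).
#' @param lambda Box-Cox power.
#' @param shift shift constant added before transforming (0 or 1e-6).
#' @return transformed values.
#' @examples
#' boxcox_transform(5, lambda = 1) # 4
#' boxcox_transform(exp(1), lambda = 0) # 1
#' @export
boxcox_transform <- function(x, lambda, shift = 0) {
  xs <- x + shift
  if (any(xs <= 0, na.rm = TRUE)) {
    abort(paste0(
      "Box-Cox transform needs strictly positive values; ",
      "add a shift constant (1e-6) for cells containing zero intakes."
    ))
  }
  if (abs(lambda) < 1e-8) log(xs) else (xs^lambda - 1) / lambda
}

#' Inverse Box-Cox transformation
#'
#' @param y transformed values.
#' @inheritParams boxcox_transform
#' @return values on the original scale (before subtracting `shift`).
#' @export
boxcox_inverse <- function(y, lambda, shift = 0) {
  if (abs(lambda) < 1e-8) {
    exp(y) - shift
  } else {
    base <- lambda * y + 1
    out <- rep(NA_real_, length(y))
    ok <- base > 0
    out[ok] <- base[ok]^(1 / lambda) - shift
    out
  }
}

#' Shift constant for cells containing zero intakes
#'
#' A constant of 1e-6 is added to every intake in a site x age-bin x nutrient
#' cell whenever that cell contains zero values, so the Box-Cox transform is
#' defined; the constant is subtracted again after back-transformation.
#'
#' @param x numeric vector of intakes for one cell (>= 0).
#' @return list with `values` (shifted) and `shift` (0 or 1e-6).
#' @export
add_zero_shift <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("Intakes must be non-negative; found negative values.")
  }
  shift <- if (any(x == 0, na.rm = TRUE)) 1e-6 else 0
  list(values = x + shift, shift = shift)
}

#' Select the Box-Cox power by profile log-likelihood
#'
#' Grid search over `lambda` in \[-2, 2\] (step 0.01), maximising the profile
#' log-likelihood of the fixed-effects linear model
#' `g(x) ~ covariates` (the child random effect is ignored at this step):
#' `ll(lambda) = -n/2 log(RSS(lambda)/n) + (lambda - 1) sum(log(x))`.
#'
#' @param x positive intakes (already shifted if the cell had zeros).
#' @param X design matrix of covariates (with intercept); defaults to
#'   intercept only.
#' @param grid candidate powers.
#' @return the selected `lambda`. Degenerate (constant) data return 1 with a
#'   warning.
#' @export
select_lambda <- function(x, X = NULL, grid = seq(-2, 2, by = 0.01)) {
  if (any(x <= 0)) abort("`x` must be strictly positive (apply the shift first).")
  n <- length(x)
  if (n < 2 || sd(x) < 1e-12) {
    warn("Constant intake values; lambda fixed at 1.")
    return(1)
  }
  if (is.null(X)) X <- matrix(1, n, 1)
  qrX <- qr(X)
  slog <- sum(log(x))
  # residual sums for all candidate powers in one pass through the fixed QR
  Y <- vapply(grid, function(l) boxcox_transform(x, l), numeric(n))
  R <- qr.resid(qrX, Y)
  rss <- colSums(R^2)
  ll <- -n / 2 * log(pmax(rss, 1e-300) / n) + (grid - 1) * slog
  grid[which.max(ll)]
}

#' Bias-corrected inverse Box-Cox of a model prediction
#'
#' A prediction `m` on the transformed scale is carried back to the intake
#' scale with a second-order Taylor correction for the residual variability
#' around the prediction:
#' `x = g^-1(m) + 0.5 * (g^-1)''(m) * sigma2`, then minus the shift constant,
#' floored at zero. With `lambda = 1` the inverse is affine and the correction
#' is exactly zero; with `lambda = 0` it equals `exp(m) * (1 + sigma2/2)`.
#'
#' @param m prediction(s) on the transformed scale.
#' @param lambda Box-Cox power of the fit.
#' @param sigma2 variance of the unexplained variability around `m` on the
#'   transformed scale (the within-person residual variance, plus any
#'   unexplained between-person variance when `m` is a shrunken prediction).
#' @param shift shift constant used in the forward transform.
#' @return intake-scale values (>= 0). Predictions outside the image of the
#'   transform (`lambda * m + 1 <= 0`) return 0 with a warning.
#' @export
backtransform_bias_corrected <- function(m, lambda, sigma2, shift = 0) {
  stopifnot(sigma2 >= 0)
  if (abs(lambda) < 1e-8) {
    out <- exp(m) * (1 + sigma2 / 2) - shift
  } else {
    base <- lambda * m + 1
    bad <- base <= 0
    if (any(bad)) {
      warn(sprintf(
        "%d prediction(s) outside the image of the Box-Cox transform; set to 0.",
        sum(bad)
      ))
      base[bad] <- NA_real_
    }
    ginv <- base^(1 / lambda)
    curv <- (1 - lambda) * base^(1 / lambda - 2)
    out <- ginv + 0.5 * curv * sigma2 - shift
    out[bad] <- 0
  }
  pmax(out, 0)
}
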