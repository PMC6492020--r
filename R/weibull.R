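# The two-parameter Weibull vulnerability model and its closed-form
# threshold algebra. The fitted curve is
#
#   PLC(psi) = 100 * (1 - exp(-(|psi| / b)^c)),   b, c > 0,
#
# with psi the xylem water potential in (negative) MPa, b the scale in MPa
# and c the dimensionless shape. PLC(0) = 0 is enforced structurally.

#' Weibull percentage loss of conductivity
#'
#' Evaluates the two-parameter Weibull vulnerability curve
#' \eqn{PLC(\Psi) = 100 (1 - \exp(-(|\Psi|/b)^c))}.
#'
#' @param psi_mpa Water potential, MPa (zero or negative; the absolute value
#'   is used so positive inputs are tolerated but discouraged).
#' @param scale_mpa Weibull scale \eqn{b} (MPa, > 0).
#' @param shape Weibull shape \eqn{c} (> 0).
#' @return PLC in percent, same length as `psi_mpa`.
#' @examples
#' plc_weibull(-2.51, 3.1, 1.8)
#' @export
plc_weibull <- function(psi_mpa, scale_mpa, shape) {
  assert_scalar_num(scale_mpa, "scale_mpa", 0, strict_lower = TRUE)
  assert_scalar_num(shape, "shape", 0, strict_lower = TRUE)
  100 * (1 - exp(-(abs(psi_mpa) / scale_mpa)^shape))
}

#' Construct a Weibull vulnerability fit object
#'
#' Low-level constructor used by [fit_weibull()] and
#' [weibull_from_thresholds()]. Not normally called directly.
#'
#' @param scale_mpa,shape Weibull parameters (MPa and dimensionless).
#' @param converged Logical convergence flag.
#' @param rss Residual sum of squares of the fit (NA when analytic).
#' @param n Number of observations behind the fit.
#' @param family Curve family label.
#' @param reason Optional explanation when `converged` is `FALSE`.
#' @return An object of class `weibull_fit`.
#' @export
weibull_fit <- function(scale_mpa, shape, converged = TRUE, rss = NA_real_,
                        n = NA_integer_, family = "weibull", reason = NULL) {
  if (isTRUE(converged)) {
    assert_scalar_num(scale_mpa, "scale_mpa", 0, strict_lower = TRUE)
    assert_scalar_num(shape, "shape", 0, strict_lower = TRUE)
  }
  structure(
    list(scale_mpa = scale_mpa, shape = shape, converged = isTRUE(converged),
         rss = rss, n = n, family = family, reason = reason),
    class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull vulnerability fit\n")
  if (!x$converged) {
    cat("  NOT converged:", x$reason %||% "unknown reason", "\n")
    return(invisible(x))
  }
  cat(sprintf("  scale b = %.4g MPa, shape c = %.4g\n", x$scale_mpa, x$shape))
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.4g on n = %d points\n", x$rss, x$n))
  cat(sprintf("  P12 = %.3f  P50 = %.3f  P88 = %.3f MPa\n",
              threshold_psi(x, 12), threshold_psi(x, 50), threshold_psi(x, 88)))
  invisible(x)
}

#' Water potential at a given percentage loss of conductivity
#'
#' Inverts the Weibull vulnerability curve:
#' \eqn{\Psi_p = -b\,(-\ln(1 - p/100))^{1/c}}. `threshold_psi(fit, 50)` is
#' the familiar P50.
#'
#' @param fit A `weibull_fit` (must be converged).
#' @param p_pct Loss percentage, strictly between 0 and 100. Vectorised.
#' @return Water potential(s) in MPa (negative).
#' @examples
#' f <- weibull_fit(3, 4)
#' threshold_psi(f, 50)  # -3 * log(2)^0.25
#' @export
threshold_psi <- function(fit, p_pct) {
  if (!inherits(fit, "weibull_fit")) stopf("`fit` must be a weibull_fit")
  if (!fit$converged) stopf("cannot extract thresholds from a non-converged fit")
  if (!is.numeric(p_pct) || any(!is.finite(p_pct)) ||
      any(p_pct <= 0) || any(p_pct >= 100))
    stopf("`p_pct` must lie strictly between 0 and 100")
  -fit$scale_mpa * (-log(1 - p_pct / 100))^(1 / fit$shape)
}

#' Solve the Weibull parameters from two printed thresholds
#'
#' Given two (p, \eqn{\Psi_p}) pairs, e.g. the P12 and P50 of a published
#' vulnerability table, recovers the unique two-parameter Weibull curve
#' passing through both. Used both to check the internal consistency of
#' published threshold triplets and to parameterise the synthetic-data
#' generator from published curves.
#'
#' @param psi_a,psi_b Thresholds in MPa (negative), at loss percentages
#'   `p_a` and `p_b`.
#' @param p_a,p_b Loss percentages in (0, 100), distinct.
#' @return A converged `weibull_fit`.
#' @examples
#' f <- weibull_from_thresholds(-1.83, -2.81, p_a = 12, p_b = 50)
#' threshold_psi(f, 88)
#' @export
weibull_from_thresholds <- function(psi_a, psi_b, p_a = 50, p_b = 88) {
  assert_scalar_num(psi_a, "psi_a", upper = 0, strict_upper = TRUE)
  assert_scalar_num(psi_b, "psi_b", upper = 0, strict_upper = TRUE)
  assert_scalar_num(p_a, "p_a", 0, 100, TRUE, TRUE)
  assert_scalar_num(p_b, "p_b", 0, 100, TRUE, TRUE)
  if (p_a == p_b) stopf("`p_a` and `p_b` must differ")
  if (abs(psi_a - psi_b) < 1e-12)
    stopf("thresholds must differ to identify the shape parameter")
  aa <- -log(1 - p_a / 100)  # (|psi_a|/b)^c
  ab <- -log(1 - p_b / 100)
  shape <- log(aa / ab) / log(abs(psi_a) / abs(psi_b))
  if (!is.finite(shape) || shape <= 0)
    stopf("thresholds are inconsistent with a Weibull curve (ordering?)")
  scale <- abs(psi_a) / aa^(1 / shape)
  weibull_fit(scale, shape, converged = TRUE, n = 2L)
}
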