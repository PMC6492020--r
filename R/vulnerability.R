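# Vulnerability-curve fitting: nonlinear least squares for the Weibull
# curve (multi-start, explicit convergence reporting), threshold
# extraction, nonparametric case-resampling bootstrap CIs and the
# CI-overlap comparison used to declare organ/method differences.

# RSS and analytic gradient in (log b, log c); the log parameterisation
# enforces positivity without constrained optimisation.
weibull_rss <- function(par, x, plc) {
  b <- exp(par[1]); cc <- exp(par[2])
  u <- (x / b)^cc
  sum((100 * (1 - exp(-u)) - plc)^2)
}

weibull_rss_grad <- function(par, x, plc) {
  b <- exp(par[1]); cc <- exp(par[2])
  u <- (x / b)^cc
  eu <- exp(-u)
  r <- 100 * (1 - eu) - plc
  lxb <- ifelse(x > 0, log(x / b), 0)
  dm_db <- -100 * eu * cc * u          # d model / d log b
  dm_dc <- 100 * eu * u * cc * lxb     # d model / d log c
  c(sum(2 * r * dm_db), sum(2 * r * dm_dc))
}

# Moment/linearisation start: regress log(-log(1 - plc/100)) on log|psi|
# over interior points.
weibull_start <- function(x, plc) {
  ok <- plc > 0.5 & plc < 99.5 & x > 0
  if (sum(ok) >= 2L && length(unique(x[ok])) >= 2L) {
    yy <- log(-log(1 - plc[ok] / 100))
    fit <- stats::lm.fit(cbind(1, log(x[ok])), yy)
    cc <- fit$coefficients[2]
    if (is.finite(cc) && cc > 0.05 && cc < 50) {
      b <- exp(-fit$coefficients[1] / cc)
      if (is.finite(b) && b > 0) return(unname(c(log(b), log(cc))))
    }
  }
  NULL
}

#' Fit a Weibull vulnerability curve
#'
#' Unweighted nonlinear least squares of PLC against water potential for
#' the curve \eqn{PLC = 100(1 - \exp(-(|\Psi|/b)^c))}. Optimisation runs
#' in log-parameter space from a linearised starting estimate plus a
#' multi-start grid (b over the quartiles of the observed |psi|, c in
#' {1, 2, 4, 8}); the best residual sum of squares wins, ties going to the
#' smaller shape. Failure to converge from every start, or degenerate data
#' (constant PLC), yields an explicit non-converged result — never a
#' silent estimate.
#'
#' @param points data.frame with columns `psi_mpa` (<= 0, not all equal)
#'   and `plc_pct` (within `[0, 100]`). Fewer than 4 points, or points on
#'   one side of the inflection only, are permitted with a warning.
#' @param start Optional `c(log_b, log_c)` used as the only start (plus
#'   grid fallback on failure); used internally to speed up bootstrap
#'   refits.
#' @return A [weibull_fit()] with `converged`, `rss` and `n` set.
#' @examples
#' pts <- generate_plc_observations(3, 4, 12, noise_sd_plc = 0, seed = 1)
#' fit_weibull(pts)
#' @export
fit_weibull <- function(points, start = NULL) {
  pts <- validate_curve_points(points)
  x <- abs(pts$psi_mpa); plc <- pts$plc_pct
  n <- length(x)
  if (n < 4L) warnf("fitting a 2-parameter curve to %d points", n)

  if (stats::sd(plc) < 1e-10)
    return(weibull_fit(NA_real_, NA_real_, converged = FALSE, n = n,
                       reason = sprintf("constant PLC (%.3g%%)", plc[1])))

  starts <- list()
  if (!is.null(start)) starts <- list(start)
  else {
    s0 <- weibull_start(x, plc)
    if (!is.null(s0)) starts <- list(s0)
    bq <- unique(stats::quantile(x[x > 0], c(0.25, 0.5, 0.75), names = FALSE))
    for (b in bq) for (cc in c(1, 2, 4, 8))
      starts <- c(starts, list(c(log(b), log(cc))))
  }

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, weibull_rss, gr = weibull_rss_grad, x = x, plc = plc,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o) || !all(is.finite(o$par))) next
    if (is.null(best) || o$value < best$value - 1e-9 ||
        (abs(o$value - best$value) <= 1e-9 && o$par[2] < best$par[2]))
      best <- o
  }
  if (is.null(best) && is.null(start))
    return(weibull_fit(NA_real_, NA_real_, converged = FALSE, n = n,
                       reason = "no start converged"))
  if (is.null(best))  # single-start path: retry with the full grid
    return(fit_weibull(points))

  b <- unname(exp(best$par[1])); cc <- unname(exp(best$par[2]))
  ok <- best$convergence == 0 && is.finite(best$value) &&
    b > 1e-4 && b < 1e3 && cc > 0.01 && cc < 1e3
  if (!ok)
    return(weibull_fit(NA_real_, NA_real_, converged = FALSE, n = n,
                       rss = best$value,
                       reason = "optimiser hit a parameter boundary or failed"))
  if (min(x) > threshold_abs(b, cc, 12) || max(x) < threshold_abs(b, cc, 50))
    warnf("observations cover only one side of the inflection region; thresholds are extrapolated")
  weibull_fit(b, cc, converged = TRUE, rss = best$value, n = n)
}

threshold_abs <- function(b, cc, p) b * (-log(1 - p / 100))^(1 / cc)

validate_curve_points <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("psi_mpa", "plc_pct") %in% names(points)))
    stopf("`points` needs columns psi_mpa and plc_pct")
  if (nrow(points) == 0L) stopf("no data: empty curve-point set")
  psi <- points$psi_mpa; plc <- points$plc_pct
  if (any(!is.finite(psi)) || any(!is.finite(plc)))
    stopf("non-finite values in curve points")
  if (any(psi > 1e-9)) stopf("water potentials must be <= 0 MPa")
  if (any(plc < -1e-8) || any(plc > 100 + 1e-8))
    stopf("PLC outside [0, 100]: range %.3g..%.3g", min(plc), max(plc))
  if (length(unique(psi)) == 1L)
    stopf("all observations share the same water potential")
  data.frame(psi_mpa = psi, plc_pct = pmin(100, pmax(0, plc)))
}

#' Bootstrap confidence intervals for vulnerability thresholds
#'
#' Nonparametric case resampling: observations (one plant, one potential)
#' are resampled with replacement, the Weibull refitted to each replicate
#' (started from the observed-data estimate) and percentile 2.5%/97.5%
#' intervals taken per threshold. Replicates that fail to converge are
#' dropped and counted; more than 50% failures is an error.
#'
#' @param points Curve points as in [fit_weibull()].
#' @param n_boot Number of bootstrap replicates (>= 200; default 1000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param probs Loss percentages of the reported thresholds.
#' @param fit Optional pre-computed observed-data fit.
#' @return A `threshold_set`: data.frame `thresholds` with columns `p`,
#'   `psi_mpa`, `ci_lo_mpa`, `ci_hi_mpa` (2.5% and 97.5% percentile
#'   bounds, lo the more negative), plus `n`, `n_boot`, `n_failed` and the
#'   observed fit.
#' @export
bootstrap_thresholds <- function(points, n_boot = 1000, seed = 1L,
                                 probs = c(12, 50, 88), fit = NULL) {
  if (n_boot < 200) stopf("`n_boot` must be >= 200")
  seed <- assert_seed(seed)
  pts <- validate_curve_points(points)
  fit <- fit %||% fit_weibull(pts)
  if (!fit$converged)
    stopf("observed-data fit did not converge: %s", fit$reason %||% "")
  start <- c(log(fit$scale_mpa), log(fit$shape))
  n <- nrow(pts)

  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(suppressWarnings(fit_weibull(pts[idx, ], start = start)),
                     error = function(e) NULL)
      if (is.null(bf) || !bf$converged) return(rep(NA_real_, length(probs)))
      threshold_psi(bf, probs)
    }, numeric(length(probs)))
  })
  boot <- matrix(boot, nrow = length(probs))
  failed <- colSums(is.na(boot)) > 0
  n_failed <- sum(failed)
  if (n_failed > n_boot / 2)
    stopf(paste0("bootstrap unstable: %d of %d replicates failed to ",
                 "converge (data too sparse or degenerate?)"),
          n_failed, n_boot)
  keep <- boot[, !failed, drop = FALSE]
  ci <- apply(keep, 1L, stats::quantile, probs = c(0.025, 0.975))
  thresholds <- data.frame(p = probs,
                           psi_mpa = threshold_psi(fit, probs),
                           ci_lo_mpa = ci[1, ], ci_hi_mpa = ci[2, ])
  structure(list(thresholds = thresholds, n = n, n_boot = n_boot,
                 n_failed = n_failed, fit = fit),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds (n = %d, %d bootstrap, %d failed):\n",
              x$n, x$n_boot, x$n_failed))
  th <- x$thresholds
  for (i in seq_len(nrow(th)))
    cat(sprintf("  P%-3d %7.3f MPa  [%.3f, %.3f]\n", th$p[i], th$psi_mpa[i],
                th$ci_lo_mpa[i], th$ci_hi_mpa[i]))
  invisible(x)
}

#' Fit a full vulnerability curve with bootstrap thresholds
#'
#' Convenience wrapper: validates and clamps the points, fits the curve
#' family and attaches bootstrap threshold CIs.
#'
#' @param points Curve points (`psi_mpa`, `plc_pct`).
#' @param organ,method Labels stored on the curve (`method` is
#'   `"microct"` or `"hydraulic"`).
#' @param family `"weibull"` (default) or `"sigmoid"` (three-parameter-free
#'   logistic alternative for sensitivity analysis; see Details).
#' @param n_boot,seed Bootstrap settings (see [bootstrap_thresholds()]).
#'
#' @details The sigmoid alternative fits
#' \eqn{PLC = 100 / (1 + \exp(-k(|\Psi| - |\Psi_{50}|)))}; unlike the
#' Weibull it does not pass through PLC = 0 at zero tension. Thresholds
#' are extracted analytically in both families. Bootstrap CIs are only
#' provided for the Weibull family.
#' @return A `vulnerability_curve`: points, fit, thresholds, labels.
#' @export
fit_vulnerability_curve <- function(points, organ = "organ",
                                    method = c("microct", "hydraulic"),
                                    family = c("weibull", "sigmoid"),
                                    n_boot = 1000, seed = 1L) {
  method <- match.arg(method)
  family <- match.arg(family)
  pts <- validate_curve_points(points)
  if (family == "weibull") {
    fit <- fit_weibull(pts)
    ths <- if (fit$converged)
      bootstrap_thresholds(pts, n_boot = n_boot, seed = seed, fit = fit)
    else NULL
  } else {
    fit <- fit_sigmoid(pts)
    ths <- NULL
  }
  structure(list(organ = organ, method = method, points = pts, fit = fit,
                 thresholds = ths),
            class = "vulnerability_curve")
}

#' @export
print.vulnerability_curve <- function(x, ...) {
  cat(sprintf("vulnerability_curve: %s / %s, %d points\n",
              x$organ, x$method, nrow(x$points)))
  print(x$fit)
  if (!is.null(x$thresholds)) print(x$thresholds)
  invisible(x)
}

# Logistic-sigmoid alternative (sensitivity analysis only).
fit_sigmoid <- function(points) {
  pts <- validate_curve_points(points)
  x <- abs(pts$psi_mpa); plc <- pts$plc_pct
  if (stats::sd(plc) < 1e-10)
    return(structure(list(x50 = NA_real_, k = NA_real_, converged = FALSE,
                          rss = NA_real_, n = length(x), family = "sigmoid",
                          reason = "constant PLC"),
                     class = "sigmoid_fit"))
  rss <- function(par) {
    m <- 100 / (1 + exp(-exp(par[2]) * (x - exp(par[1]))))
    sum((m - plc)^2)
  }
  best <- NULL
  for (x50 in stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
    for (k in c(0.5, 1, 2, 4)) {
      o <- tryCatch(stats::optim(c(log(max(x50, 1e-3)), log(k)), rss,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  if (is.null(best))
    return(structure(list(x50 = NA_real_, k = NA_real_, converged = FALSE,
                          rss = NA_real_, n = length(x), family = "sigmoid",
                          reason = "no start converged"),
                     class = "sigmoid_fit"))
  structure(list(x50 = exp(best$par[1]), k = exp(best$par[2]),
                 converged = best$convergence == 0, rss = best$value,
                 n = length(x), family = "sigmoid", reason = NULL),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) cat("sigmoid fit: NOT converged\n")
  else cat(sprintf("sigmoid fit: P50 = %.3f MPa, slope k = %.3g (RSS %.3g)\n",
                   -x$x50, x$k, x$rss))
  invisible(x)
}

#' Compare two vulnerability curves at a threshold
#'
#' Declares a significant difference iff the two 95% bootstrap confidence
#' intervals of the chosen threshold do not overlap — the standard
#' conservative CI-overlap criterion for bootstrap-based curve
#' comparisons.
#'
#' @param a,b `vulnerability_curve`s with bootstrap thresholds.
#' @param threshold One of 12, 50, 88 (or any `p` present in both
#'   threshold sets).
#' @return A `vc_comparison`: both CIs, the threshold difference and the
#'   verdict.
#' @export
compare_curves <- function(a, b, threshold = 50) {
  for (cur in list(a, b))
    if (!inherits(cur, "vulnerability_curve") || is.null(cur$thresholds))
      stopf("both curves must carry bootstrap thresholds")
  pick <- function(cur) {
    th <- cur$thresholds$thresholds
    row <- th[th$p == threshold, , drop = FALSE]
    if (nrow(row) != 1L) stopf("threshold P%g not available", threshold)
    row
  }
  ra <- pick(a); rb <- pick(b)
  ia <- sort(c(ra$ci_lo_mpa, ra$ci_hi_mpa))
  ib <- sort(c(rb$ci_lo_mpa, rb$ci_hi_mpa))
  signif <- ia[2] < ib[1] || ib[2] < ia[1]
  structure(list(threshold = threshold,
                 label_a = paste(a$organ, a$method, sep = "/"),
                 label_b = paste(b$organ, b$method, sep = "/"),
                 psi_a = ra$psi_mpa, ci_a = ia,
                 psi_b = rb$psi_mpa, ci_b = ib,
                 delta_mpa = ra$psi_mpa - rb$psi_mpa,
                 significant = signif),
            class = "vc_comparison")
}

#' @export
print.vc_comparison <- function(x, ...) {
  cat(sprintf("P%g comparison: %s %.3f [%.3f, %.3f] vs %s %.3f [%.3f, %.3f]\n",
              x$threshold, x$label_a, x$psi_a, x$ci_a[1], x$ci_a[2],
              x$label_b, x$psi_b, x$ci_b[1], x$ci_b[2]))
  cat(if (x$significant) "  -> significantly different (95% CIs disjoint)\n"
      else "  -> not significantly different (95% CIs overlap)\n")
  invisible(x)
}

#' Plot a vulnerability curve
#'
#' Observations, fitted Weibull curve and threshold verticals with their
#' bootstrap CIs.
#'
#' @param x A `vulnerability_curve`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.vulnerability_curve <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$psi_mpa, pts$plc_pct, xlab = "Water potential (MPa)",
                 ylab = "PLC (%)", ylim = c(0, 100),
                 main = sprintf("%s (%s)", x$organ, x$method), ...)
  if (inherits(x$fit, "weibull_fit") && x$fit$converged) {
    xx <- seq(min(pts$psi_mpa), 0, length.out = 200)
    graphics::lines(xx, plc_weibull(xx, x$fit$scale_mpa, x$fit$shape))
    if (!is.null(x$thresholds)) {
      th <- x$thresholds$thresholds
      graphics::abline(v = th$psi_mpa[th$p == 50], lty = 1)
      graphics::abline(v = unlist(th[th$p == 50, c("ci_lo_mpa", "ci_hi_mpa")]),
                       lty = 2)
    }
  }
  invisible(x)
}
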