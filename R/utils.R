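# Internal helpers: argument checking, seeded evaluation, truncated sampling.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

assert_seed <- function(seed, name = "seed") {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stopf("`%s` must be a single integer", name)
  invisible(as.integer(seed))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded operations do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  seed <- assert_seed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Inverse-CDF sampling from a lognormal truncated to [lo, hi].
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  if (phi - plo < 1e-12)
    stopf("truncation bounds [%g, %g] leave no probability mass", lo, hi)
  u <- stats::runif(n, plo, phi)
  stats::qlnorm(u, meanlog, sdlog)
}

# Format doubles so a write -> read round trip is lossless (17 significant
# digits is enough to reproduce any IEEE double exactly).
format_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
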