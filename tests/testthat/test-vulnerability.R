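# Curve fitting, bootstrap thresholds, comparisons.

test_that("noiseless data are recovered to 1e-6 relative", {
  for (par in list(c(3, 4), c(1.5, 1.2), c(4.5, 7))) {
    fit <- fit_weibull(dense_points(par[1], par[2]))
    expect_true(fit$converged)
    expect_rel_equal(fit$scale_mpa, par[1], 1e-6)
    expect_rel_equal(fit$shape, par[2], 1e-6)
  }
})

test_that("round trip through generate_plc_observations is exact", {
  obs <- generate_plc_observations(3, 4, 30, c(-8, 0), noise_sd_plc = 0,
                                   seed = 2)
  fit <- fit_weibull(obs)
  expect_rel_equal(fit$scale_mpa, 3, 1e-6)
  expect_rel_equal(fit$shape, 4, 1e-6)
})

test_that("degenerate inputs give explicit non-convergence or errors", {
  flat <- data.frame(psi_mpa = seq(-4, -1, length.out = 6), plc_pct = 0)
  fit <- fit_weibull(flat)
  expect_false(fit$converged)
  expect_match(fit$reason, "constant")
  expect_error(fit_weibull(data.frame(psi_mpa = rep(-2, 5),
                                      plc_pct = 1:5 * 10)), "same water")
  expect_error(fit_weibull(data.frame(psi_mpa = c(-1, -2),
                                      plc_pct = c(20, 150))), "outside")
  expect_error(fit_weibull(data.frame(psi_mpa = numeric(0),
                                      plc_pct = numeric(0))), "no data")
  expect_warning(fit_weibull(data.frame(psi_mpa = c(-1, -2, -3),
                                        plc_pct = c(10, 50, 90))),
                 "3 points")
})

test_that("converged fits always order their thresholds", {
  set.seed(7)
  for (i in 1:15) {
    obs <- generate_plc_observations(runif(1, 1, 4), runif(1, 1, 6), 12,
                                     c(-8, 0), 8, seed = 900 + i)
    fit <- suppressWarnings(fit_weibull(obs))
    if (!fit$converged) next
    th <- threshold_psi(fit, c(12, 50, 88))
    expect_true(th[1] > th[2] && th[2] > th[3])
  }
})

test_that("bootstrap thresholds are reproducible and contain the estimate", {
  obs <- generate_plc_observations(3, 2, 14, c(-6, 0), 5, seed = 3)
  b1 <- bootstrap_thresholds(obs, n_boot = 200, seed = 10)
  b2 <- bootstrap_thresholds(obs, n_boot = 200, seed = 10)
  expect_identical(b1$thresholds, b2$thresholds)
  th <- b1$thresholds
  expect_true(all(th$ci_lo_mpa <= th$psi_mpa & th$psi_mpa <= th$ci_hi_mpa))
  expect_true(all(th$ci_lo_mpa <= th$ci_hi_mpa))
})

test_that("bootstrap CI width collapses as noise vanishes", {
  width50 <- sapply(c(8, 2, 0.25), function(sd) {
    obs <- generate_plc_observations(3, 2, 16, c(-6, 0), sd, seed = 5)
    th <- bootstrap_thresholds(obs, n_boot = 200, seed = 5)$thresholds
    diff(unlist(th[th$p == 50, c("ci_lo_mpa", "ci_hi_mpa")]))
  })
  expect_true(all(diff(width50) < 0))
  expect_lt(width50[3], 0.1)
})

test_that("hopeless bootstraps error out with diagnostics", {
  # one informative point among zeros: most resamples are degenerate
  pts <- data.frame(psi_mpa = c(-0.2, -0.3, -0.4, -0.5, -6),
                    plc_pct = c(0, 0, 0, 0, 90))
  expect_error(suppressWarnings(
    bootstrap_thresholds(pts, n_boot = 200, seed = 2)),
    "unstable|did not converge")
  expect_error(bootstrap_thresholds(dense_points(3, 2), n_boot = 50),
               ">= 200")
})

test_that("CI-overlap comparison separates distinct organs only", {
  # published Acer petiole (P50 -1.13) vs stem (-2.51) at published n
  pet_gen <- weibull_from_thresholds(-1.13, -3.01, 50, 88)
  stem_gen <- weibull_from_thresholds(-2.51, -4.69, 50, 88)
  pet <- fit_vulnerability_curve(
    generate_plc_observations(pet_gen$scale_mpa, pet_gen$shape, 10,
                              c(-4, 0), 5, seed = 21),
    organ = "petiole", n_boot = 200, seed = 21)
  stem <- fit_vulnerability_curve(
    generate_plc_observations(stem_gen$scale_mpa, stem_gen$shape, 15,
                              c(-5, 0), 5, seed = 22),
    organ = "stem", n_boot = 200, seed = 22)
  cmp <- compare_curves(pet, stem, threshold = 50)
  expect_true(cmp$significant)
  # identical curves can never be significant
  cmp0 <- compare_curves(pet, pet, threshold = 50)
  expect_false(cmp0$significant)
  expect_error(compare_curves(pet, stem, threshold = 33), "not available")
})

test_that("the sigmoid alternative fits and reports its P50", {
  obs <- generate_plc_observations(3, 3, 20, c(-7, 0), 2, seed = 31)
  vc <- fit_vulnerability_curve(obs, family = "sigmoid")
  expect_s3_class(vc$fit, "sigmoid_fit")
  expect_true(vc$fit$converged)
  expect_lt(abs(-vc$fit$x50 - threshold_psi(weibull_fit(3, 3), 50)), 0.4)
})
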