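# Synthetic cross-section generator: determinism, limit cases, embolism
# statistics, density/diameter fidelity, error paths.

test_that("generation is bit-exact reproducible for a fixed seed", {
  cfg <- small_config(noise_sd = 0.03)
  a <- generate_cross_section(cfg, -2, seed = 5)
  b <- generate_cross_section(cfg, -2, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$conduits, b$truth$conduits)
  d <- generate_cross_section(cfg, -2, seed = 6)
  expect_false(identical(a$truth$conduits$x_um, d$truth$conduits$x_um))
})

test_that("limit potentials: none vs all embolised, final-scan identity", {
  cfg <- small_config(noise_sd = 0.02)
  wet <- generate_cross_section(cfg, 0, seed = 3)
  expect_true(all(wet$truth$conduits$state == "water"))
  dry <- generate_cross_section(cfg, -1e6, seed = 3)
  expect_true(all(dry$truth$conduits$state == "air"))
  # fully dry initial scan is byte-identical to the final scan (same
  # geometry and same seeded noise field)
  expect_identical(dry$image, generate_final_scan(dry$truth, cfg))
  expect_identical(generate_final_scan(wet$truth, cfg),
                   generate_final_scan(wet$truth, cfg))
})

test_that("air-filled sets are nested as potential decreases", {
  cfg <- small_config()
  psis <- c(-0.5, -1.5, -2.5, -4, -7)
  prev <- integer(0)
  for (psi in psis) {
    cs <- generate_cross_section(cfg, psi, seed = 9)
    air <- cs$truth$conduits$id[cs$truth$conduits$state == "air"]
    expect_true(all(prev %in% air))
    prev <- air
  }
})

test_that("embolised fraction converges to the Weibull CDF", {
  cfg <- small_config()
  psi <- -2
  p_true <- 1 - exp(-(abs(psi) / cfg$weibull_scale_mpa)^cfg$weibull_shape)
  n_air <- n_tot <- 0
  for (s in 1:150) {
    cs <- generate_cross_section(cfg, psi, seed = 4000 + s)
    n_air <- n_air + sum(cs$truth$conduits$state == "air")
    n_tot <- n_tot + nrow(cs$truth$conduits)
  }
  se <- sqrt(p_true * (1 - p_true) / n_tot)
  expect_lt(abs(n_air / n_tot - p_true), 3 * se)
})

test_that("realised density and diameters track the configured targets", {
  presets <- organ_presets(noise_sd = 0)
  cfg <- presets$fagus_stem  # VD target 314.4 /mm^2, d_h target 23.72 um
  vd <- dh <- numeric(5)
  for (s in 1:5) {
    tr <- generate_cross_section(cfg, -1, seed = 100 + s)$truth
    vd[s] <- nrow(tr$conduits) / tr$xylem_area_mm2
    dh[s] <- hydraulic_diameter(tr$conduits$d_um)
  }
  expect_lt(abs(mean(vd) - 314.4) / 314.4, 0.10)
  expect_lt(abs(mean(dh) - 23.72) / 23.72, 0.10)
})

test_that("threshold draws are independent of conduit diameter", {
  cfg <- small_config()
  xs <- ys <- numeric(0)
  for (s in 1:40) {
    tr <- generate_cross_section(cfg, -1, seed = 700 + s)$truth$conduits
    xs <- c(xs, tr$d_um); ys <- c(ys, tr$threshold_psi_mpa)
  }
  expect_lt(abs(stats::cor(xs, ys)), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(noise_sd = -1), "noise_sd")
  expect_error(organ_sim_config(gray_levels = c(0.45, 0.3, 0.7)),
               "darker")
  expect_error(organ_sim_config(
    diameter_dist = list(family = "lognormal", meanlog = 2, sdlog = 0.3,
                         min_um = 30, max_um = 10)), "ordered")
  expect_error(organ_sim_config(
    vessel_density_per_mm2 = 4000,
    diameter_dist = diameter_dist_lognormal(17, 24)), "packing")
})

test_that("impossible packings fail with an informative error", {
  cfg <- organ_sim_config(
    image_size_px = 128L, pixel_size_um = 2,
    xylem_region = list(type = "disc", radius_um = 70),
    vessel_density_per_mm2 = 540,
    diameter_dist = list(family = "uniform", min_um = 30, max_um = 30),
    weibull_scale_mpa = 3, weibull_shape = 2)
  expect_error(generate_cross_section(cfg, -1, seed = 2),
               "placement failed.*achieved density")
})

test_that("generate_plc_observations honours its contract", {
  # exact P50 with zero noise
  b <- 3; cc <- 4
  psi50 <- -b * log(2)^(1 / cc)
  obs <- generate_plc_observations(b, cc, 10, c(psi50 - 1e-9, psi50 + 1e-9),
                                   noise_sd_plc = 0, seed = 2)
  expect_equal(obs$plc_pct, rep(50, 10), tolerance = 1e-6)
  # determinism and clamping
  a1 <- generate_plc_observations(2, 3, 25, c(-8, 0), 30, seed = 4)
  a2 <- generate_plc_observations(2, 3, 25, c(-8, 0), 30, seed = 4)
  expect_identical(a1, a2)
  expect_true(all(a1$plc_pct >= 0 & a1$plc_pct <= 100))
  expect_error(generate_plc_observations(-1, 2, 10), "b_w")
  expect_error(generate_plc_observations(2, 2, 3), ">= 4")
  expect_error(generate_plc_observations(2, 2, 10, c(-12, 0)), "psi_range")
})
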