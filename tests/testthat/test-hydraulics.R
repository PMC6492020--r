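# Hagen-Poiseuille conductance, PLC definitions, viscosity correction.

test_that("theoretical conductance scales with d^4 and is additive", {
  k1 <- theoretical_conductance(10)
  expect_equal(theoretical_conductance(20), 16 * k1, tolerance = 1e-12)
  expect_equal(theoretical_conductance(c(10, 20)),
               k1 + theoretical_conductance(20), tolerance = 1e-12)
  # permutation invariance / additivity over partitions
  set.seed(4)
  d <- runif(30, 5, 40)
  expect_equal(theoretical_conductance(d),
               theoretical_conductance(d[1:10]) +
               theoretical_conductance(d[11:30]), tolerance = 1e-12)
  expect_equal(theoretical_conductance(sample(d)),
               theoretical_conductance(d), tolerance = 1e-12)
})

test_that("conductance of a 20-um conduit matches the unit-tracked value", {
  expect_equal(theoretical_conductance(20, per = "Pa"), 3.912e-15,
               tolerance = 1e-4)
  expect_equal(theoretical_conductance(20, per = "MPa"), 3.912e-9,
               tolerance = 1e-4)
  expect_equal(theoretical_conductance(numeric(0)), 0)
  expect_error(theoretical_conductance(c(10, -5)), "non-negative")
})

test_that("specific conductivity normalises by xylem area", {
  expect_equal(specific_conductivity(0, 1), 0)
  k <- specific_conductivity(3e-9, 0.8)
  expect_equal(specific_conductivity(3e-9, 1.6), k / 2)
  expect_error(specific_conductivity(1, 0), "xylem_area")
})

test_that("preset stem configuration lands near the published K_st", {
  # published Acer stem K_st = 0.95 kg m^-1 MPa^-1 s^-1
  cfg <- organ_presets(noise_sd = 0)$acer_stem
  kst <- sapply(1:5, function(s) {
    tr <- generate_cross_section(cfg, -1, seed = 300 + s)$truth
    specific_conductivity(theoretical_conductance(tr$conduits$d_um),
                          tr$xylem_area_mm2)
  })
  expect_lt(abs(mean(kst) - 0.95) / 0.95, 0.20)
})

test_that("hydraulic PLC covers its trivial and clamped cases", {
  expect_equal(as.numeric(plc_hydraulic(1, 1)), 0)
  expect_equal(as.numeric(plc_hydraulic(0, 1)), 100)
  expect_equal(as.numeric(plc_hydraulic(0.25, 1.0)), 75)
  # noise can push Ki above Ks: clamped to 0, raw value retained
  p <- plc_hydraulic(1.1, 1.0)
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "raw"), -10, tolerance = 1e-10)
  expect_error(plc_hydraulic(1, 0), "ks")
})

test_that("theoretical PLC from scan pairs matches the d^4 ratio", {
  fin <- manual_map(c(50, 100), c(50, 50), c(10, 20))
  ini_all_water <- manual_map(numeric(0), numeric(0), numeric(0))
  p0 <- match_scan_pair(ini_all_water, fin, psi_mpa = 0)
  expect_equal(plc_theoretical(p0), 0)
  p_all <- match_scan_pair(fin, fin, psi_mpa = -9)
  expect_equal(plc_theoretical(p_all), 100)
  # only the 20-um conduit embolised
  ini <- manual_map(100, 50, 20)
  p1 <- match_scan_pair(ini, fin, psi_mpa = -2)
  expect_equal(plc_theoretical(p1), 100 * 20^4 / (10^4 + 20^4))
  expect_equal(plc_theoretical(p1), 94.12, tolerance = 1e-3)
  pair <- scan_pair_conductance(p1)
  expect_equal(pair$kt_initial, pair$kt_final -
                 theoretical_conductance(20), tolerance = 1e-15)
})

test_that("PLC_t responds monotonically to conduit removal", {
  # removing a water-filled conduit increases PLC_t; removing an
  # embolised one decreases it
  fin <- manual_map(c(50, 100, 150), c(50, 50, 50), c(15, 20, 25))
  ini <- manual_map(100, 50, 20)  # the 20-um conduit is embolised
  base <- plc_theoretical(match_scan_pair(ini, fin, psi_mpa = -2))
  fin_less_water <- manual_map(c(50, 100), c(50, 50), c(15, 20))
  up <- plc_theoretical(match_scan_pair(ini, fin_less_water, psi_mpa = -2))
  expect_gt(up, base)
  fin_less_emb <- manual_map(c(50, 150), c(50, 50), c(15, 25))
  ini_none <- manual_map(numeric(0), numeric(0), numeric(0))
  down <- plc_theoretical(match_scan_pair(ini_none, fin_less_emb,
                                          psi_mpa = -2))
  expect_lt(down, base)
})

test_that("PLC_t is non-decreasing along a dehydration series", {
  cfg <- small_config()
  plc <- sapply(c(-0.5, -1.5, -2.5, -4, -6), function(psi) {
    cs <- generate_cross_section(cfg, psi, seed = 111)
    ini <- segment_air_conduits(cs$image,
                                xylem_area_mm2 = cs$truth$xylem_area_mm2)
    fin <- segment_air_conduits(generate_final_scan(cs$truth, cfg),
                                xylem_area_mm2 = cs$truth$xylem_area_mm2)
    plc_theoretical(match_scan_pair(ini, fin, psi_mpa = psi))
  })
  expect_true(all(diff(plc) >= 0))
})

test_that("viscosity correction is anchored at 20 C and monotone", {
  expect_equal(viscosity_correct(1, 20), 1)
  expect_equal(viscosity_correct(1, 25), 0.8895, tolerance = 1e-3)
  tt <- seq(5, 45, by = 5)
  factors <- viscosity_correct(1, tt)
  expect_true(all(diff(factors) < 0))
  expect_error(viscosity_correct(1, 55), "temperature")
  expect_error(viscosity_correct(1, 0), "temperature")
})

test_that("hydraulic sample tables are corrected then converted to PLC", {
  df <- data.frame(psi_mpa = c(-1, -2), ki = c(0.8, 0.2), ks = c(1, 1),
                   temperature_c = c(21.5, 21.5))
  out <- process_hydraulic_samples(df)
  # same temperature for ki and ks: the correction cancels in the ratio
  expect_equal(out$plc_pct, c(20, 80), tolerance = 1e-10)
  expect_true(all(out$ki_20 < df$ki))
  expect_error(process_hydraulic_samples(data.frame(psi_mpa = -1, ki = 1)),
               "needs columns")
})
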