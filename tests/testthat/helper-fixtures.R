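# Shared fixtures: a small, fast synthetic organ and tiny hand-built
# conduit maps. Everything is generated in code; no binary fixtures.

small_config <- function(noise_sd = 0, density = 250, seed = 1L, ...) {
  organ_sim_config(
    organ_label = "test_organ",
    image_size_px = 160L, pixel_size_um = 2,
    xylem_region = list(type = "disc", radius_um = 140),
    vessel_density_per_mm2 = density,
    diameter_dist = diameter_dist_lognormal(15, 20, min_um = 8, max_um = 34),
    weibull_scale_mpa = 3, weibull_shape = 2,
    noise_sd = noise_sd, seed = seed, ...)
}

# Conduit map built directly from coordinates/diameters (bypasses images).
manual_map <- function(x, y, d, area_mm2 = 1, state = "air", px = 2) {
  n <- length(x)
  conduits <- data.frame(
    id = seq_len(n), x_um = x, y_um = y,
    area_um2 = pi * (d / 2)^2, d_um = d,
    state = rep_len(state, n), border = rep(FALSE, n),
    stringsAsFactors = FALSE)
  xylemct:::new_conduit_map(conduits, area_mm2, px, "manual")
}

# Noise-free PLC points densely covering a Weibull curve.
dense_points <- function(b, cc, n = 40, lo = -8) {
  psi <- seq(lo, -0.05, length.out = n)
  data.frame(psi_mpa = psi, plc_pct = plc_weibull(psi, b, cc))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
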