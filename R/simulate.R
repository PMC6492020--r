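# Synthetic cross-section and dehydration-experiment generator.
#
# The generator renders a single micro-CT-like slice: circular conduit
# lumens packed without overlap inside a disc (or annulus) of xylem, on a
# uniform background. Each conduit carries an embolism-threshold water
# potential drawn from a Weibull distribution; at simulation potential psi
# a conduit is air-filled (dark) iff psi <= threshold. This is the ground
# truth against which segmentation and the downstream hydraulics are
# validated.

#' Simulation configuration for a synthetic organ cross-section
#'
#' Bundles and validates all generative parameters for one organ. Gray
#' levels follow phase-contrast micro-CT: air-filled lumens are dark,
#' water-filled lumens light, background (walls/parenchyma) intermediate.
#'
#' @param organ_label Free-text organ name.
#' @param image_size_px Integer pair (rows, cols) or a single integer for a
#'   square frame.
#' @param pixel_size_um Pixel edge length, micrometres (default 2).
#' @param xylem_region A list: `list(type = "disc", radius_um = r)` or
#'   `list(type = "annulus", r_inner_um = a, r_outer_um = b)`, centred in
#'   the frame. Conduits are placed entirely inside this region, which also
#'   defines the xylem cross-sectional area used for vessel density.
#' @param vessel_density_per_mm2 Target conduit density (mm^-2). The number
#'   of conduits placed is `round(density * area)` (deterministic).
#' @param diameter_dist Lumen-diameter distribution:
#'   `list(family = "lognormal", meanlog, sdlog, min_um, max_um)` or
#'   `list(family = "uniform", min_um, max_um)`. Diameters in micrometres.
#'   See [diameter_dist_lognormal()] to calibrate from a target mean and
#'   hydraulically weighted diameter.
#' @param weibull_scale_mpa,weibull_shape Parameters of the Weibull
#'   distribution of per-conduit embolism thresholds (thresholds are the
#'   negated draws, i.e. negative MPa).
#' @param gray_levels Numeric triple `c(background, water, air)` in `[0, 1]`
#'   with `air < water` (defaults 0.45 / 0.75 / 0.10).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (image clipped back to `[0, 1]`).
#' @param min_wall_px Minimum wall between neighbouring lumens and to the
#'   region border, in pixels (default 2; guarantees 8-connected
#'   separability of rendered lumens).
#' @param seed Default integer seed used when the generating functions are
#'   called without one.
#' @return An object of class `organ_sim_config`.
#' @examples
#' cfg <- organ_sim_config(vessel_density_per_mm2 = 300,
#'                         diameter_dist = diameter_dist_lognormal(17, 24))
#' @export
organ_sim_config <- function(organ_label = "organ",
                             image_size_px = c(512L, 512L),
                             pixel_size_um = 2,
                             xylem_region = list(type = "disc",
                                                 radius_um = 480),
                             vessel_density_per_mm2 = 300,
                             diameter_dist = diameter_dist_lognormal(17, 24),
                             weibull_scale_mpa = 3,
                             weibull_shape = 2,
                             gray_levels = c(background = 0.45,
                                             water = 0.75, air = 0.10),
                             noise_sd = 0,
                             min_wall_px = 2,
                             seed = 1L) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  image_size_px <- as.integer(image_size_px)
  if (any(image_size_px < 8L)) stopf("image_size_px must be >= 8 in both axes")
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  assert_scalar_num(vessel_density_per_mm2, "vessel_density_per_mm2", 0,
                    strict_lower = TRUE)
  assert_scalar_num(weibull_scale_mpa, "weibull_scale_mpa", 0,
                    strict_lower = TRUE)
  assert_scalar_num(weibull_shape, "weibull_shape", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(min_wall_px, "min_wall_px", 0)
  seed <- assert_seed(seed)

  gl <- unname(gray_levels)
  if (length(gl) != 3L || any(!is.finite(gl)) || any(gl < 0) || any(gl > 1))
    stopf("gray_levels must be three values in [0, 1]")
  if (gl[3] >= gl[2])
    stopf("air gray level (%g) must be darker than water (%g)", gl[3], gl[2])

  dd <- validate_diameter_dist(diameter_dist)
  region <- validate_region(xylem_region, image_size_px, pixel_size_um)

  cfg <- structure(
    list(organ_label = as.character(organ_label)[1],
         image_size_px = image_size_px, pixel_size_um = pixel_size_um,
         xylem_region = region,
         vessel_density_per_mm2 = vessel_density_per_mm2,
         diameter_dist = dd,
         weibull_scale_mpa = weibull_scale_mpa,
         weibull_shape = weibull_shape,
         gray_levels = c(background = gl[1], water = gl[2], air = gl[3]),
         noise_sd = noise_sd, min_wall_px = min_wall_px, seed = seed),
    class = "organ_sim_config")

  pf <- packing_fraction(cfg)
  if (pf >= 0.5)
    stopf(paste0("configuration implies packing fraction %.2f >= 0.5; ",
                 "reduce vessel density or diameters"), pf)
  cfg
}

#' @export
print.organ_sim_config <- function(x, ...) {
  cat(sprintf("organ_sim_config '%s': %dx%d px @ %g um/px\n", x$organ_label,
              x$image_size_px[1], x$image_size_px[2], x$pixel_size_um))
  cat(sprintf("  region %s, area %.4f mm^2; VD target %g /mm^2\n",
              x$xylem_region$type, region_area_mm2(x$xylem_region),
              x$vessel_density_per_mm2))
  cat(sprintf("  diameters: %s; embolism Weibull b = %g MPa, c = %g\n",
              x$diameter_dist$family, x$weibull_scale_mpa, x$weibull_shape))
  invisible(x)
}

#' Calibrate a truncated lognormal diameter distribution
#'
#' Solves the lognormal `meanlog`/`sdlog` so that the untruncated
#' distribution has arithmetic mean `mean_d_um` and hydraulically weighted
#' mean \eqn{d_h = E[d^5]/E[d^4]} equal to `d_h_um` (for a lognormal,
#' \eqn{d_h/\bar d = e^{4\sigma^2}}). Truncation bounds are applied when
#' sampling; with the default, generously wide bounds the realised moments
#' track the targets closely.
#'
#' @param mean_d_um Target mean lumen diameter (um).
#' @param d_h_um Target hydraulically weighted diameter (um, >= mean).
#' @param min_um,max_um Truncation bounds (um, positive, ordered).
#' @return A diameter distribution spec for [organ_sim_config()].
#' @export
diameter_dist_lognormal <- function(mean_d_um, d_h_um,
                                    min_um = 5, max_um = 60) {
  assert_scalar_num(mean_d_um, "mean_d_um", 0, strict_lower = TRUE)
  assert_scalar_num(d_h_um, "d_h_um", mean_d_um)
  s2 <- log(d_h_um / mean_d_um) / 4
  list(family = "lognormal", meanlog = log(mean_d_um) - s2 / 2,
       sdlog = sqrt(s2), min_um = min_um, max_um = max_um)
}

validate_diameter_dist <- function(dd) {
  if (!is.list(dd) || is.null(dd$family))
    stopf("diameter_dist must be a list with a `family` element")
  if (is.null(dd$min_um) || is.null(dd$max_um) ||
      dd$min_um <= 0 || dd$max_um < dd$min_um)
    stopf("diameter truncation bounds must be positive and ordered")
  switch(dd$family,
    lognormal = {
      if (is.null(dd$meanlog) || is.null(dd$sdlog) || dd$sdlog < 0)
        stopf("lognormal diameter_dist needs meanlog and sdlog >= 0")
    },
    uniform = NULL,
    stopf("unsupported diameter family '%s'", dd$family))
  dd
}

sample_diameters <- function(dd, n) {
  if (n == 0L) return(numeric(0))
  switch(dd$family,
    lognormal = if (dd$sdlog == 0) rep(exp(dd$meanlog), n)
                else rtrunc_lnorm(n, dd$meanlog, dd$sdlog, dd$min_um, dd$max_um),
    uniform   = stats::runif(n, dd$min_um, dd$max_um))
}

# Second raw moment of the diameter distribution (untruncated approximation
# for the lognormal), used only for the packing sanity check.
diameter_m2 <- function(dd) {
  switch(dd$family,
    lognormal = exp(2 * dd$meanlog + 2 * dd$sdlog^2),
    uniform   = (dd$min_um^2 + dd$min_um * dd$max_um + dd$max_um^2) / 3)
}

validate_region <- function(region, image_size_px, pixel_size_um) {
  if (!is.list(region) || is.null(region$type))
    stopf("xylem_region must be a list with a `type` element")
  half <- min(image_size_px) * pixel_size_um / 2
  if (region$type == "disc") {
    if (is.null(region$radius_um) || region$radius_um <= 0)
      stopf("disc region needs a positive radius_um")
    if (region$radius_um > half)
      stopf("disc radius %g um exceeds the image half-extent %g um",
            region$radius_um, half)
  } else if (region$type == "annulus") {
    if (is.null(region$r_inner_um) || is.null(region$r_outer_um) ||
        region$r_inner_um < 0 || region$r_outer_um <= region$r_inner_um)
      stopf("annulus region needs 0 <= r_inner_um < r_outer_um")
    if (region$r_outer_um > half)
      stopf("annulus outer radius exceeds the image half-extent")
  } else stopf("unsupported region type '%s'", region$type)
  region
}

region_area_mm2 <- function(region) {
  a_um2 <- if (region$type == "disc") pi * region$radius_um^2
           else pi * (region$r_outer_um^2 - region$r_inner_um^2)
  a_um2 / 1e6
}

packing_fraction <- function(cfg) {
  wall <- cfg$min_wall_px * cfg$pixel_size_um
  m2 <- diameter_m2(cfg$diameter_dist)
  m1 <- sqrt(m2)  # crude but adequate for a feasibility bound
  cfg$vessel_density_per_mm2 * pi / 4 * (m2 + 2 * wall * m1 + wall^2) / 1e6
}

#' Generate a synthetic cross-section at a given water potential
#'
#' Places non-overlapping circular conduits inside the configured xylem
#' region by rejection sampling (largest first, minimum wall
#' `min_wall_px`), assigns each an embolism-threshold water potential drawn
#' from the configured Weibull distribution (independent of diameter), and
#' renders the slice: conduits with threshold >= `psi_mpa` are air-filled
#' (dark), the rest water-filled (light). Gaussian noise of sd `noise_sd`
#' is added and the image clipped to `[0, 1]`.
#'
#' The same seed always yields the same geometry, thresholds, noise field
#' and therefore the same image, and the set of air-filled conduits at a
#' higher (less negative) potential is a subset of that at any lower one.
#'
#' @param config An [organ_sim_config()].
#' @param psi_mpa Simulated xylem water potential (MPa, <= 0).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `image` (numeric matrix in `[0, 1]`, with
#'   attribute `pixel_size_um`) and `truth` (a `ground_truth` object: the
#'   conduit table with columns id, x_um, y_um, d_um, threshold_psi_mpa,
#'   state, plus `xylem_area_mm2`).
#' @examples
#' cfg <- organ_sim_config(image_size_px = 128,
#'                         xylem_region = list(type = "disc", radius_um = 110),
#'                         vessel_density_per_mm2 = 250)
#' cs <- generate_cross_section(cfg, psi_mpa = -2, seed = 7)
#' table(cs$truth$conduits$state)
#' @export
generate_cross_section <- function(config, psi_mpa, seed = config$seed) {
  if (!inherits(config, "organ_sim_config"))
    stopf("`config` must be an organ_sim_config")
  assert_scalar_num(psi_mpa, "psi_mpa", upper = 0)
  seed <- assert_seed(seed)

  with_seed(seed, {
    geom <- place_conduits(config)
    thr <- -stats::rweibull(nrow(geom), shape = config$weibull_shape,
                            scale = config$weibull_scale_mpa)
  })
  state <- ifelse(psi_mpa <= thr, "air", "water")
  conduits <- data.frame(id = seq_len(nrow(geom)), x_um = geom$x_um,
                         y_um = geom$y_um, d_um = geom$d_um,
                         threshold_psi_mpa = thr, state = state,
                         stringsAsFactors = FALSE)
  truth <- structure(
    list(conduits = conduits,
         xylem_area_mm2 = region_area_mm2(config$xylem_region),
         psi_mpa = psi_mpa, seed = seed, noise_seed = seed + 1L),
    class = "ground_truth")
  list(image = render_scan(truth, config, conduits$state), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d conduits in %.4f mm^2 (psi = %g MPa, %d air)\n",
              nrow(x$conduits), x$xylem_area_mm2, x$psi_mpa,
              sum(x$conduits$state == "air")))
  invisible(x)
}

# Rejection-sampling circle packing. Diameters are drawn first and placed
# largest-first (improves attainable densities while staying deterministic
# for a given RNG state).
place_conduits <- function(config) {
  px <- config$pixel_size_um
  area <- region_area_mm2(config$xylem_region)
  n <- round(config$vessel_density_per_mm2 * area)
  d <- sort(sample_diameters(config$diameter_dist, n), decreasing = TRUE)
  wall <- config$min_wall_px * px
  cx0 <- config$image_size_px[2] * px / 2
  cy0 <- config$image_size_px[1] * px / 2
  reg <- config$xylem_region

  x <- y <- r <- numeric(n)
  max_attempts <- 2000L
  for (i in seq_len(n)) {
    ri <- d[i] / 2
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      if (reg$type == "disc") {
        rmax <- reg$radius_um - ri - wall
        if (rmax <= 0) stopf("conduit of diameter %.1f um cannot fit in region", d[i])
        rad <- rmax * sqrt(stats::runif(1))
      } else {
        rmin <- reg$r_inner_um + ri + wall
        rmax <- reg$r_outer_um - ri - wall
        if (rmax <= rmin) stopf("conduit of diameter %.1f um cannot fit in annulus", d[i])
        rad <- sqrt(stats::runif(1, rmin^2, rmax^2))
      }
      th <- stats::runif(1, 0, 2 * pi)
      xi <- cx0 + rad * cos(th)
      yi <- cy0 + rad * sin(th)
      if (i == 1L ||
          all((x[seq_len(i - 1L)] - xi)^2 + (y[seq_len(i - 1L)] - yi)^2 >=
              (r[seq_len(i - 1L)] + ri + wall)^2)) {
        x[i] <- xi; y[i] <- yi; r[i] <- ri
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf(paste0("conduit placement failed after %d attempts: placed %d of %d ",
                   "(achieved density %.0f of requested %.0f per mm^2)"),
            max_attempts, i - 1L, n, (i - 1L) / area,
            config$vessel_density_per_mm2)
  }
  data.frame(x_um = x, y_um = y, d_um = d)
}

# Rasterise one scan. Pixel (row r, col c), 1-based, has its centre at
# x = (c - 0.5) * px, y = (r - 0.5) * px (origin top-left, y downward).
render_scan <- function(truth, config, states) {
  px <- config$pixel_size_um
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  gl <- config$gray_levels
  img <- matrix(gl[["background"]], nr, nc)
  cd <- truth$conduits
  for (i in seq_len(nrow(cd))) {
    g <- if (states[i] == "air") gl[["air"]] else gl[["water"]]
    ri <- cd$d_um[i] / 2
    cols <- max(1L, floor((cd$x_um[i] - ri) / px)):min(nc, ceiling((cd$x_um[i] + ri) / px) + 1L)
    rows <- max(1L, floor((cd$y_um[i] - ri) / px)):min(nr, ceiling((cd$y_um[i] + ri) / px) + 1L)
    cols <- cols[cols >= 1L & cols <= nc]
    rows <- rows[rows >= 1L & rows <= nr]
    xs <- (cols - 0.5) * px - cd$x_um[i]
    ys <- (rows - 0.5) * px - cd$y_um[i]
    inside <- outer(ys^2, xs^2, `+`) <= ri^2
    img[rows, cols][inside] <- g
  }
  if (config$noise_sd > 0) {
    with_seed(truth$noise_seed, {
      img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    })
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  attr(img, "pixel_size_um") <- px
  img
}

#' Render the final (fully embolised) scan of a synthetic sample
#'
#' Same geometry and noise field as the initial scan of the same seed, but
#' every conduit rendered air-filled — the synthetic counterpart of
#' re-scanning a cut, fully dried sample.
#'
#' @param truth A `ground_truth` from [generate_cross_section()].
#' @param config The [organ_sim_config()] used to generate it.
#' @return Image matrix in `[0, 1]`.
#' @export
generate_final_scan <- function(truth, config) {
  if (!inherits(truth, "ground_truth")) stopf("`truth` must be a ground_truth")
  render_scan(truth, config, rep("air", nrow(truth$conduits)))
}

#' Simulate a noisy vulnerability-curve observation set
#'
#' Draws `n` water potentials uniformly on `psi_range`, evaluates the
#' Weibull vulnerability curve, adds Gaussian noise to the PLC and clamps
#' to `[0, 100]` — the synthetic counterpart of a bench-dehydration
#' experiment in which each plant is sampled once at its own potential.
#'
#' @param b_w,c_w Generating Weibull scale (MPa) and shape.
#' @param n Number of observations (>= 4).
#' @param psi_range Length-2 interval within `[-10, 0]` (MPa).
#' @param noise_sd_plc Gaussian noise sd on PLC (percentage points).
#' @param seed Integer seed.
#' @return data.frame with columns `psi_mpa`, `plc_pct`.
#' @examples
#' obs <- generate_plc_observations(3, 2, n = 15, seed = 1)
#' @export
generate_plc_observations <- function(b_w, c_w, n, psi_range = c(-5, 0),
                                      noise_sd_plc = 5, seed = 1L) {
  assert_scalar_num(b_w, "b_w", 0, strict_lower = TRUE)
  assert_scalar_num(c_w, "c_w", 0, strict_lower = TRUE)
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n))
    stopf("`n` must be an integer >= 4")
  if (length(psi_range) != 2L || any(psi_range < -10) || any(psi_range > 0) ||
      psi_range[1] >= psi_range[2])
    stopf("`psi_range` must be an ordered interval within [-10, 0]")
  assert_scalar_num(noise_sd_plc, "noise_sd_plc", 0)
  with_seed(seed, {
    psi <- stats::runif(n, psi_range[1], psi_range[2])
    plc <- plc_weibull(psi, b_w, c_w) + stats::rnorm(n, 0, noise_sd_plc)
  })
  data.frame(psi_mpa = psi, plc_pct = pmin(100, pmax(0, plc)))
}
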