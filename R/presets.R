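# Published reference values for the six seedling organs (two species x
# root/stem/leaf-level organ) that the synthetic generator emulates, and
# preset generator configurations calibrated to them.

#' Published vulnerability thresholds for the reference seedling dataset
#'
#' P12/P50/P88 (MPa) with 95% bootstrap CI bounds and per-curve sample
#' sizes, for *Acer pseudoplatanus* and *Fagus sylvatica* seedling organs
#' measured hydraulically (stems) and by micro-CT (petiole/leaf main vein,
#' stem, root). These published values serve two purposes: checking the
#' internal Weibull consistency of the threshold triplets, and
#' parameterising synthetic dehydration experiments at realistic effect
#' and sample sizes. Missing P12 (Acer petiole) reflects missing
#' high-potential observations in the source data.
#'
#' @return data.frame with columns `species`, `organ`, `method`, `psi12`,
#'   `psi50`, `psi88` (MPa), `n`.
#' @export
reference_thresholds <- function() {
  data.frame(
    species = rep(c("Acer pseudoplatanus", "Fagus sylvatica"), c(4, 4)),
    organ = c("stem", "petiole", "stem", "root",
              "stem", "leaf_main_vein", "stem", "root"),
    method = c("hydraulic", "microct", "microct", "microct",
               "hydraulic", "microct", "microct", "microct"),
    psi12 = c(-1.83, NA, -0.97, -1.41, -2.16, -1.30, -1.54, -1.73),
    psi50 = c(-2.81, -1.13, -2.51, -1.78, -3.36, -2.26, -2.74, -2.75),
    psi88 = c(-3.72, -3.01, -4.69, -2.08, -4.52, -3.25, -4.00, -3.74),
    n = c(13L, 10L, 15L, 10L, 9L, 12L, 16L, 8L),
    stringsAsFactors = FALSE)
}

#' Published anatomical reference values for the seedling organs
#'
#' Mean conduit diameter, hydraulically weighted diameter, vessel density
#' and wall reinforcement per organ, used to calibrate the preset
#' generator configurations.
#'
#' @return data.frame with `species`, `organ`, `d_um`, `d_h_um`,
#'   `vd_per_mm2`, `tb2`.
#' @export
reference_anatomy <- function() {
  data.frame(
    species = rep(c("Acer pseudoplatanus", "Fagus sylvatica"), each = 3),
    organ = c("root", "stem", "petiole", "root", "stem", "leaf_main_vein"),
    d_um = c(11.15, 17.24, 10.47, 14.51, 18.36, 12.01),
    d_h_um = c(15.63, 25.06, 13.96, 22.65, 23.72, 16.42),
    vd_per_mm2 = c(1284.0, 211.5, 908.3, 741.3, 314.4, 2551.3),
    tb2 = c(0.083, 0.070, 0.063, 0.080, 0.140, 0.074),
    stringsAsFactors = FALSE)
}

# Organ-specific generator geometry: frame size, xylem disc radius and
# diameter truncation bounds chosen to reflect organ dimensions (roots
# 0.5-0.8 mm across, stems a few mm -> a sub-sampled disc) and the
# published diameter class ranges (large > 38 um conduits present in the
# Acer stem but absent in the Fagus stem).
PRESET_GEOM <- list(
  acer_root       = list(img = 384L, r = 280, dmin = 6,  dmax = 32, wall = 2, psi_range = c(-4, 0)),
  acer_stem       = list(img = 512L, r = 450, dmin = 10, dmax = 46, wall = 2, psi_range = c(-5, 0)),
  acer_petiole    = list(img = 384L, r = 280, dmin = 6,  dmax = 26, wall = 2, psi_range = c(-4, 0)),
  fagus_root      = list(img = 384L, r = 300, dmin = 6,  dmax = 40, wall = 2, psi_range = c(-5, 0)),
  fagus_stem      = list(img = 512L, r = 450, dmin = 10, dmax = 38, wall = 2, psi_range = c(-5, 0)),
  fagus_leaf_vein = list(img = 320L, r = 220, dmin = 5,  dmax = 28, wall = 1, psi_range = c(-5, 0))
)

preset_key <- function(species, organ) {
  sp <- if (grepl("^Acer", species)) "acer" else "fagus"
  org <- c(root = "root", stem = "stem", petiole = "petiole",
           leaf_main_vein = "leaf_vein")[[organ]]
  paste(sp, org, sep = "_")
}

#' Preset generator configurations for the reference organs
#'
#' Returns [organ_sim_config()]s calibrated so that the simulated vessel
#' density, diameter distribution (truncated lognormal matching the
#' published mean and hydraulically weighted diameters) and per-conduit
#' embolism Weibull (solved from the published P50 and P88) emulate each
#' reference organ.
#'
#' @param names Optional subset of preset names; see
#'   `names(organ_presets())`.
#' @param noise_sd Pixel noise sd applied to all presets (default 0.02).
#' @return Named list of `organ_sim_config` objects with attributes `n`
#'   (published curve sample size) and `psi_range` attached to each.
#' @export
organ_presets <- function(names = NULL, noise_sd = 0.02) {
  ana <- reference_anatomy()
  thr <- reference_thresholds()
  out <- list()
  for (i in seq_len(nrow(ana))) {
    key <- preset_key(ana$species[i], ana$organ[i])
    g <- PRESET_GEOM[[key]]
    tr <- thr[thr$species == ana$species[i] & thr$organ == ana$organ[i] &
              thr$method == "microct", ]
    wb <- weibull_from_thresholds(tr$psi50, tr$psi88, p_a = 50, p_b = 88)
    cfg <- organ_sim_config(
      organ_label = key,
      image_size_px = g$img, pixel_size_um = 2,
      xylem_region = list(type = "disc", radius_um = g$r),
      vessel_density_per_mm2 = ana$vd_per_mm2[i],
      diameter_dist = diameter_dist_lognormal(ana$d_um[i], ana$d_h_um[i],
                                              min_um = g$dmin,
                                              max_um = g$dmax),
      weibull_scale_mpa = wb$scale_mpa, weibull_shape = wb$shape,
      noise_sd = noise_sd, min_wall_px = g$wall, seed = 1L)
    attr(cfg, "n") <- tr$n
    attr(cfg, "psi_range") <- g$psi_range
    out[[key]] <- cfg
  }
  if (!is.null(names)) {
    miss <- setdiff(names, names(out))
    if (length(miss)) stopf("unknown preset(s): %s", paste(miss, collapse = ", "))
    out <- out[names]
  }
  out
}
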