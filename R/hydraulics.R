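# Theoretical (Hagen-Poiseuille) conductance, specific conductivity,
# hydraulic PLC and theoretical PLC from matched scan pairs.
#
# Unit chain for the theoretical conductance of a set of cylindrical
# lumens under laminar flow:
#
#   k_t = (pi * rho / (128 * mu)) * sum(d_i^4)        [Eqn: mass flow per
#                                                      unit pressure
#                                                      gradient]
#   rho [kg m^-3], mu [Pa s], d [m]  =>  k_t [kg m Pa^-1 s^-1]
#   reported per MPa:  k_t [kg m MPa^-1 s^-1] = k_t[Pa] * 1e6
#   K_st = k_t / A_xylem [m^2]       =>  [kg m^-1 MPa^-1 s^-1]
#
# Pit and end-wall resistances are deliberately not modelled, so K_st
# overestimates measured specific conductivity.

#' Fluid properties for conductance calculations
#'
#' Defaults are pure water at 20 degrees C (rho = 998.2 kg m^-3,
#' mu = 1.002e-3 Pa s), the reference temperature to which measured
#' conductivities are corrected.
#'
#' @param density_kg_m3 Fluid density.
#' @param viscosity_pa_s Dynamic viscosity.
#' @param temperature_c Nominal temperature (informational).
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(density_kg_m3 = 998.2,
                             viscosity_pa_s = 1.002e-3,
                             temperature_c = 20) {
  assert_scalar_num(density_kg_m3, "density_kg_m3", 0, strict_lower = TRUE)
  assert_scalar_num(viscosity_pa_s, "viscosity_pa_s", 0, strict_lower = TRUE)
  structure(list(density_kg_m3 = density_kg_m3,
                 viscosity_pa_s = viscosity_pa_s,
                 temperature_c = temperature_c),
            class = "fluid_properties")
}

#' Theoretical hydraulic conductance of a conduit set
#'
#' Modified Hagen-Poiseuille conductance
#' \eqn{k_t = \frac{\pi \rho}{128 \mu} \sum_i d_i^4}, additive over
#' conduits and scaling with the fourth power of diameter. An empty
#' diameter set has zero conductance (not an error).
#'
#' @param diameters_um Lumen diameters, micrometres (>= 0 each).
#' @param fluid A [fluid_properties()] object.
#' @param per Pressure normalisation of the result: `"MPa"` (default,
#'   kg m MPa^-1 s^-1, the units used for reported conductivities) or
#'   `"Pa"` (SI, kg m Pa^-1 s^-1).
#' @return Conductance (scalar).
#' @examples
#' theoretical_conductance(20, per = "Pa")  # 3.91e-15
#' @export
theoretical_conductance <- function(diameters_um,
                                    fluid = fluid_properties(),
                                    per = c("MPa", "Pa")) {
  per <- match.arg(per)
  if (!inherits(fluid, "fluid_properties"))
    stopf("`fluid` must be a fluid_properties object")
  if (length(diameters_um) == 0L) return(0)
  if (any(!is.finite(diameters_um)) || any(diameters_um < 0))
    stopf("diameters must be non-negative and finite")
  kt_pa <- pi * fluid$density_kg_m3 / (128 * fluid$viscosity_pa_s) *
    sum((diameters_um * 1e-6)^4)
  if (per == "MPa") kt_pa * 1e6 else kt_pa
}

#' Theoretical specific hydraulic conductivity
#'
#' Conductance divided by xylem cross-sectional area, giving K_st in
#' kg m^-1 MPa^-1 s^-1 when `kt` is MPa-normalised.
#'
#' @param kt Theoretical conductance (kg m MPa^-1 s^-1).
#' @param xylem_area_mm2 Xylem cross-sectional area (mm^2, > 0).
#' @return Specific conductivity.
#' @export
specific_conductivity <- function(kt, xylem_area_mm2) {
  assert_scalar_num(xylem_area_mm2, "xylem_area_mm2", 0, strict_lower = TRUE)
  kt / (xylem_area_mm2 * 1e-6)
}

#' Hydraulic percentage loss of conductivity
#'
#' \eqn{PLC = (1 - K_i/K_s) \times 100}, clamped to `[0, 100]`; the raw
#' (unclamped) value is retained in the `"raw"` attribute since measurement
#' noise can make K_i marginally exceed K_s.
#'
#' @param ki Initial (native-state) conductivity, >= 0. Vectorised.
#' @param ks Final (maximum) conductivity, > 0. Vectorised.
#' @return PLC in percent with attribute `raw`.
#' @examples
#' plc_hydraulic(0.25, 1)  # 75
#' @export
plc_hydraulic <- function(ki, ks) {
  if (any(!is.finite(ks)) || any(ks <= 0)) stopf("`ks` must be positive")
  if (any(!is.finite(ki)) || any(ki < 0)) stopf("`ki` must be non-negative")
  raw <- (1 - ki / ks) * 100
  structure(pmin(100, pmax(0, raw)), raw = raw)
}

#' Fill in theoretical conductances and PLC on a scan pair
#'
#' Computes k_t over all conduits of the final (fully embolised) scan and
#' over the embolised subset observed in the initial scan; the functional
#' initial conductance is their difference, and
#' \eqn{PLC_t = (1 - k_{t,initial}/k_{t,final}) \times 100
#'            = 100\, k_t(\mathrm{embolised}) / k_t(\mathrm{final})}.
#'
#' @param pair A `scan_pair` from [match_scan_pair()].
#' @param fluid A [fluid_properties()] object.
#' @return The pair with `kt_final`, `kt_initial`, `plc_t_pct` filled in.
#' @seealso [plc_theoretical()] for the PLC value alone.
#' @export
scan_pair_conductance <- function(pair, fluid = fluid_properties()) {
  if (!inherits(pair, "scan_pair")) stopf("`pair` must be a scan_pair")
  fin <- pair$final$conduits
  if (nrow(fin) == 0L) stopf("final scan contains no conduits")
  kt_final <- theoretical_conductance(fin$d_um, fluid)
  emb <- fin$d_um[fin$id %in% pair$embolised_ids]
  kt_emb <- theoretical_conductance(emb, fluid)
  pair$kt_final <- kt_final
  pair$kt_initial <- kt_final - kt_emb
  pair$plc_t_pct <- 100 * kt_emb / kt_final
  pair
}

#' Theoretical PLC of a matched scan pair
#'
#' @param pair A `scan_pair`.
#' @param fluid A [fluid_properties()] object.
#' @return PLC_t in percent (scalar).
#' @export
plc_theoretical <- function(pair, fluid = fluid_properties()) {
  scan_pair_conductance(pair, fluid)$plc_t_pct
}

#' Water viscosity by the empirical log10 temperature relation
#'
#' \eqn{\mu(T) = 1.002\times10^{-3} \cdot
#'   10^{\frac{(20 - T)(1.3272 - 0.001053\,(T - 20))}{T + 105}}} Pa s,
#' referenced to 20 degrees C. Valid over roughly 0-50 degrees C, the
#' range accepted here.
#'
#' @param temperature_c Temperature in degrees C, in (0, 50).
#' @return Dynamic viscosity in Pa s.
#' @export
water_viscosity <- function(temperature_c) {
  if (any(!is.finite(temperature_c)) || any(temperature_c <= 0) ||
      any(temperature_c >= 50))
    stopf("temperature must lie in (0, 50) degrees C")
  t <- temperature_c
  1.002e-3 * 10^((20 - t) * (1.3272 - 0.001053 * (t - 20)) / (t + 105))
}

#' Correct a conductivity measurement to 20 degrees C
#'
#' Conductance scales inversely with viscosity, so a measurement at
#' temperature T is converted to its 20-degree equivalent by multiplying
#' with \eqn{\mu(T)/\mu(20)} (< 1 for T > 20).
#'
#' @param k_raw Measured conductivity (any conductivity unit). Vectorised.
#' @param temperature_c Measurement temperature, degrees C in (0, 50).
#' @return Corrected conductivity.
#' @examples
#' viscosity_correct(1, 25)  # ~0.89
#' @export
viscosity_correct <- function(k_raw, temperature_c) {
  k_raw * water_viscosity(temperature_c) / water_viscosity(20)
}

#' PLC table from tabular hydraulic measurements
#'
#' Applies the viscosity correction to K_i and K_s and computes per-sample
#' hydraulic PLC.
#'
#' @param samples data.frame with columns `psi_mpa`, `ki`, `ks` and
#'   optionally `temperature_c` (default 20) and `sample_id`.
#' @return The input with added columns `ki_20`, `ks_20`, `plc_pct`.
#' @export
process_hydraulic_samples <- function(samples) {
  need <- c("psi_mpa", "ki", "ks")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stopf("`samples` needs columns %s", paste(need, collapse = ", "))
  tc <- samples$temperature_c %||% rep(20, nrow(samples))
  samples$ki_20 <- viscosity_correct(samples$ki, tc)
  samples$ks_20 <- viscosity_correct(samples$ks, tc)
  samples$plc_pct <- as.numeric(plc_hydraulic(samples$ki_20, samples$ks_20))
  samples
}
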