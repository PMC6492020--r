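# Anatomical statistics: mean conduit diameter, hydraulically weighted
# diameter, vessel density, 2-um diameter class histograms and the
# thickness-to-span wall-reinforcement ratio.

#' Hydraulically weighted mean conduit diameter
#'
#' \eqn{d_h = \sum d_i^5 / \sum d_i^4}: the mean diameter with each
#' conduit weighted by its (Hagen-Poiseuille) conductance contribution,
#' so wide conduits dominate. Always >= the arithmetic mean, with equality
#' iff all diameters are equal.
#'
#' @param diameters_um Conduit diameters (um, positive, non-empty).
#' @return d_h in micrometres.
#' @examples
#' hydraulic_diameter(c(10, 20))  # 19.41
#' @export
hydraulic_diameter <- function(diameters_um) {
  if (length(diameters_um) == 0L) stopf("`diameters_um` is empty")
  if (any(!is.finite(diameters_um)) || any(diameters_um <= 0))
    stopf("`diameters_um` must be positive and finite")
  sum(diameters_um^5) / sum(diameters_um^4)
}

#' Vessel density of a conduit map
#'
#' Conduit count divided by xylem cross-sectional area.
#'
#' @param map A `conduit_map`.
#' @return Density in conduits per mm^2.
#' @export
vessel_density <- function(map) {
  if (!inherits(map, "conduit_map")) stopf("`map` must be a conduit_map")
  if (map$xylem_area_mm2 <= 0) stopf("xylem area must be positive")
  nrow(map$conduits) / map$xylem_area_mm2
}

#' Conduit diameter class histogram
#'
#' Counts diameters into half-open classes `[k*w, (k+1)*w)` of width `w`
#' (default the conventional 2 um), lower-closed so a diameter exactly on
#' a class edge falls in the upper class.
#'
#' @param diameters_um Diameters (um, >= 0).
#' @param class_width_um Class width (um, > 0).
#' @return data.frame with `class_low_um`, `class_high_um`, `count`,
#'   covering all classes from 0 to the maximum observed diameter
#'   (including empty intermediate classes); total count is conserved.
#' @export
diameter_histogram <- function(diameters_um, class_width_um = 2) {
  assert_scalar_num(class_width_um, "class_width_um", 0, strict_lower = TRUE)
  if (length(diameters_um) && (any(!is.finite(diameters_um)) ||
                               any(diameters_um < 0)))
    stopf("`diameters_um` must be non-negative and finite")
  if (length(diameters_um) == 0L)
    return(data.frame(class_low_um = numeric(0), class_high_um = numeric(0),
                      count = integer(0)))
  k <- floor(diameters_um / class_width_um)
  kmax <- max(k)
  count <- tabulate(k + 1L, kmax + 1L)
  data.frame(class_low_um = (0:kmax) * class_width_um,
             class_high_um = (1:(kmax + 1L)) * class_width_um,
             count = count)
}

#' Conduit anatomy summary
#'
#' Mean diameter, hydraulically weighted diameter, vessel density and the
#' diameter class histogram of one conduit map.
#'
#' @param map A `conduit_map`.
#' @param class_width_um Histogram class width (um).
#' @return An `anatomy_stats` list: `mean_d_um`, `d_h_um`, `vd_per_mm2`,
#'   `n_conduits`, `histogram`.
#' @export
anatomy_stats <- function(map, class_width_um = 2) {
  if (!inherits(map, "conduit_map")) stopf("`map` must be a conduit_map")
  d <- map$conduits$d_um
  structure(
    list(mean_d_um = if (length(d)) mean(d) else NA_real_,
         d_h_um = if (length(d)) hydraulic_diameter(d) else NA_real_,
         vd_per_mm2 = vessel_density(map), n_conduits = length(d),
         histogram = diameter_histogram(d, class_width_um)),
    class = "anatomy_stats")
}

#' @export
print.anatomy_stats <- function(x, ...) {
  cat(sprintf("anatomy: n = %d, mean d = %.2f um, d_h = %.2f um, VD = %.1f /mm^2\n",
              x$n_conduits, x$mean_d_um, x$d_h_um, x$vd_per_mm2))
  invisible(x)
}

#' Cell-wall reinforcement (t/b)^2 near the hydraulic diameter
#'
#' The thickness-to-span ratio squared, \eqn{(t/b)^2}, averaged over
#' conduit pairs whose mean lumen diameter lies within `window_um` of the
#' organ's hydraulically weighted diameter (the conventional "d_h +/- 2 um"
#' selection). `t` is the (double) intervessel wall thickness as supplied
#' by the measurement table — whether single or double walls were measured
#' is a property of the input data, not resolved here.
#'
#' When a `sample_id` column is present the standard error is first taken
#' across pairs within each sample and the per-sample means and SEs are
#' then averaged across samples; otherwise mean and SE are taken across
#' all retained pairs.
#'
#' @param pairs data.frame with columns `t_um`, `b_um`, `pair_mean_d_um`
#'   and optionally `sample_id`.
#' @param d_h_um Hydraulically weighted diameter of the organ (um).
#' @param window_um Half-width of the selection window (um, default 2,
#'   inclusive).
#' @return list with `mean`, `se`, `n_pairs`, `n_samples`.
#' @examples
#' p <- data.frame(t_um = 1, b_um = 4, pair_mean_d_um = 20)
#' wall_reinforcement(p, d_h_um = 20)$mean  # 0.0625
#' @export
wall_reinforcement <- function(pairs, d_h_um, window_um = 2) {
  if (!is.data.frame(pairs) ||
      !all(c("t_um", "b_um", "pair_mean_d_um") %in% names(pairs)))
    stopf("`pairs` needs columns t_um, b_um, pair_mean_d_um")
  assert_scalar_num(d_h_um, "d_h_um", 0, strict_lower = TRUE)
  if (any(pairs$t_um <= 0) || any(pairs$b_um <= 0))
    stopf("wall thickness and lumen breadth must be positive")
  sel <- abs(pairs$pair_mean_d_um - d_h_um) <= window_um
  if (!any(sel))
    stopf("no conduit pair within d_h +/- %g um (d_h = %g um)",
          window_um, d_h_um)
  kept <- pairs[sel, , drop = FALSE]
  ratio2 <- (kept$t_um / kept$b_um)^2
  if (!is.null(kept$sample_id) && length(unique(kept$sample_id)) > 1L) {
    by_mean <- tapply(ratio2, kept$sample_id, mean)
    by_se <- tapply(ratio2, kept$sample_id,
                    function(v) stats::sd(v) / sqrt(length(v)))
    list(mean = mean(by_mean), se = mean(by_se, na.rm = TRUE),
         n_pairs = nrow(kept), n_samples = length(by_mean))
  } else {
    list(mean = mean(ratio2),
         se = if (length(ratio2) > 1L)
           stats::sd(ratio2) / sqrt(length(ratio2)) else NA_real_,
         n_pairs = nrow(kept), n_samples = 1L)
  }
}
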