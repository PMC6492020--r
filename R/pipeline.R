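# End-to-end pipeline: simulate a dehydration experiment per organ,
# segment every scan pair, compute theoretical PLC, fit vulnerability
# curves with bootstrap thresholds, compare organs, and write every
# intermediate artifact plus a deterministic machine-readable summary.

#' Simulate and analyse a synthetic dehydration experiment for one organ
#'
#' For each of `n_samples` plants: draw a water potential uniformly on
#' `psi_range`, generate the initial and final cross-section scans with a
#' plant-specific seed, segment both, match the pair and compute
#' theoretical PLC. The per-plant seeds are `seed * 1000 + i`, so the
#' whole experiment is reproducible from one integer.
#'
#' @param config An [organ_sim_config()].
#' @param n_samples Number of plants (one potential each).
#' @param psi_range Sampled potential interval (MPa).
#' @param seed Integer experiment seed (keep below ~2e6 so derived seeds
#'   stay within integer range).
#' @param segmentation List of [segment_air_conduits()] override settings.
#' @param fluid [fluid_properties()].
#' @return list with `points` (data.frame sample_id, psi_mpa, plc_pct),
#'   `pairs` (list of `scan_pair`s) and `truths`.
#' @export
simulate_dehydration_experiment <- function(config, n_samples = 10,
                                            psi_range = c(-5, 0),
                                            seed = 1L,
                                            segmentation = list(),
                                            fluid = fluid_properties()) {
  seed <- assert_seed(seed)
  psis <- with_seed(seed, stats::runif(n_samples, psi_range[1], psi_range[2]))
  pairs <- vector("list", n_samples)
  truths <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    s <- seed * 1000L + i
    cs <- generate_cross_section(config, psi_mpa = psis[i], seed = s)
    fin_img <- generate_final_scan(cs$truth, config)
    seg_args <- c(list(xylem_area_mm2 = cs$truth$xylem_area_mm2),
                  segmentation)
    ini <- do.call(segment_air_conduits,
                   c(list(cs$image, config$pixel_size_um,
                          image_id = sprintf("%s_s%02d_initial",
                                             config$organ_label, i)),
                     seg_args))
    fin <- do.call(segment_air_conduits,
                   c(list(fin_img, config$pixel_size_um,
                          image_id = sprintf("%s_s%02d_final",
                                             config$organ_label, i)),
                     seg_args))
    pair <- match_scan_pair(ini, fin, psi_mpa = psis[i])
    pairs[[i]] <- scan_pair_conductance(pair, fluid)
    truths[[i]] <- cs$truth
  }
  points <- data.frame(
    sample_id = sprintf("%s_s%02d", config$organ_label, seq_len(n_samples)),
    psi_mpa = psis,
    plc_pct = vapply(pairs, function(p) p$plc_t_pct, numeric(1)))
  list(points = points, pairs = pairs, truths = truths)
}

#' Run the full analysis pipeline from a configuration
#'
#' simulate -> segment -> match -> theoretical PLC -> anatomy -> fit ->
#' bootstrap -> compare, writing every intermediate table under
#' `output_dir`: per-sample conduit-map CSVs (+ JSON sidecars), per-organ
#' curve points and anatomy, fitted curves with thresholds as JSON, a
#' combined threshold table CSV, a `summary.json` (deterministic:
#' identical config in, byte-identical summary out) and a `run.log`
#' recording versions and applied settings.
#'
#' @param config Path to a YAML config, or a config list (see
#'   [read_pipeline_config()]).
#' @param quiet Suppress progress messages.
#' @return The result bundle (organ results, comparisons, summary),
#'   invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  logl <- c(sprintf("xylemct %s | R %s",
                    as.character(utils::packageVersion("xylemct")),
                    paste(R.version$major, R.version$minor, sep = ".")),
            sprintf("seed: %d, n_boot: %d", cfg$seed, cfg$n_boot))

  fluid <- do.call(fluid_properties, as.list(cfg$fluid %||% list()))
  seg_set <- as.list(cfg$segmentation %||% list())
  presets <- organ_presets()
  organs <- list()

  for (oi in seq_along(cfg$organs)) {
    oc <- cfg$organs[[oi]]
    stage <- sprintf("organ '%s'", oc$name)
    sim_cfg <- tryCatch(organ_config_from_entry(oc, presets),
                        error = function(e)
                          stopf("[%s] config error: %s", stage,
                                conditionMessage(e)))
    n_samples <- oc$n_samples %||% attr(sim_cfg, "n") %||% 10
    psi_range <- oc$psi_range %||% attr(sim_cfg, "psi_range") %||% c(-5, 0)
    say("[%d/%d] %s: %d plants on [%g, %g] MPa", oi, length(cfg$organs),
        oc$name, n_samples, psi_range[1], psi_range[2])

    exp_seed <- cfg$seed + 37L * oi
    res <- tryCatch(
      simulate_dehydration_experiment(sim_cfg, n_samples, psi_range,
                                      seed = exp_seed,
                                      segmentation = seg_set, fluid = fluid),
      error = function(e) stopf("[%s] simulation/segmentation failed: %s",
                                stage, conditionMessage(e)))

    for (i in seq_along(res$pairs)) {
      write_conduit_map(res$pairs[[i]]$initial,
                        file.path(cfg$output_dir,
                                  sprintf("%s_s%02d_initial.csv", oc$name, i)))
      write_conduit_map(res$pairs[[i]]$final,
                        file.path(cfg$output_dir,
                                  sprintf("%s_s%02d_final.csv", oc$name, i)))
      logl <- c(logl, sprintf("%s sample %d: threshold %.4f (%s)", oc$name, i,
                              res$pairs[[i]]$initial$settings$threshold,
                              res$pairs[[i]]$initial$settings$threshold_method))
    }
    write_curve_points(cbind(res$points, organ = oc$name, method = "microct"),
                       file.path(cfg$output_dir,
                                 sprintf("%s_points.csv", oc$name)))

    ana <- anatomy_stats(res$pairs[[1]]$final)
    utils::write.csv(ana$histogram,
                     file.path(cfg$output_dir,
                               sprintf("%s_histogram.csv", oc$name)),
                     row.names = FALSE)

    curve <- tryCatch(
      fit_vulnerability_curve(res$points, organ = oc$name, method = "microct",
                              n_boot = cfg$n_boot, seed = cfg$seed + 911L * oi),
      error = function(e) stopf("[%s] curve fitting failed: %s", stage,
                                conditionMessage(e)))
    write_curve_json(curve, file.path(cfg$output_dir,
                                      sprintf("%s_curve.json", oc$name)))
    organs[[oc$name]] <- list(curve = curve, anatomy = ana,
                              n_samples = n_samples)
  }

  comparisons <- list()
  for (cmp in cfg$comparisons %||% list()) {
    a <- cmp[[1]]; b <- cmp[[2]]
    p <- if (length(cmp) >= 3) as.numeric(cmp[[3]]) else 50
    if (is.null(organs[[a]]) || is.null(organs[[b]]))
      stopf("[comparisons] unknown organ '%s' or '%s'", a, b)
    comparisons[[paste(a, b, p, sep = "_")]] <-
      compare_curves(organs[[a]]$curve, organs[[b]]$curve, threshold = p)
  }

  thr_rows <- lapply(names(organs), function(nm) {
    ts <- organs[[nm]]$curve$thresholds
    if (is.null(ts)) return(NULL)
    th <- ts$thresholds
    data.frame(organ = nm, method = "microct",
               p = th$p, psi_mpa = th$psi_mpa,
               ci_lo_mpa = th$ci_lo_mpa, ci_hi_mpa = th$ci_hi_mpa,
               n = ts$n)
  })
  thr_tab <- do.call(rbind, thr_rows)
  if (!is.null(thr_tab))
    write_table_full(thr_tab, file.path(cfg$output_dir, "thresholds.csv"))

  summary <- list(
    seed = cfg$seed, n_boot = cfg$n_boot,
    organs = lapply(organs, function(o) {
      fit <- o$curve$fit
      ts <- o$curve$thresholds
      list(converged = fit$converged,
           scale_mpa = if (fit$converged) fit$scale_mpa else NULL,
           shape = if (fit$converged) fit$shape else NULL,
           thresholds = if (!is.null(ts)) {
             stats::setNames(lapply(seq_len(nrow(ts$thresholds)), function(i)
               list(psi_mpa = ts$thresholds$psi_mpa[i],
                    ci = c(ts$thresholds$ci_lo_mpa[i],
                           ts$thresholds$ci_hi_mpa[i]))),
               paste0("p", ts$thresholds$p))
           },
           mean_d_um = o$anatomy$mean_d_um, d_h_um = o$anatomy$d_h_um,
           vd_per_mm2 = o$anatomy$vd_per_mm2)
    }),
    comparisons = lapply(comparisons, function(cc)
      list(a = cc$label_a, b = cc$label_b, p = cc$threshold,
           significant = cc$significant)))
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(logl, file.path(cfg$output_dir, "run.log"))
  say("done: %s", file.path(cfg$output_dir, "summary.json"))
  invisible(list(organs = organs, comparisons = comparisons,
                 summary = summary, config = cfg))
}

# Build an organ_sim_config from a config-file organ entry: either a named
# preset (with optional overrides) or fully spelled-out parameters.
organ_config_from_entry <- function(oc, presets) {
  if (!is.null(oc$preset)) {
    if (is.null(presets[[oc$preset]]))
      stopf("unknown preset '%s' (available: %s)", oc$preset,
            paste(names(presets), collapse = ", "))
    cfg <- presets[[oc$preset]]
    if (!is.null(oc$noise_sd)) {
      cfg$noise_sd <- oc$noise_sd
    }
    return(cfg)
  }
  need <- c("vessel_density_per_mm2", "mean_d_um", "d_h_um",
            "weibull_scale_mpa", "weibull_shape")
  miss <- setdiff(need, names(oc))
  if (length(miss))
    stopf("organ '%s': missing %s (or use `preset:`)", oc$name,
          paste(miss, collapse = ", "))
  organ_sim_config(
    organ_label = oc$name,
    image_size_px = oc$image_size_px %||% 384L,
    pixel_size_um = oc$pixel_size_um %||% 2,
    xylem_region = oc$xylem_region %||% list(type = "disc", radius_um = 300),
    vessel_density_per_mm2 = oc$vessel_density_per_mm2,
    diameter_dist = diameter_dist_lognormal(oc$mean_d_um, oc$d_h_um,
                                            min_um = oc$d_min_um %||% 5,
                                            max_um = oc$d_max_um %||% 60),
    weibull_scale_mpa = oc$weibull_scale_mpa,
    weibull_shape = oc$weibull_shape,
    noise_sd = oc$noise_sd %||% 0.02,
    min_wall_px = oc$min_wall_px %||% 2,
    seed = 1L)
}
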