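# Readers/writers for every artifact format: grayscale images (PNG via
# the png package, ASCII PGM as the text-friendly fixture format),
# conduit-map / curve-point / wall-pair / hydraulic-sample CSVs with
# strict schemas, fit/threshold JSON, YAML pipeline configs. All reals are
# serialised with 17 significant digits so write-then-read round trips
# are lossless.

# ---- images -----------------------------------------------------------

#' Write a grayscale image
#'
#' Format chosen by extension: `.png` (8-bit grayscale, via the png
#' package) or `.pgm` (ASCII P2, 16-bit — plain text, convenient for
#' fixtures).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!is.matrix(image) || any(!is.finite(image)) ||
      any(image < 0) || any(image > 1))
    stopf("`image` must be a numeric matrix in [0, 1]")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    pgm = write_pgm(image, path),
    stopf("unsupported image extension '.%s' (use .png or .pgm)", ext))
  invisible(path)
}

#' Read a grayscale image
#'
#' Reads `.png` or ASCII `.pgm` into a numeric matrix in `[0, 1]`. RGB(A)
#' PNGs are converted by channel averaging.
#'
#' @param path Image path.
#' @param pixel_size_um Optional pixel size to attach as an attribute.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) apply(a[, , seq_len(min(3L, dim(a)[3])),
                                       drop = FALSE], c(1, 2), mean)
      else a
    },
    pgm = read_pgm(path),
    stopf("unsupported image extension '.%s'", ext))
  if (!is.null(pixel_size_um)) attr(img, "pixel_size_um") <- pixel_size_um
  img
}

write_pgm <- function(image, path, maxval = 65535L) {
  v <- as.integer(round(t(image) * maxval))  # PGM is row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)),
               as.character(maxval)), con)
  writeLines(vapply(split(v, rep(seq_len(nrow(image)), each = ncol(image))),
                    paste, character(1), collapse = " "), con)
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), what = numeric(),
              quiet = TRUE)
  if (!identical(trimws(txt[1]), "P2")) stopf("only ASCII PGM (P2) supported")
  nc <- tok[1]; nr <- tok[2]; maxval <- tok[3]
  px <- tok[-(1:3)]
  if (length(px) != nr * nc) stopf("corrupt PGM: expected %d pixels, got %d",
                                   nr * nc, length(px))
  matrix(px / maxval, nrow = nr, ncol = nc, byrow = TRUE)
}

# ---- CSV schemas ------------------------------------------------------

# Every tabular format has a fixed schema; unknown columns are rejected
# with an explicit mention of the offending name, so a wrong unit suffix
# (psi_kpa instead of psi_mpa) surfaces as a schema error.
SCHEMAS <- list(
  conduit_map = list(required = c("id", "x_um", "y_um", "area_um2", "d_um",
                                  "state", "border"),
                     optional = character(0)),
  curve_points = list(required = c("psi_mpa", "plc_pct"),
                      optional = c("sample_id", "organ", "method")),
  wall_pairs = list(required = c("t_um", "b_um", "pair_mean_d_um"),
                    optional = "sample_id"),
  hydraulic_samples = list(required = c("psi_mpa", "ki", "ks"),
                           optional = c("sample_id", "temperature_c")),
  ground_truth = list(required = c("id", "x_um", "y_um", "d_um",
                                   "threshold_psi_mpa", "state"),
                      optional = character(0))
)

check_schema <- function(df, what, path = "<data>") {
  sch <- SCHEMAS[[what]]
  miss <- setdiff(sch$required, names(df))
  if (length(miss))
    stopf("%s: missing required column(s) %s in %s schema", path,
          paste(miss, collapse = ", "), what)
  extra <- setdiff(names(df), c(sch$required, sch$optional))
  if (length(extra))
    stopf("%s: unknown column(s) %s not in %s schema (wrong unit suffix?)",
          path, paste(extra, collapse = ", "), what)
  if (nrow(df) == 0L) stopf("%s: no data rows", path)
  for (col in setdiff(sch$required, c("state", "sample_id", "organ",
                                      "method", "id"))) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stopf("%s: non-numeric or missing value in column '%s', row %d",
            path, col, bad[1])
  }
  df
}

write_table_full <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- format_full(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_checked_csv <- function(path, what) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, what, path)
}

#' Write / read a conduit map
#'
#' The conduit table goes to CSV; the segmentation settings and metadata
#' (pixel size, xylem area, source image) to a JSON sidecar
#' `<path>.json`.
#'
#' @param map A `conduit_map`.
#' @param path CSV path.
#' @return `path` (write) or a `conduit_map` (read), invisibly for write.
#' @export
write_conduit_map <- function(map, path) {
  if (!inherits(map, "conduit_map")) stopf("`map` must be a conduit_map")
  write_table_full(map$conduits, path)
  meta <- list(xylem_area_mm2 = map$xylem_area_mm2,
               pixel_size_um = map$pixel_size_um,
               source_image_id = map$source_image_id,
               settings = map$settings)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_conduit_map
#' @export
read_conduit_map <- function(path) {
  df <- read_checked_csv(path, "conduit_map")
  df$border <- as.logical(df$border)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("conduit map sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new_conduit_map(df, meta$xylem_area_mm2, meta$pixel_size_um,
                  meta$source_image_id, as.list(meta$settings))
}

#' Read vulnerability curve points from CSV
#'
#' Schema: `psi_mpa`, `plc_pct` (+ optional `sample_id`, `organ`,
#' `method`). Schema violations and empty files raise explicit errors.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_curve_points <- function(path) read_checked_csv(path, "curve_points")

#' @rdname read_curve_points
#' @param points Curve-point data.frame to write.
#' @export
write_curve_points <- function(points, path) {
  check_schema(points, "curve_points")
  write_table_full(points, path)
}

#' Read wall-pair measurements from CSV
#'
#' Schema: `t_um`, `b_um`, `pair_mean_d_um` (+ optional `sample_id`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_wall_pairs <- function(path) read_checked_csv(path, "wall_pairs")

#' Read hydraulic conductivity samples from CSV
#'
#' Schema: `psi_mpa`, `ki`, `ks` (+ optional `sample_id`,
#' `temperature_c`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_hydraulic_samples <- function(path) read_checked_csv(path, "hydraulic_samples")

#' Write ground truth conduits to CSV
#'
#' @param truth A `ground_truth`.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  if (!inherits(truth, "ground_truth")) stopf("`truth` must be a ground_truth")
  write_table_full(truth$conduits, path)
}

#' Serialise a fitted curve and its thresholds to JSON
#'
#' @param curve A `vulnerability_curve`.
#' @param path JSON path.
#' @export
write_curve_json <- function(curve, path) {
  if (!inherits(curve, "vulnerability_curve"))
    stopf("`curve` must be a vulnerability_curve")
  fit <- curve$fit
  obj <- list(organ = curve$organ, method = curve$method,
              family = fit$family, converged = fit$converged,
              n = nrow(curve$points))
  if (inherits(fit, "weibull_fit") && fit$converged)
    obj <- c(obj, list(scale_mpa = fit$scale_mpa, shape = fit$shape,
                       rss = fit$rss))
  if (!is.null(curve$thresholds)) {
    th <- curve$thresholds$thresholds
    obj$thresholds <- lapply(seq_len(nrow(th)), function(i)
      list(p = th$p[i], psi_mpa = th$psi_mpa[i],
           ci_lo_mpa = th$ci_lo_mpa[i], ci_hi_mpa = th$ci_hi_mpa[i]))
    obj$n_boot <- curve$thresholds$n_boot
    obj$n_failed <- curve$thresholds$n_failed
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- pipeline config --------------------------------------------------

CONFIG_KEYS <- list(
  top = c("seed", "n_boot", "output_dir", "log_level", "fluid",
          "segmentation", "organs", "comparisons"),
  fluid = c("density_kg_m3", "viscosity_pa_s", "temperature_c"),
  segmentation = c("threshold", "threshold_method", "min_area_um2",
                   "min_circularity", "connectivity"),
  organ = c("name", "preset", "n_samples", "psi_range", "image_size_px",
            "pixel_size_um", "xylem_region", "vessel_density_per_mm2",
            "mean_d_um", "d_h_um", "d_min_um", "d_max_um",
            "weibull_scale_mpa", "weibull_shape", "noise_sd", "gray_levels",
            "min_wall_px"))

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stopf("unknown config key(s) in %s: %s", where,
          paste(extra, collapse = ", "))
  x
}

#' Read and validate a pipeline configuration
#'
#' YAML file with top-level keys `seed` (mandatory), `n_boot`,
#' `output_dir`, `fluid`, `segmentation`, `organs` (list; each either
#' names a `preset` from [organ_presets()] or spells out generator
#' parameters) and `comparisons` (list of `[organ_a, organ_b, p]`
#' triples). Unknown keys anywhere are rejected before any computation.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stopf("`path` must be a file or list")
  reject_unknown(cfg, CONFIG_KEYS$top, "top level")
  if (is.null(cfg$seed)) stopf("config validation: `seed` is mandatory")
  cfg$seed <- assert_seed(cfg$seed, "seed")
  cfg$n_boot <- cfg$n_boot %||% 1000
  cfg$output_dir <- cfg$output_dir %||% "xylemct-out"
  if (!is.null(cfg$fluid)) reject_unknown(cfg$fluid, CONFIG_KEYS$fluid, "fluid")
  if (!is.null(cfg$segmentation))
    reject_unknown(cfg$segmentation, CONFIG_KEYS$segmentation, "segmentation")
  if (is.null(cfg$organs) || !length(cfg$organs))
    stopf("config validation: at least one organ is required")
  for (i in seq_along(cfg$organs)) {
    org <- reject_unknown(cfg$organs[[i]], CONFIG_KEYS$organ,
                          sprintf("organs[%d]", i))
    if (is.null(org$name)) stopf("organs[%d]: `name` is required", i)
    cfg$organs[[i]] <- org
  }
  structure(cfg, class = "pipeline_config")
}
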