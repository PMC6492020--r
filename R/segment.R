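# Detection of air-filled conduits in a grayscale cross-section: global
# threshold (fixed or Otsu), 8-connected component labelling, area and
# circularity filtering. The in-R replacement for the classic ImageJ
# "threshold + Analyse particles" workflow.

#' Equivalent circular diameter from lumen area
#'
#' \eqn{d = 2\sqrt{A/\pi}} — the diameter of the circle with the same
#' area, the standard convention for reporting conduit diameters measured
#' on cross-sections.
#'
#' @param area_um2 Lumen area(s), square micrometres (> 0).
#' @return Diameter(s) in micrometres.
#' @examples
#' equivalent_diameter(25 * pi)  # 10
#' @export
equivalent_diameter <- function(area_um2) {
  if (!is.numeric(area_um2) || any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stopf("`area_um2` must be positive and finite")
  2 * sqrt(area_um2 / pi)
}

# 8- or 4-connected component labelling by iterative minimum-label
# propagation (vectorised over the whole frame; converges in at most the
# maximal component diameter in pixels, small for conduit-scale blobs).
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)

  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))

  shift_mat <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }

  repeat {
    new <- lab
    for (s in shifts) new <- pmin(new, shift_mat(lab, s[1], s[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Otsu's between-class-variance threshold on a 256-bin histogram.
otsu_threshold <- function(img, nbins = 256L) {
  h <- tabulate(pmin(nbins, floor(img * nbins) + 1L), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)] + 0.5 / nbins  # upper edge of the best bin
}

#' Segment air-filled conduits in a cross-section image
#'
#' Pixels darker than the threshold form the candidate foreground;
#' 8-connected components are labelled, filtered by minimum area (and
#' optionally circularity), and each surviving component becomes one
#' air-filled conduit with its centroid, area and equivalent-circle
#' diameter. Components touching the frame border are kept but flagged.
#'
#' @param image Numeric matrix with values in `[0, 1]` (air-filled lumens
#'   dark), or a list with an `image` element as returned by
#'   [generate_cross_section()].
#' @param pixel_size_um Pixel edge length (um); taken from the image
#'   attribute when present.
#' @param threshold Gray threshold in `[0, 1]` (foreground strictly below),
#'   used when `threshold_method = "fixed"`. Default 0.30, midway between
#'   the default air and background gray levels.
#' @param threshold_method `"fixed"` or `"otsu"` (automatic, computed on
#'   the image histogram). The threshold actually applied is recorded in
#'   the returned settings.
#' @param min_area_um2 Minimum component area; default the area of a
#'   5-um-diameter circle (smaller blobs are noise-scale at 2 um/px).
#' @param min_circularity Optional lower bound on \eqn{4\pi A / P^2}
#'   (perimeter from boundary-pixel count; a crude estimator, off by
#'   default).
#' @param mask Optional logical matrix restricting the analysed region;
#'   also defines the xylem area unless `xylem_area_mm2` is given.
#' @param xylem_area_mm2 Xylem cross-sectional area override (mm^2);
#'   default: mask area, else the whole frame.
#' @param connectivity 8 (default) or 4.
#' @param image_id Identifier stored on the result.
#' @return A `conduit_map`: list with `conduits` (data.frame id, x_um,
#'   y_um, area_um2, d_um, state, border) plus `xylem_area_mm2`,
#'   `pixel_size_um`, `source_image_id`, `settings`.
#' @export
segment_air_conduits <- function(image, pixel_size_um = NULL,
                                 threshold = 0.30,
                                 threshold_method = c("fixed", "otsu"),
                                 min_area_um2 = pi * 2.5^2,
                                 min_circularity = NULL,
                                 mask = NULL, xylem_area_mm2 = NULL,
                                 connectivity = 8,
                                 image_id = "image") {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stopf("`image` must be a non-empty numeric matrix")
  if (any(!is.finite(image))) stopf("image contains non-finite pixels")
  pixel_size_um <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(pixel_size_um))
    stopf("`pixel_size_um` missing and not stored on the image")
  assert_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "otsu") threshold <- otsu_threshold(image)
  assert_scalar_num(threshold, "threshold", 0, 1)
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")

  fg <- image < threshold
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(image)))
      stopf("`mask` must be a logical matrix matching the image")
    fg <- fg & mask
  }

  nr <- nrow(image); nc <- ncol(image)
  px2 <- pixel_size_um^2
  area_mm2 <- xylem_area_mm2 %||%
    (if (!is.null(mask)) sum(mask) * px2 / 1e6 else nr * nc * px2 / 1e6)
  assert_scalar_num(area_mm2, "xylem_area_mm2", 0, strict_lower = TRUE)

  settings <- list(threshold = threshold, threshold_method = threshold_method,
                   min_area_um2 = min_area_um2,
                   min_circularity = min_circularity,
                   connectivity = connectivity)

  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), d_um = numeric(0),
                      state = character(0), border = logical(0),
                      stringsAsFactors = FALSE)
  if (!any(fg))
    return(new_conduit_map(empty, area_mm2, pixel_size_um, image_id, settings))

  lab <- label_components(fg, connectivity)
  idx <- which(fg)
  reps <- lab[idx]
  comp <- match(reps, sort(unique(reps)))
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L

  npx <- tabulate(comp)
  cx <- rowsum((cols - 0.5) * pixel_size_um, comp)[, 1] / npx
  cy <- rowsum((rows - 0.5) * pixel_size_um, comp)[, 1] / npx
  border <- rowsum(as.numeric(rows == 1L | rows == nr |
                              cols == 1L | cols == nc), comp)[, 1] > 0
  area <- npx * px2

  keep <- area >= min_area_um2
  if (!is.null(min_circularity)) {
    # boundary pixels: foreground with at least one 4-neighbour background
    interior <- fg
    interior[1, ] <- interior[nr, ] <- interior[, 1] <- interior[, nc] <- FALSE
    up <- rbind(fg[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, fg[-nr, , drop = FALSE])
    lf <- cbind(fg[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, fg[, -nc, drop = FALSE])
    boundary <- fg & !(up & dn & lf & rt)
    per_px <- rowsum(as.numeric(boundary[idx]), comp)[, 1]
    perim <- per_px * pixel_size_um
    circ <- 4 * pi * area / pmax(perim, pixel_size_um)^2
    keep <- keep & (circ >= min_circularity)
  }

  if (!any(keep))
    return(new_conduit_map(empty, area_mm2, pixel_size_um, image_id, settings))

  conduits <- data.frame(
    id = seq_len(sum(keep)),
    x_um = cx[keep], y_um = cy[keep],
    area_um2 = area[keep], d_um = equivalent_diameter(area[keep]),
    state = "air", border = border[keep], stringsAsFactors = FALSE)
  new_conduit_map(conduits, area_mm2, pixel_size_um, image_id, settings)
}

new_conduit_map <- function(conduits, xylem_area_mm2, pixel_size_um,
                            source_image_id, settings = list()) {
  conduits[] <- lapply(conduits, unname)
  rownames(conduits) <- NULL
  structure(list(conduits = conduits, xylem_area_mm2 = xylem_area_mm2,
                 pixel_size_um = pixel_size_um,
                 source_image_id = source_image_id, settings = settings),
            class = "conduit_map")
}

#' @export
print.conduit_map <- function(x, ...) {
  cat(sprintf("conduit_map '%s': %d conduits, xylem area %.4f mm^2 (%g um/px)\n",
              x$source_image_id, nrow(x$conduits), x$xylem_area_mm2,
              x$pixel_size_um))
  if (nrow(x$conduits))
    cat(sprintf("  d: %.1f-%.1f um (mean %.1f); %d touching border\n",
                min(x$conduits$d_um), max(x$conduits$d_um),
                mean(x$conduits$d_um), sum(x$conduits$border)))
  invisible(x)
}

#' Match an initial scan against its fully embolised final scan
#'
#' Each air-filled conduit detected in the initial scan is matched to the
#' nearest conduit (by centroid) in the final scan, within `tol_um`. The
#' matched final-scan ids form the embolised subset on which theoretical
#' PLC is computed; the final scan supplies the complete conduit
#' population.
#'
#' @param initial,final `conduit_map`s sharing a pixel size; `final` must
#'   contain every conduit (all embolised).
#' @param tol_um Maximum centroid distance for a match (default 2 pixels).
#' @param psi_mpa Water potential of the initial scan (MPa, <= 0).
#' @return A `scan_pair`: psi, both maps, `embolised_ids` (final-scan ids),
#'   `unmatched` (initial-scan ids with no neighbour within tolerance) —
#'   conductances and PLC are filled in by [scan_pair_conductance()].
#' @export
match_scan_pair <- function(initial, final,
                            tol_um = 2 * initial$pixel_size_um,
                            psi_mpa = NA_real_) {
  if (!inherits(initial, "conduit_map") || !inherits(final, "conduit_map"))
    stopf("`initial` and `final` must be conduit_map objects")
  if (abs(initial$pixel_size_um - final$pixel_size_um) > 1e-9)
    stopf("scan pair pixel sizes differ (%g vs %g um)",
          initial$pixel_size_um, final$pixel_size_um)
  if (nrow(final$conduits) == 0L) stopf("final scan contains no conduits")

  ini <- initial$conduits[initial$conduits$state == "air", , drop = FALSE]
  matched <- integer(0)
  unmatched <- integer(0)
  if (nrow(ini)) {
    dx <- outer(ini$x_um, final$conduits$x_um, `-`)
    dy <- outer(ini$y_um, final$conduits$y_um, `-`)
    dist <- sqrt(dx^2 + dy^2)
    nearest <- apply(dist, 1L, which.min)
    mind <- dist[cbind(seq_len(nrow(ini)), nearest)]
    ok <- mind <= tol_um
    hit <- nearest[ok]
    if (anyDuplicated(hit)) {
      dup <- hit[duplicated(hit)]
      bad <- ini$id[ok][hit %in% dup]
      stopf("ambiguous match: initial conduits [%s] map to the same final conduit(s) [%s]",
            paste(bad, collapse = ", "), paste(unique(dup), collapse = ", "))
    }
    matched <- final$conduits$id[hit]
    unmatched <- ini$id[!ok]
    if (length(unmatched))
      warnf("%d initial conduit(s) had no final-scan match within %g um: [%s]",
            length(unmatched), tol_um, paste(unmatched, collapse = ", "))
  }
  structure(list(psi_mpa = psi_mpa, initial = initial, final = final,
                 embolised_ids = matched, unmatched = unmatched,
                 kt_final = NA_real_, kt_initial = NA_real_,
                 plc_t_pct = NA_real_),
            class = "scan_pair")
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf("scan_pair (psi = %g MPa): %d/%d conduits embolised",
              x$psi_mpa, length(x$embolised_ids), nrow(x$final$conduits)))
  if (is.finite(x$plc_t_pct)) cat(sprintf("; PLC_t = %.1f%%", x$plc_t_pct))
  cat("\n")
  invisible(x)
}
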