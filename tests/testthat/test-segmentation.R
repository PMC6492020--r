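# Segmentation against synthetic ground truth, filter monotonicity,
# geometric invariances and scan-pair matching.

test_that("noiseless synthetic images are segmented exactly", {
  cfg <- small_config()
  for (s in c(21, 22, 23)) {
    cs <- generate_cross_section(cfg, -2.5, seed = s)
    seg <- segment_air_conduits(cs$image,
                                xylem_area_mm2 = cs$truth$xylem_area_mm2)
    tr <- cs$truth$conduits
    air <- tr[tr$state == "air", ]
    expect_equal(nrow(seg$conduits), nrow(air))
    # match each detected conduit to the nearest truth conduit and check
    # area within one perimeter-pixel band of the ideal disc area
    for (i in seq_len(nrow(seg$conduits))) {
      j <- which.min((air$x_um - seg$conduits$x_um[i])^2 +
                     (air$y_um - seg$conduits$y_um[i])^2)
      ideal <- pi * (air$d_um[j] / 2)^2
      band <- pi * air$d_um[j] * cfg$pixel_size_um
      expect_lt(abs(seg$conduits$area_um2[i] - ideal), band)
    }
  }
})

test_that("uniform background yields zero conduits", {
  img <- matrix(0.45, 64, 64)
  seg <- segment_air_conduits(img, pixel_size_um = 2)
  expect_equal(nrow(seg$conduits), 0L)
})

test_that("final scans expose the complete conduit population", {
  cfg <- small_config()
  cs <- generate_cross_section(cfg, -1, seed = 31)
  seg <- segment_air_conduits(generate_final_scan(cs$truth, cfg),
                              xylem_area_mm2 = cs$truth$xylem_area_mm2)
  expect_equal(nrow(seg$conduits), nrow(cs$truth$conduits))
})

test_that("detected count is monotone non-increasing in the area filter", {
  cfg <- small_config()
  cs <- generate_cross_section(cfg, -1e6, seed = 41)
  counts <- vapply(c(0, 20, 80, 200, 400, 1000), function(a)
    nrow(segment_air_conduits(cs$image, min_area_um2 = a)$conduits),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("moderate noise changes counts by at most 2%", {
  cfg <- small_config(noise_sd = 0.05)
  cfg0 <- small_config(noise_sd = 0)
  tot_true <- tot_det <- 0
  for (s in 1:5) {
    cs <- generate_cross_section(cfg, -1e6, seed = 50 + s)
    seg <- segment_air_conduits(cs$image)
    tot_true <- tot_true + nrow(cs$truth$conduits)
    tot_det <- tot_det + nrow(seg$conduits)
  }
  expect_lt(abs(tot_det - tot_true) / tot_true, 0.02)
})

test_that("equivalent diameters are invariant to translation and rotation", {
  cfg <- small_config()
  cs <- generate_cross_section(cfg, -1e6, seed = 61)
  d0 <- sort(segment_air_conduits(cs$image)$conduits$d_um)
  rot90 <- t(cs$image)[ncol(cs$image):1, ]  # 90 degree rotation
  attr(rot90, "pixel_size_um") <- 2
  expect_equal(sort(segment_air_conduits(rot90)$conduits$d_um), d0)
  shifted <- matrix(0.45, 180, 180)
  shifted[11:170, 11:170] <- cs$image
  d1 <- sort(segment_air_conduits(shifted, pixel_size_um = 2)$conduits$d_um)
  expect_equal(d1, d0)
})

test_that("equivalent_diameter inverts the circle area", {
  expect_equal(equivalent_diameter(25 * pi), 10)
  expect_equal(equivalent_diameter(100 * pi), 20)
  expect_equal(equivalent_diameter(452.39), 24.0, tolerance = 1e-4)
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(-3), "positive")
})

test_that("segmentation rejects malformed input", {
  img <- matrix(0.5, 32, 32)
  expect_error(segment_air_conduits(matrix(numeric(0), 0, 0), 2), "non-empty")
  img[5, 5] <- NA
  expect_error(segment_air_conduits(img, 2), "non-finite")
  expect_error(segment_air_conduits(matrix(0.5, 8, 8), 2, threshold = 1.5),
               "threshold")
  expect_error(segment_air_conduits(matrix(0.5, 8, 8), -1), "pixel_size_um")
})

test_that("otsu thresholding separates the synthetic gray levels", {
  cfg <- small_config(noise_sd = 0.02)
  cs <- generate_cross_section(cfg, -1e6, seed = 71)
  seg <- segment_air_conduits(cs$image, threshold_method = "otsu")
  expect_equal(nrow(seg$conduits), nrow(cs$truth$conduits))
  expect_true(seg$settings$threshold > 0.1 && seg$settings$threshold < 0.75)
})

test_that("scan pairs match ground truth states", {
  cfg <- small_config()
  cs <- generate_cross_section(cfg, -2.5, seed = 81)
  ini <- segment_air_conduits(cs$image,
                              xylem_area_mm2 = cs$truth$xylem_area_mm2)
  fin <- segment_air_conduits(generate_final_scan(cs$truth, cfg),
                              xylem_area_mm2 = cs$truth$xylem_area_mm2)
  pair <- match_scan_pair(ini, fin, psi_mpa = -2.5)
  expect_length(pair$embolised_ids,
                sum(cs$truth$conduits$state == "air"))
  expect_length(pair$unmatched, 0L)
  # matched embolised diameters equal the ground-truth air diameters
  d_emb <- sort(fin$conduits$d_um[fin$conduits$id %in% pair$embolised_ids])
  d_true <- sort(cs$truth$conduits$d_um[cs$truth$conduits$state == "air"])
  expect_equal(d_emb, d_true, tolerance = 0.15)
})

test_that("match_scan_pair handles edge and error cases", {
  fin <- manual_map(c(50, 100, 150), c(50, 50, 50), c(20, 25, 30))
  # no air conduits in the initial scan -> empty embolised set
  ini0 <- manual_map(numeric(0), numeric(0), numeric(0))
  pair <- match_scan_pair(ini0, fin, psi_mpa = 0)
  expect_length(pair$embolised_ids, 0L)
  # initial == final -> everything matched
  pair2 <- match_scan_pair(fin, fin, psi_mpa = -9)
  expect_setequal(pair2$embolised_ids, fin$conduits$id)
  # two initial conduits nearest to the same final conduit -> error
  ini2 <- manual_map(c(49, 51), c(50, 50), c(20, 20))
  expect_error(match_scan_pair(ini2, fin, tol_um = 10), "ambiguous")
  # far-away conduit flagged as unmatched, with a warning
  ini3 <- manual_map(300, 300, 20)
  expect_warning(p3 <- match_scan_pair(ini3, fin, tol_um = 4), "no final")
  expect_equal(p3$unmatched, 1L)
})
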