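# Film pipeline: scan I/O, optical density, calibration, registration.

test_that("16-bit RGB scans round-trip with their resolution metadata", {
  px <- array(0L, dim = c(40, 60, 3))
  px[, , 1] <- matrix(sample.int(65536, 40 * 60, replace = TRUE) - 1L, 40, 60)
  px[, , 2] <- 12345L; px[, , 3] <- 60000L
  p <- tempfile(fileext = ".tif")
  vaudit:::write_tiff_rgb16(px, p, dpi = 150)
  scan <- read_scan(p, expected_dpi = 150)
  expect_identical(scan$pixels, px)
  expect_identical(scan$dpi, 150)
  expect_identical(scan$channels, c("R", "G", "B"))
  expect_length(scan$warnings, 0)
})

test_that("non-conforming scans are rejected; off-nominal dpi warns but scales", {
  # 8-bit RGB file (written by the independent tiff package)
  p8 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(10 * 10 * 3), dim = c(10, 10, 3)), p8,
                  bits.per.sample = 8L)
  expect_error(read_scan(p8), class = "vaudit_format_error")
  # grayscale 16-bit
  pg <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(100), 10, 10), pg, bits.per.sample = 16L)
  expect_error(read_scan(pg), class = "vaudit_format_error")
  # valid 300 dpi file against an expected 150: accepted with a warning,
  # and downstream mm scaling uses the file's 300 dpi
  p300 <- tempfile(fileext = ".tif")
  vaudit:::write_tiff_rgb16(array(30000L, dim = c(10, 10, 3)), p300, dpi = 300)
  scan <- read_scan(p300, expected_dpi = 150)
  expect_match(scan$warnings, "differs from expected", all = FALSE)
  expect_identical(scan$dpi, 300)
  curve <- fit_calibration(data.frame(net_od = c(0, 0.2, 0.5),
                                      dose = c(0, 0.5, 2)))
  plane <- apply_calibration(curve, matrix(0.1, 4, 4), dpi = scan$dpi)
  expect_equal(plane$spacing, rep(25.4 / 300, 2))
})

test_that("red channel extraction is verbatim and isolated from G/B", {
  px <- array(0L, dim = c(5, 7, 3))
  ramp <- matrix(seq(0L, 65535L, length.out = 35), 5, 7)
  storage.mode(ramp) <- "integer"
  px[, , 1] <- ramp
  p <- tempfile(fileext = ".tif"); vaudit:::write_tiff_rgb16(px, p)
  scan <- read_scan(p)
  expect_identical(red_channel(scan), ramp)          # bit-identical
  px2 <- px; px2[, , 2] <- 100L; px2[, , 3] <- 65535L
  p2 <- tempfile(fileext = ".tif"); vaudit:::write_tiff_rgb16(px2, p2)
  expect_identical(red_channel(read_scan(p2)), ramp) # G/B changes: no effect
})

test_that("optical density follows -log10(PV/ref) with clipping at PV = 1", {
  m <- matrix(c(65535, 6553.5, 0, 655.35), 2, 2)
  od <- optical_density(m, 65535)
  expect_equal(od[1, 1], 0)
  expect_equal(od[2, 1], 1)
  expect_equal(od[1, 2], log10(65535))   # PV clipped to 1
  expect_equal(od[2, 2], 2)
  expect_error(optical_density(m, 0), class = "vaudit_argument_error")
  expect_error(optical_density(m, -5), class = "vaudit_argument_error")
})

test_that("unset-film subtraction cancels shared scanner fields exactly", {
  base <- matrix(0.3, 50, 80)
  grad <- matrix(0.05 * sin(seq(0, 3, length.out = 80)), 50, 80, byrow = TRUE)
  net <- correct_nonuniformity(base + grad + 0.2, base + grad)
  expect_lt(max(abs(net - 0.2)), 1e-12)
  # scalar baseline and trivial cases
  expect_equal(correct_nonuniformity(base, 0), base, ignore_attr = TRUE)
  u <- correct_nonuniformity(matrix(0.5, 3, 3), matrix(0.1, 3, 3))
  expect_true(all(u == 0.4))
  # negative results clip to zero and are counted
  c2 <- correct_nonuniformity(matrix(c(0.1, 0.5), 1, 2), 0.3)
  expect_equal(as.vector(c2), c(0, 0.2))
  expect_identical(attr(c2, "n_clipped"), 1L)
  expect_error(correct_nonuniformity(base, matrix(0, 2, 2)),
               class = "vaudit_argument_error")
})

test_that("subfilm readout averages the clean core only", {
  od <- matrix(0.4, 100, 100)
  region <- list(x = 11, y = 21, w = 50, h = 60)
  expect_equal(mean_region_od(od, region, 0), 0.4)
  expect_equal(mean_region_od(od, region, 0.3), 0.4)
  # contaminate a 10%-wide border; margin 0.2 must see only the clean core
  od2 <- od
  od2[21:26, 11:60] <- 5; od2[75:80, 11:60] <- 5
  od2[21:80, 11:15] <- 5; od2[21:80, 56:60] <- 5
  expect_equal(mean_region_od(od2, region, 0.2), 0.4)
  # margin 0.49 on a 100-px region leaves a 2-px core: still defined
  expect_equal(mean_region_od(od, list(x = 1, y = 1, w = 100, h = 100), 0.49),
               0.4)
  expect_error(mean_region_od(od, region, 0.5), class = "vaudit_argument_error")
  expect_error(mean_region_od(od, list(x = 90, y = 90, w = 20, h = 20), 0.2),
               class = "vaudit_argument_error")  # region outside the map
})

test_that("calibration fitting recovers exact polynomials through the origin", {
  # noise-free cubic: 5 points determine the constrained cubic exactly
  x <- c(0, 0.1, 0.2, 0.3, 0.4)
  d <- 10 * x + 5 * x^2 + 2 * x^3
  curve <- fit_calibration(data.frame(net_od = x, dose = d))
  expect_identical(curve$degree, 3L)
  expect_lt(max(abs(curve$coefs - c(10, 5, 2)) / c(10, 5, 2)), 1e-6)
  expect_lt(max(abs(curve$residuals)), 1e-9)

  # three points: constrained quadratic through all of them, cross-checked
  # against the independently solved 2x2 linear system
  pts <- data.frame(net_od = c(0, 0.2, 0.5), dose = c(0, 0.5, 2.0))
  c3 <- fit_calibration(pts)
  expect_identical(c3$degree, 2L)
  ab <- solve(matrix(c(0.2, 0.2^2, 0.5, 0.5^2), 2, 2, byrow = TRUE),
              c(0.5, 2.0))
  expect_equal(unname(c3$coefs), ab, tolerance = 1e-9)
  expect_lt(max(abs(vaudit:::eval_calibration(c3, pts$net_od) - pts$dose)), 1e-9)

  # dose decreasing with OD -> not monotone -> calibration error
  expect_error(fit_calibration(data.frame(net_od = c(0, 0.2, 0.5),
                                          dose = c(0, 2, 0.5))),
               class = "vaudit_calibration_error")
  expect_error(fit_calibration(data.frame(net_od = c(0, 0.2), dose = c(0, 1))),
               class = "vaudit_argument_error")
  expect_error(fit_calibration(data.frame(net_od = c(0.1, 0.2, 0.3),
                                          dose = c(0.5, 1, 2))),
               class = "vaudit_argument_error")  # no 0 Gy anchor
})

test_that("dose conversion maps OD elementwise and sets the mm pitch from dpi", {
  curve <- fit_calibration(data.frame(net_od = c(0, 0.2, 0.5),
                                      dose = c(0, 0.5, 2)))
  z <- apply_calibration(curve, matrix(0, 5, 5), dpi = 150)
  expect_true(all(z$values == 0))                       # D(0) = 0 constraint
  expect_equal(z$spacing, rep(25.4 / 150, 2))           # 0.16933... mm
  # forward-inverse round trip at several doses, inverse found independently
  inv <- vapply(c(0.3, 1.0, 1.9), function(D)
    uniroot(function(x) vaudit:::eval_calibration(curve, x) - D,
            c(0, 1), tol = 1e-14)$root, 0)
  back <- apply_calibration(curve, matrix(inv, 1, 3), dpi = 150)
  expect_lt(max(abs(back$values - c(0.3, 1.0, 1.9))), 1e-9)
  # OD above the fitted range: extrapolated, with a warning
  expect_warning(apply_calibration(curve, matrix(0.9, 2, 2), dpi = 150),
                 "extrapolation")
})

test_that("fiducial detection: symmetric films give center and zero rotation", {
  od <- plant_marks()
  fid <- detect_fiducials(od, edge_band_fraction = 0.2)
  expect_lt(max(abs(fid$isocenter - 151)), 0.1)
  expect_lt(abs(fid$rotation_deg), 0.01)
})

test_that("fiducial detection recovers planted rotations and off-center isocenters", {
  for (th in c(-2, 2)) {
    od <- plant_marks(theta_deg = th, center = c(160, 140))
    fid <- detect_fiducials(od, edge_band_fraction = 0.25)
    expect_lt(abs(fid$rotation_deg - th), 0.1)
    expect_lt(max(abs(fid$isocenter - c(160, 140))), 0.5)
  }
})

test_that("missing or ambiguous marks abort with the offending side named", {
  od3 <- plant_marks(sides = c("left", "right", "top"))
  err <- tryCatch(detect_fiducials(od3, edge_band_fraction = 0.2),
                  error = identity)
  expect_s3_class(err, "vaudit_fiducial_error")
  expect_identical(err$side, "bottom")
  # two comparable candidates in one band -> refuse to guess
  od_amb <- plant_marks()
  rr <- 50:70; cc <- 10:30   # second, equally strong mark in the left band
  d2 <- outer((rr - 60)^2, (cc - 20)^2, `+`)
  od_amb[rr, cc] <- od_amb[rr, cc] + 1.2 * exp(-d2 / (2 * 2^2))
  err2 <- tryCatch(detect_fiducials(od_amb, edge_band_fraction = 0.2),
                   error = identity)
  expect_s3_class(err2, "vaudit_fiducial_error")
  expect_identical(err2$side, "left")
})

test_that("alignment restores rotated films and recenters pure translations", {
  # identity: zero rotation about the exact grid center
  vals <- matrix(runif(101 * 101, 0, 2), 101, 101)
  plane <- dose_grid_2d(vals, origin = c(0, 0), spacing = c(0.2, 0.2))
  fid0 <- structure(list(isocenter = c(x = 51, y = 51), rotation_deg = 0),
                    class = "fiducial_set")
  out <- align_to_isocenter(plane, fid0)
  ax <- vaudit:::plane_axes(out)
  i0 <- which(abs(ax$u) < 1e-9); j0 <- which(abs(ax$v) < 1e-9)
  expect_equal(out$values[i0, j0], vals[51, 51])
  # pure translation: the marks' intersection maps exactly to (0, 0)
  fidt <- structure(list(isocenter = c(x = 31.25, y = 66.5), rotation_deg = 0),
                    class = "fiducial_set")
  outt <- align_to_isocenter(plane, fidt)
  axt <- vaudit:::plane_axes(outt)
  it <- which(abs(axt$u) < 1e-9); jt <- which(abs(axt$v) < 1e-9)
  truth <- vaudit:::bilinear_sample(vals, c(0, 0), c(0.2, 0.2),
                                    (31.25 - 1) * 0.2, (66.5 - 1) * 0.2)
  expect_equal(outt$values[it, jt], truth, tolerance = 1e-12)
  expect_error(align_to_isocenter(plane, structure(
    list(isocenter = c(x = 51, y = 51), rotation_deg = 12),
    class = "fiducial_set")), class = "vaudit_argument_error")
})

test_that("rotate-and-restore matches the unrotated pipeline within 1% of 2 Gy", {
  b <- fx_film_base()
  run <- function(error) {
    scen <- scenario(seed = 11, grid_extent = c(160, 160, 80),
                     grid_spacing = 2, pixel_noise = 0, error = error)
    film <- make_film_scan(b$plane, scen, fx_dir(paste0("rot_", error$type,
                                                        error$degrees %||% 0)))
    film_audit(film$scan, b$paths$dose, b$paths$plan, film$layout,
               unset_scan_path = film$unset, keep_intermediates = TRUE)
  }
  base <- run(list(type = "none"))
  at <- expand.grid(u = seq(-50, 50, by = 0.5), v = seq(-50, 50, by = 0.5))
  samp <- function(rep_) {
    al <- rep_$diagnostics$aligned
    vaudit:::bilinear_sample(al$values, al$origin, al$spacing, at$u, at$v)
  }
  ref <- samp(base)
  rot <- run(list(type = "rotation", degrees = 2))
  expect_lt(abs(rot$diagnostics$fiducials$rotation_deg - 2), 0.1)
  expect_lt(max(abs(samp(rot) - ref), na.rm = TRUE), 0.01 * 2)
})
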