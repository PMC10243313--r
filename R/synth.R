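# Seeded synthetic-data generator: every input the audit consumes can be
# produced from a scenario object, with plantable delivery errors, so the
# whole toolchain is testable without any external dataset.
#
# Film forward model: PV = 65535 * 10^-(OD_base + g + curve^-1(D)), where g
# is an additive scanner non-uniformity field shared with the unset scan and
# curve^-1 is the monotone inverse of the calibration truth; multiplicative
# Gaussian pixel noise is applied to PV. This makes the film pipeline's
# inverse exactly recoverable, up to the planted noise.

#' Synthetic audit scenario
#'
#' Bundles the seed, grid specification, calibration truth, noise levels and
#' the planted error mode that together define one synthetic audit dataset.
#' With a fixed seed every writer in this module is byte-deterministic.
#'
#' @param seed integer RNG seed.
#' @param grid_extent,grid_spacing dose-grid extent and voxel pitch (mm);
#'   grids are centered on the isocenter with a voxel at (0, 0, 0).
#' @param calibration coefficients `(a1, a2, a3)` of the monotone cubic
#'   calibration truth `D(x) = a1 x + a2 x^2 + a3 x^3` (dose Gy vs net OD).
#' @param pixel_noise multiplicative Gaussian noise s.d. on film pixel
#'   values (fraction; default 0.5%).
#' @param detector_noise additive Gaussian noise s.d. on detector doses
#'   (Gy; default 0.005).
#' @param od_base film-base optical density (default 0.05).
#' @param scanner_gradient peak-to-peak additive OD non-uniformity across
#'   the scan width, shared by exposed and unset scans (default 0.02).
#' @param film_mm side length of the square irradiated film (default 120).
#' @param dpi scan resolution (default 150).
#' @param error planted error: `list(type = "none")`,
#'   `list(type = "subfilm_overdose", actual_gy = 2.293)`,
#'   `list(type = "dose_scale", factor = 1.05)`,
#'   `list(type = "shift", vector_mm = c(...))` (2 components for film, 3
#'   for arrays) or `list(type = "rotation", degrees = 2)`.
#' @return an object of class `vaudit_scenario`.
#' @export
scenario <- function(seed = 1,
                     grid_extent = c(230, 230, 230),
                     grid_spacing = c(2.5, 2.5, 2.5),
                     calibration = c(3.5, 1.5, 2),
                     pixel_noise = 0.005,
                     detector_noise = 0.005,
                     od_base = 0.05,
                     scanner_gradient = 0.02,
                     film_mm = 120,
                     dpi = 150,
                     error = list(type = "none")) {
  if (pixel_noise < 0 || detector_noise < 0)
    stop_argument("noise levels must be >= 0")
  grid_extent <- rep_len(as.numeric(grid_extent), 3)
  grid_spacing <- rep_len(as.numeric(grid_spacing), 3)
  if (any(grid_spacing <= 0)) stop_argument("grid spacing must be > 0")
  type <- match.arg(error$type,
                    c("none", "subfilm_overdose", "dose_scale", "shift", "rotation"))
  structure(list(seed = as.integer(seed), grid_extent = grid_extent,
                 grid_spacing = grid_spacing, calibration = calibration,
                 pixel_noise = pixel_noise, detector_noise = detector_noise,
                 od_base = od_base, scanner_gradient = scanner_gradient,
                 film_mm = film_mm, dpi = dpi, error = error),
            class = "vaudit_scenario")
}

# Fixed C-shape parameters of the audit target (mm / Gy). The C is an
# annular 270-degree arc in the axial plane around a central avoidance
# cylinder, with Gaussian lateral falloff, a 2 Gy per-fraction plateau and a
# broad low-dose bath standing in for entrance/exit dose.
.cshape <- list(r_inner = 15, r_outer = 35, gap_half_deg = 45, edge_sigma = 4,
                z_half = 20, z_sigma = 6, plateau_gy = 2,
                bath_frac = 0.5, bath_sigma = 110)

# Distance from points (x, y) to the annular-arc region (vectorized).
.c_region_distance <- function(x, y, p = .cshape) {
  r <- sqrt(x^2 + y^2)
  alpha <- atan2(x, -y)  # 0 at the anterior gap center
  in_arc <- abs(alpha) >= p$gap_half_deg * pi / 180
  d <- pmax(0, p$r_inner - r, r - p$r_outer)
  seg_dist <- function(ax, ay, bx, by) {
    vx <- bx - ax; vy <- by - ay
    t <- pmin(pmax(((x - ax) * vx + (y - ay) * vy) / (vx^2 + vy^2), 0), 1)
    sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
  }
  gh <- p$gap_half_deg * pi / 180
  # Arc-end edge segments at alpha = +/- gap_half (direction (sin a, -cos a)).
  d_edge <- pmin(
    seg_dist(p$r_inner * sin(gh), -p$r_inner * cos(gh),
             p$r_outer * sin(gh), -p$r_outer * cos(gh)),
    seg_dist(-p$r_inner * sin(gh), -p$r_inner * cos(gh),
             -p$r_outer * sin(gh), -p$r_outer * cos(gh))
  )
  ifelse(in_arc, d, d_edge)
}

#' Analytic C-shaped audit dose distribution
#'
#' Builds the per-fraction planned dose: a 2 Gy plateau on a C-shaped
#' annular arc (270 degrees around a central avoidance cylinder) with
#' Gaussian lateral falloff, a broad low-dose bath, and a longitudinal
#' plateau-plus-falloff profile. The global maximum stays below 110% of
#' 2 Gy and the dose on the avoidance-cylinder axis below 60%. The plan
#' metadata carries the trial prescription (20 Gy in 10 fractions) with the
#' isocenter at the grid center.
#'
#' @param scen a [scenario()].
#' @return a list with elements `grid` ([dose_grid_3d()]) and `plan`
#'   ([plan_info()]).
#' @export
make_c_shape_dose <- function(scen) {
  p <- .cshape
  need <- 2 * (p$r_outer + 2 * p$edge_sigma)
  if (scen$grid_extent[1] < need || scen$grid_extent[2] < need)
    stop_argument(sprintf("grid extent too small to contain the C target (need >= %g mm)", need))
  ax <- lapply(1:3, function(k) {
    h <- floor(scen$grid_extent[k] / 2 / scen$grid_spacing[k])
    (-h:h) * scen$grid_spacing[k]
  })
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  xg <- rep(ax[[1]], times = ny); yg <- rep(ax[[2]], each = nx)
  d <- .c_region_distance(xg, yg, p)
  c_prof <- exp(-d^2 / (2 * p$edge_sigma^2))
  r2 <- xg^2 + yg^2
  bath <- p$bath_frac * exp(-r2 / (2 * p$bath_sigma^2))
  s_xy <- matrix(pmax(c_prof, bath), nx, ny)
  zz <- abs(ax[[3]])
  lz <- ifelse(zz <= p$z_half, 1, exp(-(zz - p$z_half)^2 / (2 * p$z_sigma^2)))
  vals <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vals[, , k] <- p$plateau_gy * s_xy * lz[k]
  list(grid = dose_grid_3d(vals,
                           origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]),
                           spacing = scen$grid_spacing),
       plan = plan_info(isocenter = c(0, 0, 0), n_fractions = 10,
                        prescription_dose = 20, machine = "SYNTH-LINAC",
                        tps = "SYNTH-TPS"))
}

#' Write synthetic DICOM-RT Dose and Plan files
#'
#' Encodes the grid and plan as standards-conformant part-10 files (explicit
#' VR little endian) that [read_rt_dose()] / [read_rt_plan()] read back
#' equal: dose values to the 16-bit scaling quantum, geometry exactly.
#'
#' @param grid a [dose_grid_3d()].
#' @param plan a [plan_info()].
#' @param out_dir output directory (created if needed).
#' @param seed integer; determines the generated DICOM UIDs.
#' @return named list with the written `dose` and `plan` paths.
#' @export
write_rt_files <- function(grid, plan, out_dir, seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dose_path <- file.path(out_dir, "rtdose.dcm")
  plan_path <- file.path(out_dir, "rtplan.dcm")
  write_rt_dose_file(grid, dose_path, seed = seed)
  write_rt_plan_file(plan, plan_path, seed = seed)
  list(dose = dose_path, plan = plan_path)
}

## ---- TIFF writing ---------------------------------------------------------

# Uncompressed 16-bit/channel RGB TIFF writer with resolution tags.
# Independent of the tiff-package reader used by the film module, which
# makes the scan round-trip tests a genuine cross-implementation check.
write_tiff_rgb16 <- function(pixels, path, dpi = 150) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop_argument("'pixels' must be [rows, cols, 3]")
  h <- d[1]; w <- d[2]
  data_off <- 8L
  data_len <- w * h * 3L * 2L
  bps_off <- data_off + data_len            # BitsPerSample (3 x SHORT)
  xres_off <- bps_off + 6L                  # RATIONALs
  yres_off <- xres_off + 8L
  ifd_off <- yres_off + 8L
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) {
    x <- as.numeric(x)
    c(u16(x %% 65536), u16(x %/% 65536))
  }
  entry_short <- function(tag, value) c(u16(tag), u16(3), u32(1), u16(value), u16(0))
  entry_long <- function(tag, value) c(u16(tag), u16(4), u32(1), u32(value))
  entry_off <- function(tag, type, count, off) c(u16(tag), u16(type), u32(count), u32(off))
  entries <- list(
    entry_long(256, w), entry_long(257, h),
    entry_off(258, 3, 3, bps_off),
    entry_short(259, 1), entry_short(262, 2),
    entry_long(273, data_off),
    entry_short(277, 3), entry_long(278, h),
    entry_long(279, data_len),
    entry_off(282, 5, 1, xres_off), entry_off(283, 5, 1, yres_off),
    entry_short(284, 1), entry_short(296, 2)
  )
  ifd <- c(u16(length(entries)), do.call(c, entries), u32(0))
  # channel-interleaved, row-major
  interleaved <- as.integer(aperm(pixels, c(3, 2, 1)))
  out <- c(charToRaw("II"), u16(42), u32(ifd_off),
           writeBin(interleaved, raw(), size = 2, endian = "little"),
           u16(c(16, 16, 16)),
           u32(dpi), u32(1), u32(dpi), u32(1),
           ifd)
  writeBin(out, path)
  invisible(path)
}

## ---- film scan synthesis --------------------------------------------------

.film_od_to_pv <- function(od, noise_sd) {
  pv <- 65535 * 10^(-od)
  if (noise_sd > 0) pv <- pv * (1 + rnorm(length(pv), 0, noise_sd))
  m <- matrix(as.integer(pmin(pmax(round(pv), 0), 65535)), nrow(od), ncol(od))
  m
}

#' Synthesize a composite film scan
#'
#' Paints the irradiated film (pixel values obtained by inverting the
#' calibration truth at the dose plane's values, with seeded multiplicative
#' noise), three calibration subfilms at nominal 0 / 0.5 / 2 Gy, four
#' fiducial marks consistent with the scenario rotation, film-base OD and a
#' shared scanner-gradient field; writes the 150 dpi 48-bit RGB TIFF, a
#' separate unset-film scan of the same canvas, and the matching layout
#' JSON. Under `subfilm_overdose` the 2 Gy subfilm is painted at the actual
#' dose while the layout still declares 2 Gy; under `shift`/`rotation` the
#' delivered distribution is shifted relative to the fiducials, or the whole
#' film is rotated in the scanner.
#'
#' @param dose_plane the delivered dose as a [dose_grid_2d()] in
#'   isocenter-centered coordinates (axis 1 = film u, axis 2 = film v, mm).
#' @param scen a [scenario()].
#' @param out_dir output directory.
#' @return named list of written paths: `scan`, `unset`, `layout`.
#' @export
make_film_scan <- function(dose_plane, scen, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  px_mm <- 25.4 / scen$dpi
  film_px <- round(scen$film_mm / px_mm)
  margin <- 40L
  sub_px <- 180L
  sub_gap <- 60L
  film_rect <- list(x = margin + 1, y = margin + 1, w = film_px, h = film_px)
  sub_x <- margin + film_px + sub_gap
  sub_doses <- c(0, 0.5, 2)
  sub_rects <- lapply(seq_along(sub_doses), function(i) {
    list(x = sub_x, y = margin + 1 + (i - 1) * (sub_px + sub_gap),
         w = sub_px, h = sub_px, dose_gy = sub_doses[i])
  })
  W <- sub_x + sub_px + margin
  H <- max(margin + film_px, margin + 3 * sub_px + 2 * sub_gap) + margin
  err <- scen$error
  theta <- if (err$type == "rotation") err$degrees * pi / 180 else 0
  shift <- if (err$type == "shift") rep_len(as.numeric(err$vector_mm), 2) else c(0, 0)

  od <- matrix(0, H, W)                          # scanner bed: fully white
  gradient <- matrix(scen$scanner_gradient * ((seq_len(W) - 1) / (W - 1) - 0.5),
                     H, W, byrow = TRUE)

  # irradiated film: base + dose image (rotated/shifted delivered field)
  rows <- film_rect$y:(film_rect$y + film_rect$h - 1)
  cols <- film_rect$x:(film_rect$x + film_rect$w - 1)
  ctr <- c(x = film_rect$x + (film_rect$w - 1) / 2,
           y = film_rect$y + (film_rect$h - 1) / 2)
  pc <- (rep(cols, each = length(rows)) - ctr["x"]) * px_mm   # [row, col] order
  pr <- (rep(rows, times = length(cols)) - ctr["y"]) * px_mm
  qu <- cos(-theta) * pc - sin(-theta) * pr - shift[1]
  qv <- sin(-theta) * pc + cos(-theta) * pr - shift[2]
  dose_vals <- bilinear_sample(dose_plane$values, dose_plane$origin,
                               dose_plane$spacing, qu, qv)
  dose_vals[is.na(dose_vals)] <- 0
  net <- invert_calibration(scen$calibration, dose_vals)
  od[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <-
    scen$od_base + net

  # fiducial marks: Gaussian OD bumps at the rotated mid-side positions
  a <- (film_px / 2 - 25)
  eu <- c(cos(theta), sin(theta)); ev <- c(-sin(theta), cos(theta))
  mark_pos <- list(ctr[c("x", "y")] - a * eu, ctr[c("x", "y")] + a * eu,
                   ctr[c("x", "y")] - a * ev, ctr[c("x", "y")] + a * ev)
  for (mp in mark_pos) {
    sel_r <- max(1, floor(mp[2] - 12)):min(H, ceiling(mp[2] + 12))
    sel_c <- max(1, floor(mp[1] - 12)):min(W, ceiling(mp[1] + 12))
    dd2 <- outer((sel_r - mp[2])^2, (sel_c - mp[1])^2, `+`)
    od[sel_r, sel_c] <- od[sel_r, sel_c] + 1.3 * exp(-dd2 / (2 * 2.5^2))
  }

  # subfilms: uniform nominal dose (or the planted overdose on the 2 Gy one)
  for (i in seq_along(sub_rects)) {
    r <- sub_rects[[i]]
    actual <- r$dose_gy
    if (err$type == "subfilm_overdose" && r$dose_gy == 2) actual <- err$actual_gy
    od[r$y:(r$y + r$h - 1), r$x:(r$x + r$w - 1)] <-
      scen$od_base + invert_calibration(scen$calibration, actual)
  }

  pixels <- array(0L, dim = c(H, W, 3))
  unset_od <- matrix(scen$od_base, H, W) + gradient
  unset_pixels <- array(0L, dim = c(H, W, 3))
  with_seed(scen$seed, {
    for (ch in 1:3) {
      f <- c(1, 0.7, 0.4)[ch]   # dye absorbs mostly in the red
      pixels[, , ch] <- .film_od_to_pv(od * f + gradient, scen$pixel_noise)
      unset_pixels[, , ch] <- .film_od_to_pv(unset_od * f + gradient * (1 - f),
                                             scen$pixel_noise)
    }
  })
  scan_path <- file.path(out_dir, "scan.tif")
  unset_path <- file.path(out_dir, "unset.tif")
  layout_path <- file.path(out_dir, "layout.json")
  write_tiff_rgb16(pixels, scan_path, dpi = scen$dpi)
  write_tiff_rgb16(unset_pixels, unset_path, dpi = scen$dpi)
  write_scan_layout(scan_layout(film = film_rect, subfilms = sub_rects,
                                dpi = scen$dpi), layout_path)
  list(scan = scan_path, unset = unset_path, layout = layout_path)
}

## ---- array measurement synthesis ------------------------------------------

#' Synthesize an array-detector measurement export
#'
#' Detector doses are the planned grid sampled trilinearly at the detector
#' positions, with the scenario's planted `dose_scale` or `shift` applied to
#' the delivered distribution, plus seeded additive Gaussian noise; written
#' in the tab-separated text dialect of [write_measured_text()].
#'
#' @param grid planned dose as a [dose_grid_3d()].
#' @param geom a `detector_geometry`.
#' @param scen a [scenario()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
make_array_measurement <- function(grid, geom, scen, path) {
  err <- scen$error
  scale <- if (err$type == "dose_scale") err$factor else 1
  shift <- if (err$type == "shift") rep_len(as.numeric(err$vector_mm), 3) else c(0, 0, 0)
  det <- geom$detectors
  d <- trilinear_sample(grid$values, grid$origin, grid$spacing,
                        det$x - shift[1], det$y - shift[2], det$z - shift[3])
  if (anyNA(d))
    stop_bounds("detector positions (after shift) fall outside the dose grid")
  d <- d * scale
  if (scen$detector_noise > 0)
    d <- with_seed(scen$seed + 17L, d + rnorm(length(d), 0, scen$detector_noise))
  d <- pmax(d, 0)
  ms <- measured_set(geom$device, setNames(d, det$id),
                     meta = list(seed = as.character(scen$seed),
                                 error = err$type))
  write_measured_text(ms, path)
}
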