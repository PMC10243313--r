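# Radiochromic-film pipeline: composite scan -> absolute 2-D dose aligned to
# the plan isocenter.
#
# Image-space convention: pixel matrices are [row, col] with row = scanner y
# (downwards) and col = scanner x (rightwards), 1-based. Rectangles are
# (x, y, w, h) with (x, y) the top-left pixel. Dose planes returned to the
# gamma stage use axis 1 = x and axis 2 = y in millimetres.

## ---- scan layout ----------------------------------------------------------

layout_rect <- function(r) {
  r <- as.list(r)
  if (!all(c("x", "y", "w", "h") %in% names(r)))
    stop_argument("rectangle needs fields x, y, w, h (pixels)")
  lapply(r[c("x", "y", "w", "h")], as.numeric)
}

rects_overlap <- function(a, b) {
  !(a$x + a$w <= b$x || b$x + b$w <= a$x || a$y + a$h <= b$y || b$y + b$h <= a$y)
}

#' Composite-scan layout
#'
#' Describes where the irradiated film, the calibration subfilms (with their
#' nominal doses) and optionally an unset-film region sit within a scan, in
#' pixels. At least three subfilms including one at 0 Gy are required; all
#' rectangles must be pairwise disjoint.
#'
#' @param film rectangle `list(x, y, w, h)` of the irradiated film (px).
#' @param subfilms list of rectangles, each with an additional `dose_gy`.
#' @param unset optional rectangle of the unset-film region.
#' @param dpi nominal scan resolution recorded in the layout.
#' @return an object of class `scan_layout`.
#' @export
scan_layout <- function(film, subfilms, unset = NULL, dpi = 150) {
  film <- layout_rect(film)
  if (length(subfilms) < 3) stop_argument("at least 3 subfilms are required")
  subs <- lapply(subfilms, function(s) {
    r <- layout_rect(s)
    if (is.null(s$dose_gy) || s$dose_gy < 0)
      stop_argument("each subfilm needs a nominal dose_gy >= 0")
    r$dose_gy <- as.numeric(s$dose_gy)
    r
  })
  if (!any(vapply(subs, function(s) s$dose_gy == 0, TRUE)))
    stop_argument("one subfilm must have nominal dose 0 Gy")
  if (!is.null(unset)) unset <- layout_rect(unset)
  rects <- c(list(film), subs, if (!is.null(unset)) list(unset))
  for (i in seq_along(rects)) for (j in seq_len(i - 1)) {
    if (rects_overlap(rects[[i]], rects[[j]]))
      stop_argument("layout rectangles must be pairwise disjoint")
  }
  structure(list(film = film, subfilms = subs, unset = unset,
                 dpi = as.numeric(dpi)),
            class = "scan_layout")
}

#' Read a scan layout from JSON
#' @param path path to the layout JSON file.
#' @return a [scan_layout()] object.
#' @export
read_scan_layout <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scan_layout(film = j$film, subfilms = j$subfilms, unset = j$unset,
              dpi = if (is.null(j$dpi)) 150 else j$dpi)
}

write_scan_layout <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

rect_crop <- function(mat, rect) {
  if (rect$x < 1 || rect$y < 1 || rect$x + rect$w - 1 > ncol(mat) ||
      rect$y + rect$h - 1 > nrow(mat))
    stop_argument("rectangle outside image bounds")
  mat[rect$y:(rect$y + rect$h - 1), rect$x:(rect$x + rect$w - 1), drop = FALSE]
}

## ---- scan reading ---------------------------------------------------------

#' Read a film scan (16-bit RGB TIFF)
#'
#' Loads the scan as integer pixel values (0..65535 per channel) and the
#' scan resolution from the TIFF metadata. A resolution differing from
#' `expected_dpi` is accepted with a warning recorded on the scan (and the
#' metadata value is what downstream mm scaling uses); files that are not
#' 16 bits/channel RGB are rejected.
#'
#' @param path path to the TIFF file.
#' @param expected_dpi nominal resolution, default 150.
#' @return an object of class `film_scan` with fields `pixels`
#'   (`[row, col, channel]` integer array), `dpi`, `channels`, `warnings`.
#' @export
read_scan <- function(path, expected_dpi = 150) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits) || bits != 16L)
    stop_format(sprintf("expected 16 bits/channel (48-bit RGB), got %s bits",
                        if (is.null(bits)) "unknown" else bits))
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop_format("expected an RGB scan; got a grayscale or indexed image")
  warnings <- character(0)
  dpi <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (is.null(dpi)) {
    warnings <- c(warnings, sprintf(
      "no resolution metadata in scan; assuming %g dpi", expected_dpi))
    dpi <- expected_dpi
  } else {
    if (!is.null(unit) && identical(unit, "cm")) dpi <- dpi * 2.54
    if (abs(dpi - expected_dpi) > 1e-6)
      warnings <- c(warnings, sprintf(
        "scan resolution %g dpi differs from expected %g dpi", dpi, expected_dpi))
  }
  pixels <- round(img[, , 1:3, drop = FALSE] * 65535)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, dpi = as.numeric(dpi),
                 channels = c("R", "G", "B"), warnings = warnings),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<film_scan> %d x %d px, %d channels, %g dpi\n",
              d[1], d[2], d[3], x$dpi))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Extract the red channel
#'
#' Returns the R channel verbatim — no smoothing, filtering or type change.
#'
#' @param scan a [read_scan()] result.
#' @return integer matrix `[row, col]` of red-channel pixel values.
#' @export
red_channel <- function(scan) {
  if (!inherits(scan, "film_scan")) stop_argument("'scan' must be a film_scan")
  scan$pixels[, , 1]
}

## ---- optical density ------------------------------------------------------

#' Optical density from pixel values
#'
#' `OD = -log10(PV / reference_value)` elementwise, with pixel values
#' clipped to `>= 1` before the ratio so fully opaque pixels stay finite.
#'
#' @param response numeric matrix of pixel values (e.g. [red_channel()]).
#' @param reference_value transmission reference (scanner white level);
#'   default 65535.
#' @return matrix of optical densities.
#' @export
optical_density <- function(response, reference_value = 65535) {
  if (!is.numeric(reference_value) || length(reference_value) != 1 ||
      !is.finite(reference_value) || reference_value <= 0)
    stop_argument("'reference_value' must be a positive number")
  pv <- pmax(response, 1)
  od <- -log10(pv / reference_value)
  dim(od) <- dim(response)
  od
}

#' Scanner non-uniformity correction (unset-film subtraction)
#'
#' Net OD is the exposed-film OD minus the unset-film OD (a full map or a
#' scalar baseline); any additive scanner-response field present in both
#' scans cancels exactly. Negative net values are sub-base readings (noise);
#' they are clipped to 0 and counted in the `"n_clipped"` attribute.
#'
#' @param od OD map of the exposed scan region.
#' @param unset_od matching OD map of the unset film, or a scalar baseline.
#' @return net OD map with attribute `n_clipped`.
#' @export
correct_nonuniformity <- function(od, unset_od) {
  if (length(unset_od) > 1 && !identical(dim(od), dim(unset_od)))
    stop_argument("'unset_od' map must match the shape of 'od'")
  net <- od - unset_od
  n_clipped <- sum(net < 0)
  net[net < 0] <- 0
  attr(net, "n_clipped") <- n_clipped
  net
}

#' Mean OD of a region core
#'
#' Shrinks the rectangle by `margin_fraction` on each side (discarding
#' contaminated borders) and returns the mean OD of the remaining core.
#'
#' @param od OD map.
#' @param region rectangle `list(x, y, w, h)` in map pixels.
#' @param margin_fraction fraction (`0 <= f < 0.5`) trimmed from each side.
#' @return scalar mean OD.
#' @export
mean_region_od <- function(od, region, margin_fraction = 0.2) {
  if (margin_fraction < 0 || margin_fraction >= 0.5)
    stop_argument("'margin_fraction' must be in [0, 0.5)")
  region <- layout_rect(region)
  mx <- floor(region$w * margin_fraction)
  my <- floor(region$h * margin_fraction)
  core <- list(x = region$x + mx, y = region$y + my,
               w = region$w - 2 * mx, h = region$h - 2 * my)
  if (core$w < 1 || core$h < 1) stop_argument("margin leaves an empty core region")
  mean(rect_crop(od, core))
}

## ---- calibration ----------------------------------------------------------

#' Fit a constrained polynomial calibration curve
#'
#' Least-squares polynomial `D(x) = a1 x + a2 x^2 + ... + ad x^d` mapping
#' net optical density to dose with the zero-dose constraint `D(0) = 0`
#' (anchored by the 0 Gy subfilm) and degree `d = min(3, n_points - 1)`: the
#' canonical three-subfilm set yields a constrained quadratic, five or more
#' points the full constrained cubic. The fit must be strictly increasing
#' over the fitted OD range.
#'
#' @param points data frame (or list of pairs) with columns `net_od` and
#'   `dose` (Gy); at least 3 distinct points including one at dose 0.
#' @return an object of class `calibration_curve` with fields `coefs`
#'   (`a1..ad`), `degree`, `od_range`, `residuals`, `points`.
#' @export
fit_calibration <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(net_od = p[[1]], dose = p[[2]])))
  if (!all(c("net_od", "dose") %in% names(points)))
    stop_argument("'points' needs columns net_od and dose")
  points <- points[order(points$net_od), ]
  if (nrow(unique(points)) < 3)
    stop_argument("at least 3 distinct calibration points are required")
  if (min(points$dose) > 1e-9)
    stop_argument("a 0 Gy calibration point is required (zero-dose constraint)")
  n <- nrow(points)
  degree <- min(3L, n - 1L)
  X <- outer(points$net_od, seq_len(degree), `^`)
  fit <- lm.fit(X, points$dose)
  coefs <- setNames(fit$coefficients, paste0("a", seq_len(degree)))
  coefs[is.na(coefs)] <- 0
  od_max <- max(points$net_od)
  xs <- seq(0, od_max, length.out = 256)[-1]
  deriv <- rep(0, length(xs))
  for (j in seq_len(degree)) deriv <- deriv + j * coefs[j] * xs^(j - 1)
  if (any(deriv <= 0) || coefs[1] <= 0)
    stop_calibration("fitted calibration curve is not strictly increasing over the OD range")
  structure(list(coefs = coefs, degree = degree, od_range = c(0, od_max),
                 residuals = unname(points$dose - as.vector(X %*% coefs)),
                 points = points),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> degree %d, D(x) = %s, OD range [0, %.3g]\n",
              x$degree,
              paste(sprintf("%+.4g x^%d", x$coefs, seq_along(x$coefs)),
                    collapse = " "),
              x$od_range[2]))
  invisible(x)
}

# Evaluate a calibration curve at net OD values.
eval_calibration <- function(curve, x) polyval0(curve$coefs, x)

# Invert a monotone calibration curve: net OD producing each dose. Used by
# the synthesis forward model; dense monotone interpolation of the forward
# curve (exact to ~1e-8 OD at 4096 knots).
invert_calibration <- function(coefs, dose, od_max = 2) {
  xs <- seq(0, od_max, length.out = 4096)
  ds <- polyval0(coefs, xs)
  if (any(diff(ds) <= 0)) stop_argument("calibration truth must be monotone")
  if (any(dose > max(ds))) stop_argument("dose outside invertible range")
  stats::approx(ds, xs, xout = pmax(dose, 0), rule = 2)$y
}

#' Convert a net OD map to absolute dose
#'
#' Applies the calibration polynomial elementwise. OD values above the
#' fitted range are evaluated by polynomial extrapolation and counted in an
#' `n_extrapolated` attribute (with a warning). The pixel pitch is
#' `25.4 / dpi` mm.
#'
#' @param curve a [fit_calibration()] result.
#' @param net_od net OD map (`[row, col]`, image space).
#' @param dpi scan resolution (dots per inch).
#' @param orientation plane label for the resulting dose plane.
#' @return a [dose_grid_2d()] with axis 1 = scanner x, axis 2 = scanner y
#'   (mm, origin at the first pixel center).
#' @export
apply_calibration <- function(curve, net_od, dpi, orientation = "axial") {
  if (!inherits(curve, "calibration_curve"))
    stop_argument("'curve' must be a calibration_curve")
  if (dpi <= 0) stop_argument("'dpi' must be > 0")
  n_extra <- sum(net_od > curve$od_range[2] + 1e-12)
  if (n_extra > 0)
    warning(sprintf("%d pixel(s) above the fitted OD range; polynomial extrapolation used",
                    n_extra), call. = FALSE)
  dose <- eval_calibration(curve, net_od)
  dose[dose < 0] <- 0
  px_mm <- 25.4 / dpi
  plane <- dose_grid_2d(t(dose), origin = c(0, 0), spacing = c(px_mm, px_mm),
                        orientation = orientation)
  attr(plane, "n_extrapolated") <- n_extra
  plane
}

## ---- fiducial registration ------------------------------------------------

# Locate the strongest high-OD blob in one edge band. Returns the
# intensity-weighted centroid in band-local (x, y) pixels.
.find_mark <- function(band, side, min_peak_od) {
  mx <- max(band)
  if (mx < min_peak_od)
    stop_fiducial(sprintf("no fiducial mark above the detection threshold on the %s side", side),
                  side = side)
  th <- EBImage::otsu(band / mx, range = c(0, 1)) * mx
  mask <- band > th
  if (!any(mask))
    stop_fiducial(sprintf("no fiducial mark above the detection threshold on the %s side", side),
                  side = side)
  lab <- EBImage::bwlabel(mask)
  excess <- band - th
  masses <- vapply(seq_len(max(lab)), function(k) sum(excess[lab == k]), 0)
  ord <- order(masses, decreasing = TRUE)
  if (length(masses) > 1 && masses[ord[2]] >= 0.8 * masses[ord[1]])
    stop_fiducial(sprintf("ambiguous fiducial candidates of comparable strength on the %s side", side),
                  side = side)
  best <- ord[1]
  if (max(band[lab == best]) < min_peak_od)
    stop_fiducial(sprintf("no fiducial mark above the detection threshold on the %s side", side),
                  side = side)
  sel <- lab == best
  w <- excess[sel]
  rows <- row(band)[sel]; cols <- col(band)[sel]
  c(x = sum(cols * w) / sum(w), y = sum(rows * w) / sum(w))
}

#' Detect the four fiducial marks and the film isocenter
#'
#' Searches one band along each image side (band width =
#' `edge_band_fraction` times the image size) for the strongest connected
#' high-OD blob (automatic Otsu threshold per band; an ambiguous second
#' candidate within 80% of the strongest mass is an error — audits fail
#' loudly rather than guess). The isocenter is the intersection of the two
#' lines joining opposite marks; the rotation is the mean angular deviation
#' of those lines from the image axes.
#'
#' @param od OD map of the film region (`[row, col]`).
#' @param edge_band_fraction band width as a fraction of the image size;
#'   default 0.12.
#' @param min_peak_od minimum peak OD for a blob to count as a mark.
#' @return an object of class `fiducial_set`: `marks` (per-side centroids,
#'   px), `isocenter` (px), `rotation_deg`.
#' @export
detect_fiducials <- function(od, edge_band_fraction = 0.12, min_peak_od = 0.6) {
  nr <- nrow(od); nc <- ncol(od)
  bw <- max(2L, round(edge_band_fraction * nc))
  bh <- max(2L, round(edge_band_fraction * nr))
  bands <- list(
    left   = list(rows = seq_len(nr), cols = seq_len(bw)),
    right  = list(rows = seq_len(nr), cols = (nc - bw + 1):nc),
    top    = list(rows = seq_len(bh), cols = seq_len(nc)),
    bottom = list(rows = (nr - bh + 1):nr, cols = seq_len(nc))
  )
  marks <- lapply(names(bands), function(side) {
    b <- bands[[side]]
    cen <- .find_mark(od[b$rows, b$cols, drop = FALSE], side, min_peak_od)
    c(x = unname(cen["x"]) + b$cols[1] - 1, y = unname(cen["y"]) + b$rows[1] - 1)
  })
  names(marks) <- names(bands)
  mL <- marks$left; mR <- marks$right; mT <- marks$top; mB <- marks$bottom
  # Intersection of lines left-right and top-bottom.
  d1 <- mR - mL; d2 <- mB - mT
  den <- d1["x"] * d2["y"] - d1["y"] * d2["x"]
  if (abs(den) < 1e-9) stop_fiducial("fiducial lines are parallel")
  t1 <- ((mT["x"] - mL["x"]) * d2["y"] - (mT["y"] - mL["y"]) * d2["x"]) / den
  iso <- c(x = unname(mL["x"] + t1 * d1["x"]), y = unname(mL["y"] + t1 * d1["y"]))
  ang_lr <- atan2(d1["y"], d1["x"])            # deviation from image x axis
  ang_tb <- atan2(-d2["x"], d2["y"])           # deviation from image y axis
  rotation <- mean(c(ang_lr, ang_tb)) * 180 / pi
  if (abs(rotation) > 10)
    stop_fiducial(sprintf("implausible film rotation %.1f deg (sanity bound 10 deg)",
                          rotation))
  structure(list(marks = do.call(rbind, marks), isocenter = iso,
                 rotation_deg = unname(rotation)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> isocenter (%.1f, %.1f) px, rotation %.3f deg\n",
              x$isocenter["x"], x$isocenter["y"], x$rotation_deg))
  invisible(x)
}

#' Register a film dose plane to the isocenter
#'
#' Rotates the dose plane by minus the detected rotation about the detected
#' isocenter (bilinear resampling) and re-centers it so the isocenter sits
#' at in-plane coordinate (0, 0). Output pixels that fall outside the film
#' support are `NA` and are excluded from all downstream statistics.
#'
#' @param dose film dose plane from [apply_calibration()] (axis 1 = x,
#'   axis 2 = y, origin at the first pixel).
#' @param fid a [detect_fiducials()] result (`|rotation| <= 10` degrees).
#' @return a [dose_grid_2d()] centered on the isocenter.
#' @export
align_to_isocenter <- function(dose, fid) {
  if (!inherits(dose, "dose_grid2")) stop_argument("'dose' must be a dose_grid2")
  if (!inherits(fid, "fiducial_set")) stop_argument("'fid' must be a fiducial_set")
  if (abs(fid$rotation_deg) > 10)
    stop_argument("|rotation| must be <= 10 degrees")
  s <- dose$spacing
  iso_mm <- c(dose$origin[1] + (fid$isocenter["x"] - 1) * s[1],
              dose$origin[2] + (fid$isocenter["y"] - 1) * s[2])
  d <- dim(dose$values)
  # Cover the whole rotated support: half-extent = farthest corner distance.
  corners_u <- dose$origin[1] + c(0, d[1] - 1) * s[1]
  corners_v <- dose$origin[2] + c(0, d[2] - 1) * s[2]
  hw <- max(sqrt(outer((corners_u - iso_mm[1])^2, (corners_v - iso_mm[2])^2, `+`)))
  n_half <- ceiling(hw / s[1])
  u <- (-n_half:n_half) * s[1]
  v <- (-n_half:n_half) * s[2]
  th <- fid$rotation_deg * pi / 180
  cu <- rep(u, times = length(v)); cv <- rep(v, each = length(u))
  px <- iso_mm[1] + cos(th) * cu - sin(th) * cv
  py <- iso_mm[2] + sin(th) * cu + cos(th) * cv
  vals <- matrix(bilinear_sample(dose$values, dose$origin, dose$spacing, px, py),
                 nrow = length(u), ncol = length(v))
  dose_grid_2d(vals, origin = c(u[1], v[1]), spacing = s,
               orientation = dose$orientation, offplane = dose$offplane)
}
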