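# Detector-array geometries and measured-data handling.
#
# ArcCHECK is modeled as a helical diode lattice on a cylinder (default
# radius 104 mm — a vendor constant, overridable and recorded in reports)
# with 10 mm spacing along the helix and a 10 mm axial pitch between turns.
# Analysis happens on the unwrapped cylinder surface with arc length 0 at
# the posterior-most detector column and z = 0 at the isocenter. Delta4 is
# modeled as two orthogonal detector planes (coronal and sagittal) with
# 5 mm pitch in the central 60 x 60 mm region and 10 mm outside.

#' ArcCHECK helical detector geometry
#'
#' Builds the helical diode lattice: consecutive detectors are `spacing_mm`
#' apart in arc length along the helix, and successive turns are
#' `spacing_mm` apart axially. Each detector carries its unwrap coordinates
#' `(u, v)`: `u` is the cylinder arc length from the posterior column
#' (range \eqn{[-\pi r, \pi r)}), `v` is the axial position z (mm, 0 at the
#' isocenter).
#'
#' @param radius_mm cylinder radius (mm); vendor constant, default 104.
#' @param spacing_mm helix arc spacing and turn pitch (mm); default 10.
#' @param length_mm axial extent of the cylinder (mm); default 210.
#' @return an object of class `detector_geometry`.
#' @export
arccheck_geometry <- function(radius_mm = 104, spacing_mm = 10, length_mm = 210) {
  if (radius_mm <= 0 || spacing_mm <= 0 || length_mm <= 0)
    stop_argument("geometry parameters must be positive")
  circ <- 2 * pi * radius_mm
  helix_per_turn <- sqrt(circ^2 + spacing_mm^2)   # arc length of one turn
  n_turns <- length_mm / spacing_mm
  total <- helix_per_turn * n_turns
  s <- seq(0, total + 1e-9, by = spacing_mm)
  s <- s[s <= total + 1e-9]
  theta <- s * 2 * pi / helix_per_turn
  z <- -length_mm / 2 + s * spacing_mm / helix_per_turn
  wrapped <- ((theta + pi) %% (2 * pi)) - pi
  det <- data.frame(
    id = sprintf("AC%04d", seq_along(s)),
    x = radius_mm * sin(theta),
    y = radius_mm * cos(theta),
    z = z,
    u = radius_mm * wrapped,
    v = z,
    plane = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(
    list(device = "arccheck", detectors = det,
         radius_mm = radius_mm, spacing_mm = spacing_mm, length_mm = length_mm),
    class = "detector_geometry"
  )
}

#' Delta4 dual-plane detector geometry
#'
#' Two orthogonal detector planes through the isocenter (labelled coronal,
#' y = 0, and sagittal, x = 0) with in-plane pitch `pitch_central_mm` inside
#' the central `2*central_halfwidth_mm` square (boundary inclusive) and
#' `pitch_outer_mm` outside, out to `half_extent_mm`. Detectors on the
#' shared axis line (x = y = 0) are assigned to the coronal plane only, so
#' ids and physical positions are unique.
#'
#' @param central_halfwidth_mm half-width of the fine-pitch central zone
#'   (mm); default 30 (a 60 x 60 mm region).
#' @param pitch_central_mm,pitch_outer_mm detector pitches (mm); defaults 5
#'   and 10.
#' @param half_extent_mm half-extent of each board (mm); default 90.
#' @return an object of class `detector_geometry`.
#' @export
delta4_geometry <- function(central_halfwidth_mm = 30, pitch_central_mm = 5,
                            pitch_outer_mm = 10, half_extent_mm = 90) {
  ch <- central_halfwidth_mm
  fine <- seq(-ch, ch, by = pitch_central_mm)
  coarse <- seq(-half_extent_mm, half_extent_mm, by = pitch_outer_mm)
  central <- expand.grid(a = fine, b = fine)
  outer <- expand.grid(a = coarse, b = coarse)
  outer <- outer[!(abs(outer$a) <= ch & abs(outer$b) <= ch), , drop = FALSE]
  pts <- rbind(central, outer)
  cor <- pts
  sag <- pts[pts$a != 0, , drop = FALSE]  # axis line belongs to the coronal plane
  det <- rbind(
    data.frame(id = sprintf("C%04d", seq_len(nrow(cor))),
               x = cor$a, y = 0, z = cor$b, u = cor$a, v = cor$b,
               plane = "coronal", stringsAsFactors = FALSE),
    data.frame(id = sprintf("S%04d", seq_len(nrow(sag))),
               x = 0, y = sag$a, z = sag$b, u = sag$a, v = sag$b,
               plane = "sagittal", stringsAsFactors = FALSE)
  )
  structure(
    list(device = "delta4", detectors = det,
         central_halfwidth_mm = ch, pitch_central_mm = pitch_central_mm,
         pitch_outer_mm = pitch_outer_mm, half_extent_mm = half_extent_mm),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry %s> %d detectors\n", x$device, nrow(x$detectors)))
  invisible(x)
}

#' Per-detector measured (or sampled) doses
#'
#' @param device `"arccheck"` or `"delta4"`.
#' @param doses named numeric vector, names are detector ids; finite, >= 0.
#' @param meta free-form acquisition metadata (named list of strings).
#' @return an object of class `measured_set`.
#' @export
measured_set <- function(device, doses, meta = list()) {
  device <- match.arg(device, c("arccheck", "delta4"))
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop_argument("'doses' must be named by detector id")
  if (anyDuplicated(names(doses)))
    stop_validation("duplicate detector ids in measured set")
  if (any(!is.finite(doses)) || any(doses < 0))
    stop_argument("measured doses must be finite and >= 0")
  structure(list(device = device, doses = doses, meta = meta),
            class = "measured_set")
}

#' Sample a planned dose grid at the detector positions
#'
#' Trilinear interpolation of the plan dose at each detector's 3-D position.
#'
#' @param plan a [dose_grid_3d()] object.
#' @param geom a `detector_geometry` object.
#' @return a [measured_set()] with one dose per detector.
#' @export
sample_at_detectors <- function(plan, geom) {
  if (!inherits(plan, "dose_grid3")) stop_argument("'plan' must be a dose_grid3")
  if (!inherits(geom, "detector_geometry"))
    stop_argument("'geom' must be a detector_geometry")
  det <- geom$detectors
  d <- trilinear_sample(plan$values, plan$origin, plan$spacing,
                        det$x, det$y, det$z)
  if (anyNA(d)) {
    bad <- det$id[is.na(d)]
    stop_bounds(sprintf("%d detector(s) outside the dose grid: %s%s",
                        length(bad), paste(head(bad, 8), collapse = ", "),
                        if (length(bad) > 8) ", ..." else ""),
                ids = bad)
  }
  measured_set(geom$device, setNames(d, det$id))
}

#' Unwrap ArcCHECK measurements onto the cylinder surface
#'
#' Maps each detector to its unwrap coordinates (arc length from the
#' posterior column, axial z); the surface unwrap is an isometry, so
#' neighbour distances are preserved except across the seam at \eqn{\pm\pi
#' r}. Doses are passed through unchanged.
#'
#' @param values a [measured_set()] with `device == "arccheck"`.
#' @param geom the matching [arccheck_geometry()].
#' @return data frame with columns `id`, `u`, `v` (mm) and `dose` (Gy).
#' @export
unwrap_arccheck <- function(values, geom) {
  if (!inherits(values, "measured_set") || values$device != "arccheck" ||
      geom$device != "arccheck")
    stop_argument("unwrap_arccheck needs ArcCHECK measurements and geometry")
  det <- geom$detectors
  idx <- match(names(values$doses), det$id)
  if (anyNA(idx)) stop_validation("measured ids not present in geometry")
  data.frame(id = names(values$doses), u = det$u[idx], v = det$v[idx],
             dose = unname(values$doses), stringsAsFactors = FALSE)
}

#' Split Delta4 measurements into the two detector planes
#'
#' Partitions detectors by their plane label (exhaustive and disjoint; axis
#' detectors belong to the coronal plane by construction) and assigns
#' in-plane 2-D coordinates. Doses are passed through unchanged.
#'
#' @param values a [measured_set()] with `device == "delta4"`.
#' @param geom the matching [delta4_geometry()].
#' @return a named list of two data frames (`coronal`, `sagittal`) with
#'   columns `id`, `u`, `v`, `dose`.
#' @export
delta4_planes <- function(values, geom) {
  if (!inherits(values, "measured_set") || values$device != "delta4" ||
      geom$device != "delta4")
    stop_argument("delta4_planes needs Delta4 measurements and geometry")
  det <- geom$detectors
  idx <- match(names(values$doses), det$id)
  if (anyNA(idx)) stop_validation("measured ids not present in geometry")
  all_pts <- data.frame(id = names(values$doses),
                        u = det$u[idx], v = det$v[idx],
                        plane = det$plane[idx],
                        dose = unname(values$doses), stringsAsFactors = FALSE)
  list(coronal = all_pts[all_pts$plane == "coronal",
                         c("id", "u", "v", "dose")],
       sagittal = all_pts[all_pts$plane == "sagittal",
                          c("id", "u", "v", "dose")])
}

#' Write a measured-dose text export
#'
#' The dialect this package defines (vendor export converters are out of
#' scope): `#`-prefixed comment lines, `key: value` header lines (at least
#' `device:`), then one line per detector, `id<TAB>dose_gy`.
#'
#' @param values a [measured_set()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_measured_text <- function(values, path) {
  hdr <- c("# vaudit measured-dose export v1",
           sprintf("device: %s", values$device),
           vapply(names(values$meta),
                  function(k) sprintf("%s: %s", k, values$meta[[k]]), ""))
  body <- sprintf("%s\t%.6f", names(values$doses), values$doses)
  writeLines(c(hdr, "", body), path)
  invisible(path)
}

#' Read a measured-dose text export
#'
#' Parses the tab-separated dialect written by [write_measured_text()].
#' Malformed lines raise a parse error naming the line number; detector ids
#' absent from the geometry, and duplicated ids, raise validation errors.
#'
#' @param path path to the text export.
#' @param device `"arccheck"` or `"delta4"` (default geometry is built), or
#'   a `detector_geometry` to validate against.
#' @return a [measured_set()].
#' @export
read_measured_text <- function(path, device) {
  geom <- if (inherits(device, "detector_geometry")) device
  else switch(match.arg(device, c("arccheck", "delta4")),
              arccheck = arccheck_geometry(), delta4 = delta4_geometry())
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); doses <- numeric(0); meta <- list(); dev <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    if (grepl("^[A-Za-z_][A-Za-z0-9_ -]*:", ln)) {
      kv <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]*:", "", ln))
      if (kv == "device") dev <- val else meta[[kv]] <- val
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop_parse(sprintf("line %d: expected 'id<TAB>dose_gy', got %s", i,
                         deparse(ln)), line = i)
    dose <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(dose))
      stop_parse(sprintf("line %d: dose is not a number (%s)", i,
                         deparse(parts[2])), line = i)
    ids <- c(ids, parts[1]); doses <- c(doses, dose)
  }
  if (is.null(dev)) stop_parse("missing 'device:' header line")
  if (dev != geom$device)
    stop_validation(sprintf("file device '%s' does not match geometry '%s'",
                            dev, geom$device))
  if (anyDuplicated(ids))
    stop_validation(sprintf("duplicate detector id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  unknown <- setdiff(ids, geom$detectors$id)
  if (length(unknown) > 0)
    stop_validation(sprintf("detector id(s) not in geometry: %s",
                            paste(head(unknown, 8), collapse = ", ")))
  measured_set(dev, setNames(doses, ids), meta = meta)
}
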