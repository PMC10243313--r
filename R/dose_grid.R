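# Dose-grid data model shared by the film and array pipelines.
#
# Coordinate convention: DICOM patient coordinate system, millimetres,
# voxel-center positions, axis-aligned grids only. Axis 1 = x (right->left),
# axis 2 = y (anterior->posterior), axis 3 = z (inferior->superior).
# Dose is always absolute Gy for a single delivered fraction; no
# normalisation step exists anywhere in the package.

#' Three-dimensional absorbed-dose grid
#'
#' A physical dose distribution on a regular, axis-aligned grid in the DICOM
#' patient coordinate system. `values[i, j, k]` is the dose (Gy) at position
#' `origin + (c(i, j, k) - 1) * spacing` (voxel-center convention).
#'
#' @param values numeric 3-D array of absorbed dose (Gy); finite, `>= 0`.
#' @param origin numeric length 3; position (mm) of the first voxel center.
#' @param spacing numeric length 3; per-axis voxel pitch (mm), all `> 0`.
#' @param axes character length 3; orientation labels, fixed to the patient
#'   axes `c("x (R->L)", "y (A->P)", "z (I->S)")`.
#' @return an object of class `dose_grid3`.
#' @export
dose_grid_3d <- function(values, origin, spacing,
                         axes = c("x (R->L)", "y (A->P)", "z (I->S)")) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_argument("'values' must be a 3-D array")
  storage.mode(values) <- "double"
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop_argument("'origin' and 'spacing' must have length 3")
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop_argument("all grid spacings must be finite and > 0")
  if (!all(is.finite(values)) || any(values < 0))
    stop_argument("dose values must be finite and >= 0")
  structure(
    list(values = values, origin = origin, spacing = spacing, axes = axes),
    class = "dose_grid3"
  )
}

#' Two-dimensional dose plane
#'
#' A dose distribution on a regular in-plane grid. `values[i, j]` is the dose
#' (Gy) at in-plane position `origin + (c(i, j) - 1) * spacing`. `NA` entries
#' mark positions with no valid dose (e.g. outside the film support after
#' registration); they are excluded from all downstream statistics.
#'
#' @param values numeric matrix of dose (Gy); finite and `>= 0` or `NA`.
#' @param origin,spacing numeric length 2 (mm); spacing `> 0`.
#' @param orientation plane label: `"axial"`, `"coronal"`, `"sagittal"` or
#'   `"unwrapped-cylinder"`.
#' @param offplane out-of-plane coordinate (mm) of the plane.
#' @return an object of class `dose_grid2`.
#' @export
dose_grid_2d <- function(values, origin, spacing,
                         orientation = c("axial", "coronal", "sagittal",
                                         "unwrapped-cylinder"),
                         offplane = 0) {
  orientation <- match.arg(orientation)
  if (!is.matrix(values)) stop_argument("'values' must be a matrix")
  storage.mode(values) <- "double"
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 2L || length(spacing) != 2L)
    stop_argument("'origin' and 'spacing' must have length 2")
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop_argument("plane spacings must be finite and > 0")
  fin <- values[!is.na(values)]
  if (any(!is.finite(fin)) || any(fin < 0))
    stop_argument("dose values must be finite and >= 0 (or NA)")
  structure(
    list(values = values, origin = origin, spacing = spacing,
         orientation = orientation, offplane = as.numeric(offplane)[1]),
    class = "dose_grid2"
  )
}

#' Treatment-plan summary
#'
#' @param isocenter numeric length 3; plan isocenter (mm, patient coords).
#' @param n_fractions planned fraction count (`>= 1`), or `NA` if absent.
#' @param prescription_dose total prescription dose (Gy, `> 0`), or `NA`.
#' @param machine,tps free-form labels (may be `NA`).
#' @return an object of class `plan_info`.
#' @export
plan_info <- function(isocenter, n_fractions = NA, prescription_dose = NA,
                      machine = NA_character_, tps = NA_character_) {
  isocenter <- as.numeric(isocenter)
  if (length(isocenter) != 3L || !all(is.finite(isocenter)))
    stop_argument("'isocenter' must be a finite 3-vector (mm)")
  if (!is.na(n_fractions) && (n_fractions < 1 || n_fractions != round(n_fractions)))
    stop_argument("'n_fractions' must be a whole number >= 1")
  if (!is.na(prescription_dose) && prescription_dose <= 0)
    stop_argument("'prescription_dose' must be > 0 Gy")
  structure(
    list(isocenter = isocenter,
         n_fractions = as.numeric(n_fractions),
         prescription_dose = as.numeric(prescription_dose),
         machine = machine, tps = tps),
    class = "plan_info"
  )
}

# Voxel-center coordinates along one grid axis.
grid_axis <- function(n, origin, spacing) origin + (seq_len(n) - 1) * spacing

# In-plane coordinate vectors of a dose_grid2.
plane_axes <- function(plane) {
  list(u = grid_axis(nrow(plane$values), plane$origin[1], plane$spacing[1]),
       v = grid_axis(ncol(plane$values), plane$origin[2], plane$spacing[2]))
}

#' @export
print.dose_grid3 <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid3> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, dose range %.4g..%.4g Gy\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.dose_grid2 <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid2 %s @ %.4g mm> %d x %d, spacing %s mm, dose %.4g..%.4g Gy\n",
              x$orientation, x$offplane, d[1], d[2],
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# Which grid axis is fixed by a plane orientation, and which two remain
# in-plane (in order). Axial planes fix z and keep (x, y); coronal fix y and
# keep (x, z); sagittal fix x and keep (y, z).
plane_axis_map <- function(orientation) {
  switch(orientation,
    axial    = list(fixed = 3L, inplane = c(1L, 2L)),
    coronal  = list(fixed = 2L, inplane = c(1L, 3L)),
    sagittal = list(fixed = 1L, inplane = c(2L, 3L)),
    stop_argument(sprintf("unknown plane orientation '%s'", orientation))
  )
}

#' Extract a 2-D plane from a 3-D dose grid
#'
#' Samples the grid on the plane `axis == coordinate`, linearly interpolating
#' between the two neighbouring slices when the coordinate does not fall on a
#' voxel center. In-plane geometry (origin, spacing) is preserved.
#'
#' @param grid a [dose_grid_3d()] object.
#' @param orientation `"axial"` (fixes z), `"coronal"` (fixes y) or
#'   `"sagittal"` (fixes x).
#' @param coordinate position (mm) of the plane along the fixed axis; must
#'   lie within the grid extent.
#' @return a [dose_grid_2d()] object.
#' @export
extract_plane <- function(grid, orientation, coordinate) {
  if (!inherits(grid, "dose_grid3")) stop_argument("'grid' must be a dose_grid3")
  am <- plane_axis_map(match.arg(orientation, c("axial", "coronal", "sagittal")))
  n <- dim(grid$values)[am$fixed]
  ax <- grid_axis(n, grid$origin[am$fixed], grid$spacing[am$fixed])
  eps <- 1e-9 * max(1, abs(ax[n]))
  if (coordinate < ax[1] - eps || coordinate > ax[n] + eps)
    stop_bounds(sprintf("plane coordinate %.4g mm outside grid extent [%.4g, %.4g]",
                        coordinate, ax[1], ax[n]))
  f <- (coordinate - ax[1]) / grid$spacing[am$fixed] + 1
  f <- min(max(f, 1), n)
  k0 <- min(floor(f), max(n - 1L, 1L)); w <- f - k0; k1 <- min(k0 + 1L, n)
  slice <- function(k) {
    switch(am$fixed,
           grid$values[k, , ],   # sagittal: (y, z)
           grid$values[, k, ],   # coronal:  (x, z)
           grid$values[, , k])   # axial:    (x, y)
  }
  vals <- (1 - w) * slice(k0) + w * slice(k1)
  dose_grid_2d(vals,
               origin = grid$origin[am$inplane],
               spacing = grid$spacing[am$inplane],
               orientation = switch(am$fixed, "sagittal", "coronal", "axial"),
               offplane = coordinate)
}

#' Resample a dose plane onto a new spacing
#'
#' Bilinear interpolation onto a regular grid with the requested spacing,
#' anchored at the plane origin and covering the same extent (the far corner
#' is included exactly when the extent is an integer multiple of the new
#' spacing). Corner values are preserved.
#'
#' @param plane a [dose_grid_2d()] object.
#' @param new_spacing scalar or length-2 spacing (mm), `> 0`.
#' @return a [dose_grid_2d()] object.
#' @export
resample_plane <- function(plane, new_spacing) {
  if (!inherits(plane, "dose_grid2")) stop_argument("'plane' must be a dose_grid2")
  new_spacing <- rep_len(as.numeric(new_spacing), 2L)
  if (any(!is.finite(new_spacing)) || any(new_spacing <= 0))
    stop_argument("'new_spacing' must be > 0")
  d <- dim(plane$values)
  ext <- (d - 1L) * plane$spacing
  n_new <- pmax(1L, floor(ext / new_spacing + 1e-9) + 1L)
  u <- grid_axis(n_new[1], plane$origin[1], new_spacing[1])
  v <- grid_axis(n_new[2], plane$origin[2], new_spacing[2])
  uu <- rep(u, times = n_new[2]); vv <- rep(v, each = n_new[1])
  vals <- matrix(bilinear_sample(plane$values, plane$origin, plane$spacing, uu, vv),
                 nrow = n_new[1], ncol = n_new[2])
  dose_grid_2d(vals, origin = plane$origin, spacing = new_spacing,
               orientation = plane$orientation, offplane = plane$offplane)
}
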