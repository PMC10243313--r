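# Shared fixtures, built lazily once per test run and cached in-process.
# Everything is generated by the synth module under fixed seeds; nothing is
# read from disk fixtures.

.fx_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fx <- function(name, builder) {
  # `builder` is a lazily evaluated promise: it only runs on a cache miss
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder
  .fx_cache[[name]]
}

fx_dir <- function(...) {
  d <- file.path(tempdir(), "vaudit-fixtures", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# The standard audit target on a film-sized grid (fine spacing), with its
# DICOM-RT files and the isocenter axial plane.
fx_film_base <- function() fx("film_base", {
  scen <- scenario(seed = 11, grid_extent = c(160, 160, 80), grid_spacing = 2)
  cd <- make_c_shape_dose(scen)
  paths <- write_rt_files(cd$grid, cd$plan, fx_dir("film_base"), seed = 11)
  plane <- extract_plane(cd$grid, "axial", 0)
  film <- make_film_scan(plane, scen, fx_dir("film_base"))
  list(scen = scen, grid = cd$grid, plan = cd$plan, paths = paths,
       plane = plane, film = film)
})

# Error-free end-to-end film audit report (with diagnostics).
fx_film_report <- function() fx("film_report", {
  b <- fx_film_base()
  film_audit(b$film$scan, b$paths$dose, b$paths$plan, b$film$layout,
             unset_scan_path = b$film$unset, keep_intermediates = TRUE)
})

# Matched scenario whose 2 Gy subfilm was actually delivered 2.293 Gy.
fx_overdose_report <- function() fx("overdose_report", {
  b <- fx_film_base()
  scen <- scenario(seed = 11, grid_extent = c(160, 160, 80), grid_spacing = 2,
                   error = list(type = "subfilm_overdose", actual_gy = 2.293))
  film <- make_film_scan(b$plane, scen, fx_dir("overdose"))
  film_audit(film$scan, b$paths$dose, b$paths$plan, film$layout,
             unset_scan_path = film$unset)
})

# The audit target on an array-sized grid covering both phantom geometries.
fx_array_base <- function() fx("array_base", {
  scen <- scenario(seed = 5)
  cd <- make_c_shape_dose(scen)
  paths <- write_rt_files(cd$grid, cd$plan, fx_dir("array_base"), seed = 5)
  list(scen = scen, grid = cd$grid, plan = cd$plan, paths = paths)
})

array_measurement_path <- function(device, error = list(type = "none"),
                                   detector_noise = 0.005, tag = "m") {
  b <- fx_array_base()
  geom <- if (device == "arccheck") arccheck_geometry() else delta4_geometry()
  scen <- scenario(seed = 5, error = error, detector_noise = detector_noise)
  path <- file.path(fx_dir("measure"),
                    sprintf("%s_%s_%s.txt", tag, device, error$type))
  make_array_measurement(b$grid, geom, scen, path)
  path
}

# A seeded smooth random dose plane (sum of Gaussian bumps), for gamma
# property and oracle-equivalence tests.
smooth_random_plane <- function(seed, n = 41, spacing = 1, amplitude = 2) {
  with_seed_test(seed, {
    x <- (seq_len(n) - (n + 1) / 2) * spacing
    f <- matrix(0, n, n)
    for (k in 1:5) {
      cx <- runif(1, min(x) * 0.75, max(x) * 0.75)
      cy <- runif(1, min(x) * 0.75, max(x) * 0.75)
      s <- runif(1, 5, 15)
      a <- runif(1, 0.2, 1)
      f <- f + a * exp(-outer((x - cx)^2, (x - cy)^2, `+`) / (2 * s^2))
    }
    dose_grid_2d(amplitude * f / max(f), origin = c(x[1], x[1]),
                 spacing = c(spacing, spacing))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Paint four Gaussian fiducial marks onto a background OD map.
plant_marks <- function(n = 301, theta_deg = 0, center = NULL, bg = 0.05,
                        arm = 120, sides = c("left", "right", "top", "bottom")) {
  od <- matrix(bg, n, n)
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  th <- theta_deg * pi / 180
  eu <- c(cos(th), sin(th)); ev <- c(-sin(th), cos(th))
  pos <- list(left = center - arm * eu, right = center + arm * eu,
              top = center - arm * ev, bottom = center + arm * ev)
  for (s in sides) {
    p <- pos[[s]]
    rr <- pmax(1, floor(p[2] - 10)):pmin(n, ceiling(p[2] + 10))
    cc <- pmax(1, floor(p[1] - 10)):pmin(n, ceiling(p[1] + 10))
    d2 <- outer((rr - p[2])^2, (cc - p[1])^2, `+`)
    od[rr, cc] <- od[rr, cc] + 1.2 * exp(-d2 / (2 * 2^2))
  }
  od
}

# Uniform dose plane helper for closed-form gamma checks.
uniform_plane <- function(dose, n = 41, spacing = 1) {
  half <- (n - 1) / 2 * spacing
  dose_grid_2d(matrix(dose, n, n), origin = c(-half, -half),
               spacing = c(spacing, spacing))
}

# Interior reference points of a plane (margin keeps the search disc inside).
interior_points <- function(dose, extent = 10, spacing = 1) {
  g <- expand.grid(u = seq(-extent, extent, by = spacing),
                   v = seq(-extent, extent, by = spacing))
  data.frame(u = g$u, v = g$v, dose = dose)
}
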