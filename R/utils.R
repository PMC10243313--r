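# Internal utilities: structured errors, interpolation primitives, seeding.

vaudit_stop <- function(class, msg, ..., call. = FALSE) {
  cnd <- structure(
    class = c(class, "vaudit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cnd)
}

stop_format      <- function(msg, ...) vaudit_stop("vaudit_format_error", msg, ...)
stop_argument    <- function(msg, ...) vaudit_stop("vaudit_argument_error", msg, ...)
stop_bounds      <- function(msg, ...) vaudit_stop("vaudit_bounds_error", msg, ...)
stop_geometry    <- function(msg, ...) vaudit_stop("vaudit_unsupported_geometry_error", msg, ...)
stop_calibration <- function(msg, ...) vaudit_stop("vaudit_calibration_error", msg, ...)
stop_fiducial    <- function(msg, ...) vaudit_stop("vaudit_fiducial_error", msg, ...)
stop_parse       <- function(msg, ...) vaudit_stop("vaudit_parse_error", msg, ...)
stop_validation  <- function(msg, ...) vaudit_stop("vaudit_validation_error", msg, ...)

#' Bilinear interpolation on a regular grid
#'
#' Samples `values[i, j]` (axis 1 at `origin[1] + (i-1)*spacing[1]`, axis 2
#' analogous) at arbitrary in-plane positions. Positions outside the grid
#' support, or cells with any missing corner, yield `NA`.
#'
#' @param values numeric matrix.
#' @param origin,spacing length-2 numerics (mm), voxel-center convention.
#' @param u,v coordinates (mm) of the sample points, recycled to a common
#'   length.
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
bilinear_sample <- function(values, origin, spacing, u, v) {
  n1 <- nrow(values); n2 <- ncol(values)
  m <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), m); v <- rep_len(as.numeric(v), m)
  fi <- (u - origin[1]) / spacing[1] + 1
  fj <- (v - origin[2]) / spacing[2] + 1
  eps <- 1e-9
  ok <- fi >= 1 - eps & fi <= n1 + eps & fj >= 1 - eps & fj <= n2 + eps &
    is.finite(fi) & is.finite(fj)
  out <- rep(NA_real_, m)
  if (!any(ok)) return(out)
  fi <- pmin(pmax(fi[ok], 1), n1)
  fj <- pmin(pmax(fj[ok], 1), n2)
  i0 <- pmin(floor(fi), max(n1 - 1L, 1L)); wi <- fi - i0
  j0 <- pmin(floor(fj), max(n2 - 1L, 1L)); wj <- fj - j0
  i1 <- pmin(i0 + 1L, n1); j1 <- pmin(j0 + 1L, n2)
  v00 <- values[cbind(i0, j0)]; v10 <- values[cbind(i1, j0)]
  v01 <- values[cbind(i0, j1)]; v11 <- values[cbind(i1, j1)]
  out[ok] <- (1 - wi) * (1 - wj) * v00 + wi * (1 - wj) * v10 +
    (1 - wi) * wj * v01 + wi * wj * v11
  out
}

# Trilinear interpolation on a 3-D regular grid; NA outside the support.
trilinear_sample <- function(values, origin, spacing, x, y, z) {
  d <- dim(values)
  m <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), m); y <- rep_len(as.numeric(y), m)
  z <- rep_len(as.numeric(z), m)
  f1 <- (x - origin[1]) / spacing[1] + 1
  f2 <- (y - origin[2]) / spacing[2] + 1
  f3 <- (z - origin[3]) / spacing[3] + 1
  eps <- 1e-9
  ok <- f1 >= 1 - eps & f1 <= d[1] + eps &
    f2 >= 1 - eps & f2 <= d[2] + eps &
    f3 >= 1 - eps & f3 <= d[3] + eps
  ok[is.na(ok)] <- FALSE
  out <- rep(NA_real_, m)
  if (!any(ok)) return(out)
  f1 <- pmin(pmax(f1[ok], 1), d[1])
  f2 <- pmin(pmax(f2[ok], 1), d[2])
  f3 <- pmin(pmax(f3[ok], 1), d[3])
  i0 <- pmin(floor(f1), max(d[1] - 1L, 1L)); wi <- f1 - i0
  j0 <- pmin(floor(f2), max(d[2] - 1L, 1L)); wj <- f2 - j0
  k0 <- pmin(floor(f3), max(d[3] - 1L, 1L)); wk <- f3 - k0
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  g <- function(i, j, k) values[cbind(i, j, k)]
  out[ok] <-
    (1 - wi) * (1 - wj) * (1 - wk) * g(i0, j0, k0) +
    wi * (1 - wj) * (1 - wk) * g(i1, j0, k0) +
    (1 - wi) * wj * (1 - wk) * g(i0, j1, k0) +
    wi * wj * (1 - wk) * g(i1, j1, k0) +
    (1 - wi) * (1 - wj) * wk * g(i0, j0, k1) +
    wi * (1 - wj) * wk * g(i1, j0, k1) +
    (1 - wi) * wj * wk * g(i0, j1, k1) +
    wi * wj * wk * g(i1, j1, k1)
  out
}

# Evaluate a seeded expression without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Horner evaluation of dose = sum_j coefs[j] * x^j (j >= 1, no constant term).
polyval0 <- function(coefs, x) {
  out <- 0
  for (j in rev(seq_along(coefs))) out <- (out + coefs[j]) * x
  out
}
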