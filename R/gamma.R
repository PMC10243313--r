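# Global gamma-index analysis with credentialing presets.
#
# Role convention (documented prominently): the *measured* distribution is
# the reference — the set of points that are scored — and the *planned*
# distribution is the evaluated distribution that is searched. The low-dose
# threshold applies to the reference (measured) dose and is expressed as a
# percentage of the same denominator as the dose criterion. Gamma is always
# global: no renormalisation ("dataset scaling") of either distribution
# happens at any stage.

#' Gamma-analysis criteria
#'
#' Defines a global gamma test: dose tolerance (percent of a fixed
#' denominator), distance-to-agreement, low-dose threshold and the passing
#' tolerance used for the audit verdict.
#'
#' @param dose_tolerance_percent dose-difference criterion \eqn{\Delta D}
#'   (percent of the denominator), e.g. 3.
#' @param dta_mm distance-to-agreement criterion \eqn{\Delta d} (mm), e.g. 3
#'   or 2.
#' @param denominator either a fixed dose in Gy (e.g. `2`) or the string
#'   `"max"` for the maximum of the evaluated (planned) distribution.
#' @param threshold_percent low-dose cutoff, percent of the denominator;
#'   reference points below it are excluded from the statistics.
#' @param pass_tolerance_percent minimum passing rate (percent) for a `pass`
#'   verdict (inclusive), e.g. 90 or 95.
#' @param search_cap_mm maximum search radius around each reference point;
#'   default `3 * dta_mm`.
#' @param search_step_mm search-lattice step; default `dta_mm / 50` (the
#'   evaluated dose is interpolated bilinearly on this lattice).
#' @return an object of class `gamma_criteria`.
#' @seealso [gamma_preset()] for the credentialing presets.
#' @export
gamma_criteria <- function(dose_tolerance_percent, dta_mm, denominator,
                           threshold_percent, pass_tolerance_percent,
                           search_cap_mm = 3 * dta_mm,
                           search_step_mm = dta_mm / 50) {
  if (dose_tolerance_percent <= 0 || dta_mm <= 0 || threshold_percent <= 0 ||
      pass_tolerance_percent <= 0 || search_cap_mm <= 0 || search_step_mm <= 0)
    stop_argument("all gamma criteria must be positive")
  if (threshold_percent >= 100)
    stop_argument("'threshold_percent' must be < 100")
  if (identical(denominator, "max")) {
    den_mode <- "max_of_evaluated"; den_value <- NA_real_
  } else if (is.numeric(denominator) && length(denominator) == 1 &&
             is.finite(denominator) && denominator > 0) {
    den_mode <- "fixed_dose"; den_value <- as.numeric(denominator)
  } else {
    stop_argument("'denominator' must be a positive dose (Gy) or \"max\"")
  }
  structure(
    list(dose_tolerance_percent = dose_tolerance_percent,
         dta_mm = dta_mm,
         denominator_mode = den_mode,
         denominator_value = den_value,
         threshold_percent = threshold_percent,
         pass_tolerance_percent = pass_tolerance_percent,
         search_cap_mm = search_cap_mm,
         search_step_mm = search_step_mm),
    class = "gamma_criteria"
  )
}

#' Credentialing gamma presets
#'
#' `"jcog-film"`: 3%/3 mm with a fixed 2 Gy denominator, 30% threshold dose
#' and a 90% tolerance level (film evaluation). `"jcog-array"`: 3%/2 mm with
#' the maximum of the evaluated (planned) distribution as denominator, 10%
#' threshold dose and a 95% tolerance level (array-detector evaluation).
#'
#' @param name preset name.
#' @return a [gamma_criteria()] object.
#' @export
gamma_preset <- function(name = c("jcog-film", "jcog-array")) {
  name <- match.arg(name)
  switch(name,
    "jcog-film" = gamma_criteria(3, 3, denominator = 2,
                                 threshold_percent = 30,
                                 pass_tolerance_percent = 90),
    "jcog-array" = gamma_criteria(3, 2, denominator = "max",
                                  threshold_percent = 10,
                                  pass_tolerance_percent = 95)
  )
}

#' @export
print.gamma_criteria <- function(x, ...) {
  den <- if (x$denominator_mode == "fixed_dose")
    sprintf("%.4g Gy (fixed)", x$denominator_value) else "max of evaluated"
  cat(sprintf("<gamma_criteria> %g%%/%g mm, denominator %s, threshold %g%%, tolerance %g%%\n",
              x$dose_tolerance_percent, x$dta_mm, den, x$threshold_percent,
              x$pass_tolerance_percent))
  invisible(x)
}

#' Resolve the gamma dose denominator
#'
#' @param criteria a [gamma_criteria()] object.
#' @param evaluated the evaluated (planned) distribution: a
#'   [dose_grid_2d()], or a numeric vector / data frame of doses.
#' @return the denominator in Gy (always `> 0`).
#' @export
resolve_denominator <- function(criteria, evaluated) {
  if (criteria$denominator_mode == "fixed_dose") return(criteria$denominator_value)
  doses <- if (inherits(evaluated, "dose_grid2")) evaluated$values
  else if (is.data.frame(evaluated)) evaluated$dose
  else as.numeric(evaluated)
  doses <- doses[!is.na(doses)]
  if (length(doses) == 0) stop_argument("evaluated distribution is empty")
  mx <- max(doses)
  if (mx <= 0) stop_argument("gamma denominator must be positive (evaluated max is 0)")
  mx
}

# Coerce a reference distribution to points (u, v, dose).
as_ref_points <- function(reference) {
  if (inherits(reference, "dose_grid2")) {
    ax <- plane_axes(reference)
    data.frame(u = rep(ax$u, times = length(ax$v)),
               v = rep(ax$v, each = length(ax$u)),
               dose = as.vector(reference$values))
  } else if (is.data.frame(reference)) {
    if (!all(c("u", "v", "dose") %in% names(reference)))
      stop_argument("reference points need columns u, v, dose")
    reference[c("u", "v", "dose")]
  } else {
    stop_argument("'reference' must be a dose_grid2 or a data frame of points")
  }
}

.gamma_assemble <- function(pts, gam, criteria, denominator) {
  included <- !is.na(gam)
  n_eval <- sum(included)
  if (n_eval == 0) vaudit_stop("vaudit_empty_analysis_error",
                               "no reference point could be evaluated")
  rate <- 100 * sum(gam[included] <= 1) / n_eval
  structure(
    list(points = data.frame(u = pts$u, v = pts$v, dose = pts$dose,
                             gamma = gam, included = included),
         n_evaluated = n_eval,
         passing_rate = rate,
         criteria = criteria,
         denominator = denominator),
    class = "gamma_result"
  )
}

.gamma_common <- function(reference, evaluated, criteria, engine) {
  if (!inherits(evaluated, "dose_grid2"))
    stop_argument("'evaluated' must be a dose_grid2")
  pts <- as_ref_points(reference)
  denominator <- resolve_denominator(criteria, evaluated)
  dd_abs <- criteria$dose_tolerance_percent / 100 * denominator
  thresh <- criteria$threshold_percent / 100 * denominator
  gam <- rep(NA_real_, nrow(pts))
  sel <- !is.na(pts$dose) & pts$dose >= thresh
  if (!any(sel))
    vaudit_stop("vaudit_empty_analysis_error",
                "no reference point above the threshold dose")
  step <- if (identical(engine, gamma_brute_cpp))
    min(criteria$search_step_mm, criteria$dta_mm / 50) else criteria$search_step_mm
  gam[sel] <- engine(pts$u[sel], pts$v[sel], pts$dose[sel],
                     evaluated$values, evaluated$origin[1], evaluated$origin[2],
                     evaluated$spacing[1], evaluated$spacing[2],
                     criteria$dta_mm, dd_abs, criteria$search_cap_mm, step)
  .gamma_assemble(pts, gam, criteria, denominator)
}

#' Global gamma map between measured and planned distributions
#'
#' For each reference (measured) point at or above the threshold dose,
#' computes \deqn{\gamma(r) = \min_e \sqrt{\|e - r\|^2/\Delta d^2 +
#' (D_{eval}(e) - D_{ref}(r))^2/\Delta D^2}} over candidate positions `e`
#' within the search cap, with the evaluated (planned) dose interpolated
#' bilinearly on a dense search lattice. Points below the threshold are
#' excluded from the statistics; the passing rate is the percentage of
#' evaluated points with \eqn{\gamma \le 1} (inclusive).
#'
#' @param reference measured distribution: a [dose_grid_2d()] or a data
#'   frame with columns `u`, `v` (mm) and `dose` (Gy), sharing the
#'   evaluated plane's coordinate frame.
#' @param evaluated planned distribution as a [dose_grid_2d()].
#' @param criteria a [gamma_criteria()] object.
#' @return an object of class `gamma_result`: per-point gamma values (`NA`
#'   where excluded), `n_evaluated`, `passing_rate` (percent), the criteria
#'   and the resolved denominator (Gy).
#' @export
gamma_map <- function(reference, evaluated, criteria) {
  .gamma_common(reference, evaluated, criteria, gamma_engine_cpp)
}

#' Brute-force gamma oracle
#'
#' Identical contract to [gamma_map()] but computed by exhaustive evaluation
#' of every lattice candidate (step at most \eqn{\Delta d / 50}) with no
#' ordering, pruning or early exit. Intended for verification on small
#' instances; complexity is quadratic in the search radius per point.
#'
#' @inheritParams gamma_map
#' @return a `gamma_result` object.
#' @export
gamma_bruteforce <- function(reference, evaluated, criteria) {
  pts <- as_ref_points(reference)
  if (nrow(pts) > 1e4)
    stop_argument("gamma_bruteforce is limited to <= 10^4 reference points")
  .gamma_common(reference, evaluated, criteria, gamma_brute_cpp)
}

#' Pass/fail verdict from a gamma passing rate
#'
#' `pass` iff the passing rate is greater than or equal to the tolerance
#' level (inclusive comparison at the boundary).
#'
#' @param result a `gamma_result` object.
#' @param criteria a [gamma_criteria()] object; defaults to the criteria
#'   stored in `result`.
#' @return `"pass"` or `"fail"`.
#' @export
passing_rate_verdict <- function(result, criteria = result$criteria) {
  if (result$n_evaluated <= 0) stop_argument("no evaluated points")
  if (result$passing_rate >= criteria$pass_tolerance_percent) "pass" else "fail"
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %d evaluated points, passing rate %.1f%% (denominator %.4g Gy)\n",
              x$n_evaluated, x$passing_rate, x$denominator))
  invisible(x)
}

#' Serialize a gamma result to JSON
#'
#' Includes the criteria, denominator, statistics and the full per-point
#' gamma map.
#'
#' @param result a `gamma_result` object.
#' @return a JSON string.
#' @export
gamma_result_json <- function(result) {
  jsonlite::toJSON(list(
    criteria = unclass(result$criteria),
    denominator_gy = result$denominator,
    n_evaluated = result$n_evaluated,
    passing_rate_percent = result$passing_rate,
    points = result$points
  ), auto_unbox = TRUE, digits = NA, na = "null")
}
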