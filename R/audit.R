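# Audit orchestration: the film and array credentialing workflows, the
# plausibility checks, and machine-readable reports.

#' Audit configuration
#'
#' @param device `"film"`, `"arccheck"` or `"delta4"`.
#' @param criteria a [gamma_criteria()]; defaults to the `"jcog-film"`
#'   preset for film and `"jcog-array"` for arrays.
#' @param orientation film plane orientation, `"axial"` or `"coronal"`
#'   (declared, never auto-detected).
#' @param expected_dpi nominal film-scan resolution.
#' @param analysis_spacing_mm film dose is resampled to this pitch before
#'   gamma scoring (default 1 mm).
#' @param unwrap_spacing_mm lattice pitch of the unwrapped-cylinder planned
#'   plane for ArcCHECK (default 1 mm).
#' @param edge_band_fraction fiducial search band width (fraction of the
#'   film image size).
#' @param subfilm_margin_fraction border fraction trimmed from each subfilm
#'   before averaging its OD.
#' @param scale_warn_tolerance warn (calibration-suspect) when the median
#'   measured/planned dose ratio in the high-dose region deviates from 1 by
#'   more than this fraction (default 0.05).
#' @param arccheck,delta4 geometry parameter overrides (named lists passed
#'   to [arccheck_geometry()] / [delta4_geometry()]).
#' @return an object of class `audit_config`.
#' @export
audit_config <- function(device = c("film", "arccheck", "delta4"),
                         criteria = NULL,
                         orientation = c("axial", "coronal"),
                         expected_dpi = 150,
                         analysis_spacing_mm = 1,
                         unwrap_spacing_mm = 1,
                         edge_band_fraction = 0.12,
                         subfilm_margin_fraction = 0.25,
                         scale_warn_tolerance = 0.05,
                         arccheck = list(),
                         delta4 = list()) {
  device <- match.arg(device)
  orientation <- match.arg(orientation)
  if (is.null(criteria))
    criteria <- gamma_preset(if (device == "film") "jcog-film" else "jcog-array")
  structure(list(device = device, criteria = criteria,
                 orientation = orientation, expected_dpi = expected_dpi,
                 analysis_spacing_mm = analysis_spacing_mm,
                 unwrap_spacing_mm = unwrap_spacing_mm,
                 edge_band_fraction = edge_band_fraction,
                 subfilm_margin_fraction = subfilm_margin_fraction,
                 scale_warn_tolerance = scale_warn_tolerance,
                 arccheck = arccheck, delta4 = delta4),
            class = "audit_config")
}

# Run one pipeline stage; failures abort the audit with a condition naming
# the stage and the original message.
audit_stage <- function(stage_name, expr) {
  tryCatch(expr, error = function(e) {
    vaudit_stop("vaudit_stage_error",
                sprintf("audit stage '%s' failed: %s", stage_name,
                        conditionMessage(e)),
                stage = stage_name)
  })
}

.input_identity <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  lapply(paths, function(p)
    list(path = as.character(p), md5 = unname(tools::md5sum(as.character(p)))))
}

.provenance <- function(seed = NULL) {
  list(software = sprintf("vaudit %s", as.character(packageVersion("vaudit"))),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       seed = if (is.null(seed)) NA else as.integer(seed))
}

.make_report <- function(device, inputs, criteria, denominator, result,
                         warnings, seed = NULL) {
  verdict <- passing_rate_verdict(result, criteria)
  structure(list(device = device,
                 inputs = inputs,
                 criteria = unclass(criteria),
                 denominator_gy = denominator,
                 n_evaluated = result$n_evaluated,
                 passing_rate = result$passing_rate,
                 verdict = verdict,
                 warnings = as.character(warnings),
                 gamma = result$points[result$points$included,
                                       c("u", "v", "dose", "gamma")],
                 provenance = .provenance(seed)),
            class = "audit_report")
}

#' Plan plausibility checks
#'
#' Warns when the plan deviates from the audit prescription (20 Gy in 10
#' fractions) or does not carry it. Dose-volume coverage and organ-at-risk
#' checks require structure sets and are outside this package's scope; the
#' warning text says so.
#'
#' @param plan a [plan_info()].
#' @return character vector of warnings (empty when compliant).
#' @export
check_plan_constraints <- function(plan) {
  w <- character(0)
  if (is.na(plan$n_fractions))
    w <- c(w, "fraction count not verifiable (absent from plan)")
  else if (plan$n_fractions != 10)
    w <- c(w, sprintf("plan has %g fractions, audit protocol expects 10",
                      plan$n_fractions))
  if (is.na(plan$prescription_dose))
    w <- c(w, "prescription dose not verifiable (absent from plan)")
  else if (abs(plan$prescription_dose - 20) > 1e-6)
    w <- c(w, sprintf("prescription %g Gy, audit protocol expects 20 Gy",
                      plan$prescription_dose))
  if (length(w) > 0)
    w <- c(w, "target coverage / organ-at-risk constraints not checked (needs structure set; out of scope)")
  w
}

# Median measured/planned ratio over the high-dose region; a deviation
# beyond tolerance suggests a calibration (subfilm) or delivery-scale error.
.dose_scale_check <- function(meas_pts, evaluated, denominator, tol) {
  ev <- bilinear_sample(evaluated$values, evaluated$origin, evaluated$spacing,
                        meas_pts$u, meas_pts$v)
  sel <- !is.na(ev) & !is.na(meas_pts$dose) & ev >= 0.5 * denominator
  if (sum(sel) < 10) return(character(0))
  ratio <- median(meas_pts$dose[sel] / ev[sel])
  if (abs(ratio - 1) > tol)
    sprintf("calibration-suspect: median measured/planned dose ratio %.3f in the high-dose region (tolerance %.0f%%)",
            ratio, 100 * tol)
  else character(0)
}

#' Film credentialing audit
#'
#' Runs the full film workflow: scan reading, red-channel extraction,
#' optical density, unset-film non-uniformity correction, subfilm readout,
#' constrained polynomial calibration, dose conversion, fiducial
#' registration to the isocenter, extraction of the matching planned plane,
#' and global gamma analysis under the film preset (3%/3 mm, 2 Gy
#' denominator, 30% threshold, 90% tolerance) unless overridden.
#'
#' If `unset_scan_path` is given, the unset-film OD map (median-filtered
#' 5x5, only for this correction map) is subtracted pixelwise; otherwise the
#' scalar mean OD of the 0 Gy subfilm serves as the baseline.
#'
#' @param scan_path composite film scan (16-bit RGB TIFF).
#' @param rt_dose_path,rt_plan_path planned dose recalculated on the QA
#'   phantom (DICOM-RT).
#' @param layout_path scan layout JSON (see [scan_layout()]).
#' @param unset_scan_path optional unset-film scan.
#' @param config an [audit_config()].
#' @param seed recorded in the report provenance (the audit itself is
#'   deterministic).
#' @param keep_intermediates attach the calibration curve, fiducial set and
#'   aligned film dose to the report (`$diagnostics`) for inspection.
#' @return an object of class `audit_report`.
#' @export
film_audit <- function(scan_path, rt_dose_path, rt_plan_path, layout_path,
                       unset_scan_path = NULL,
                       config = audit_config("film"), seed = NULL,
                       keep_intermediates = FALSE) {
  plan3 <- audit_stage("dose_model", read_rt_dose(rt_dose_path))
  pinfo <- audit_stage("dose_model", read_rt_plan(rt_plan_path))
  warnings <- check_plan_constraints(pinfo)

  layout <- audit_stage("film", read_scan_layout(layout_path))
  scan <- audit_stage("film", read_scan(scan_path, config$expected_dpi))
  warnings <- c(warnings, scan$warnings)

  net <- audit_stage("film", {
    od <- optical_density(red_channel(scan))
    baseline <- if (!is.null(unset_scan_path)) {
      unset_scan <- read_scan(unset_scan_path, config$expected_dpi)
      unset_od <- optical_density(red_channel(unset_scan))
      sc <- max(unset_od, 1e-6)
      EBImage::medianFilter(unset_od / sc, 2) * sc
    } else {
      zero <- Filter(function(s) s$dose_gy == 0, layout$subfilms)[[1]]
      mean_region_od(od, zero, config$subfilm_margin_fraction)
    }
    # Shallow sub-base readings are pixel noise and clip silently; a
    # systematically negative irradiated-film region is worth flagging.
    raw_film <- rect_crop(od, layout$film) -
      (if (length(baseline) > 1) rect_crop(baseline, layout$film) else baseline)
    deep <- mean(raw_film < -0.01)
    if (deep > 0.01)
      warnings <- c(warnings, sprintf(
        "%.1f%% of irradiated-film pixels read more than 0.01 OD below the unset baseline",
        100 * deep))
    correct_nonuniformity(od, baseline)
  })

  curve <- audit_stage("film", {
    pts <- do.call(rbind, lapply(layout$subfilms, function(s) data.frame(
      net_od = mean_region_od(net, s, config$subfilm_margin_fraction),
      dose = s$dose_gy)))
    fit_calibration(pts)
  })

  film_od <- audit_stage("film", rect_crop(net, layout$film))
  film_dose <- audit_stage("film", {
    fd <- suppressWarnings(
      apply_calibration(curve, film_od, scan$dpi, config$orientation))
    # noise straddling the top calibration point extrapolates marginally and
    # is expected; a sizable region far above the fitted range is not
    far <- mean(film_od > curve$od_range[2] + 0.02)
    if (far > 0.005)
      warnings <- c(warnings, sprintf(
        "%.1f%% of film pixels far above the fitted OD range (polynomial extrapolation)",
        100 * far))
    fd
  })
  fid <- audit_stage("film", detect_fiducials(film_od, config$edge_band_fraction))
  aligned <- audit_stage("film", align_to_isocenter(film_dose, fid))

  result <- audit_stage("gamma", {
    plan_plane <- {
      am <- plane_axis_map(config$orientation)
      pl <- extract_plane(plan3, config$orientation,
                          pinfo$isocenter[am$fixed])
      pl$origin <- pl$origin - pinfo$isocenter[am$inplane]
      pl
    }
    measured <- resample_plane(aligned, config$analysis_spacing_mm)
    meas_pts <- as_ref_points(measured)
    den <- resolve_denominator(config$criteria, plan_plane)
    warnings <- c(warnings, .dose_scale_check(meas_pts, plan_plane, den,
                                              config$scale_warn_tolerance))
    gamma_map(meas_pts, plan_plane, config$criteria)
  })

  inputs <- .input_identity(list(scan = scan_path, unset = unset_scan_path,
                                 rt_dose = rt_dose_path,
                                 rt_plan = rt_plan_path, layout = layout_path))
  report <- .make_report("film", inputs, config$criteria, result$denominator,
                         result, warnings, seed)
  if (keep_intermediates)
    report$diagnostics <- list(curve = curve, fiducials = fid,
                               aligned = aligned)
  report
}

# Planned dose on the unwrapped ArcCHECK cylinder surface around the
# isocenter axis: a (u = arc length, v = z) lattice mapped back to the
# cylinder and sampled trilinearly. Lattice cells outside the dose grid are
# NA and excluded by the gamma engine.
arccheck_unwrapped_plane <- function(plan3, geom, isocenter, spacing_mm = 1) {
  r <- geom$radius_mm
  u <- seq(-pi * r, pi * r, by = spacing_mm)
  v <- seq(-geom$length_mm / 2, geom$length_mm / 2, by = spacing_mm)
  uu <- rep(u, times = length(v)); vv <- rep(v, each = length(u))
  x <- isocenter[1] + r * sin(uu / r)
  y <- isocenter[2] + r * cos(uu / r)
  z <- isocenter[3] + vv
  vals <- matrix(trilinear_sample(plan3$values, plan3$origin, plan3$spacing,
                                  x, y, z),
                 nrow = length(u), ncol = length(v))
  dose_grid_2d(vals, origin = c(u[1], v[1]), spacing = c(spacing_mm, spacing_mm),
               orientation = "unwrapped-cylinder", offplane = r)
}

# Pool per-plane gamma results into one result (single passing rate over all
# evaluated detectors, as audits report one rate per dataset).
.pool_gamma <- function(results, criteria) {
  pts <- do.call(rbind, lapply(names(results), function(nm) {
    p <- results[[nm]]$points
    p$plane <- nm
    p
  }))
  gam <- pts$gamma
  included <- pts$included
  n_eval <- sum(included)
  rate <- 100 * sum(gam[included] <= 1) / n_eval
  structure(list(points = pts, n_evaluated = n_eval, passing_rate = rate,
                 criteria = criteria,
                 denominator = vapply(results, function(r) r$denominator, 0)),
            class = "gamma_result")
}

#' Array-detector credentialing audit
#'
#' Runs the array workflow: measured-text parsing, device geometry, planned
#' dose sampling (unwrapped cylinder surface for ArcCHECK; coronal and
#' sagittal planes at the isocenter for Delta4, gamma computed per plane and
#' the passing rate pooled over all evaluated detectors), and global gamma
#' under the array preset (3%/2 mm, denominator = maximum of the evaluated
#' planned plane, 10% threshold, 95% tolerance) unless overridden.
#'
#' @param measured_path measured-dose text export.
#' @param rt_dose_path,rt_plan_path planned dose (DICOM-RT).
#' @param device `"arccheck"` or `"delta4"`.
#' @param config an [audit_config()]; defaults to the device's preset.
#' @param seed recorded in report provenance.
#' @return an object of class `audit_report`.
#' @export
array_audit <- function(measured_path, rt_dose_path, rt_plan_path,
                        device = c("arccheck", "delta4"),
                        config = NULL, seed = NULL) {
  device <- match.arg(device)
  if (is.null(config)) config <- audit_config(device)
  plan3 <- audit_stage("dose_model", read_rt_dose(rt_dose_path))
  pinfo <- audit_stage("dose_model", read_rt_plan(rt_plan_path))
  warnings <- check_plan_constraints(pinfo)

  geom <- audit_stage("arrays", {
    if (device == "arccheck") do.call(arccheck_geometry, config$arccheck)
    else do.call(delta4_geometry, config$delta4)
  })
  ms <- audit_stage("arrays", read_measured_text(measured_path, geom))
  if (length(ms$doses) < nrow(geom$detectors))
    warnings <- c(warnings, sprintf("measured set covers %d of %d detectors",
                                    length(ms$doses), nrow(geom$detectors)))

  result <- audit_stage("gamma", {
    if (device == "arccheck") {
      pts <- unwrap_arccheck(ms, geom)
      ev <- arccheck_unwrapped_plane(plan3, geom, pinfo$isocenter,
                                     config$unwrap_spacing_mm)
      den <- resolve_denominator(config$criteria, ev)
      warnings <- c(warnings, .dose_scale_check(pts, ev, den,
                                                config$scale_warn_tolerance))
      res <- gamma_map(pts, ev, config$criteria)
      .pool_gamma(list(cylinder = res), config$criteria)
    } else {
      planes <- delta4_planes(ms, geom)
      per <- lapply(names(planes), function(orient) {
        am <- plane_axis_map(orient)
        ev <- extract_plane(plan3, orient, pinfo$isocenter[am$fixed])
        ev$origin <- ev$origin - pinfo$isocenter[am$inplane]
        den <- resolve_denominator(config$criteria, ev)
        warnings <<- c(warnings, .dose_scale_check(planes[[orient]], ev, den,
                                                   config$scale_warn_tolerance))
        gamma_map(planes[[orient]], ev, config$criteria)
      })
      names(per) <- names(planes)
      .pool_gamma(per, config$criteria)
    }
  })

  inputs <- .input_identity(list(measured = measured_path,
                                 rt_dose = rt_dose_path,
                                 rt_plan = rt_plan_path))
  rep_ <- .make_report(device, inputs, config$criteria,
                       result$denominator, result, unique(warnings), seed)
  rep_
}

#' @export
print.audit_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

#' Render an audit report
#'
#' JSON serialization is lossless (see [parse_report()]); the text form
#' lists the criteria, denominator, passing rate (one decimal), verdict and
#' warnings.
#'
#' @param report an `audit_report`.
#' @param format `"json"` or `"text"`.
#' @return a JSON string, or a character vector of text lines.
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- unclass(report)
    x$diagnostics <- NULL  # in-memory inspection objects, not part of the record
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                            na = "null", null = "null", dataframe = "columns"))
  }
  cr <- report$criteria
  den <- paste(sprintf("%.4g", report$denominator_gy), collapse = " / ")
  c(sprintf("vaudit report — device: %s", report$device),
    sprintf("criteria: %g%%/%g mm, threshold %g%%, tolerance %g%%",
            cr$dose_tolerance_percent, cr$dta_mm, cr$threshold_percent,
            cr$pass_tolerance_percent),
    sprintf("denominator: %s Gy", den),
    sprintf("evaluated points: %d", report$n_evaluated),
    sprintf("passing rate: %.1f%%", report$passing_rate),
    sprintf("verdict: %s", toupper(report$verdict)),
    if (length(report$warnings))
      paste0("warning: ", report$warnings)
    else "warnings: none")
}

#' Parse an audit report from its JSON rendering
#'
#' @param json a JSON string produced by [render_report()].
#' @return an `audit_report` object equal to the original (timestamps
#'   included; they round-trip verbatim).
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  x$gamma <- as.data.frame(x$gamma)
  x$warnings <- as.character(x$warnings)
  x$denominator_gy <- as.numeric(unlist(x$denominator_gy))
  structure(x, class = "audit_report")
}
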