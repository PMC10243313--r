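# Global gamma engine: closed forms, invariants and the brute-force oracle.

test_that("identical distributions give gamma zero everywhere and 100% passing", {
  ev <- smooth_random_plane(101)
  res <- gamma_map(ev, ev, gamma_preset("jcog-film"))
  expect_true(all(res$points$gamma[res$points$included] == 0))
  expect_equal(res$passing_rate, 100)
  expect_identical(passing_rate_verdict(res), "pass")
})

test_that("uniform dose offsets follow the closed form |dD| / (3% of 2 Gy) exactly", {
  crit <- gamma_preset("jcog-film")
  ref <- interior_points(2.0)
  for (offset in c(0, 0.02, 0.04, 0.05, 0.06, 0.08, 0.10, 0.12)) {
    ev <- uniform_plane(2.0 + offset)
    res <- gamma_map(ref, ev, crit)
    expected <- offset / 0.06
    expect_lt(max(abs(res$points$gamma - expected)), 1e-9)
    if (abs(offset - 0.06) > 1e-6)   # knife-edge case checked below
      expect_equal(res$passing_rate, if (offset < 0.06) 100 else 0)
  }
  # inclusive gamma <= 1 boundary, with exactly representable arithmetic:
  # dose tolerance 25% of 2 Gy = 0.5 Gy, offset exactly 0.5 -> gamma = 1
  crit_b <- gamma_criteria(25, 3, 2, 30, 90)
  resb <- gamma_map(ref, uniform_plane(2.5), crit_b)
  expect_identical(unique(resb$points$gamma), 1)
  expect_equal(resb$passing_rate, 100)
  # the two canonical cases: 2.05 Gy -> 0.833..., 2.08 Gy -> 1.333...
  r05 <- gamma_map(ref, uniform_plane(2.05), crit)
  r08 <- gamma_map(ref, uniform_plane(2.08), crit)
  expect_equal(unique(r05$points$gamma), 0.05 / 0.06, tolerance = 1e-12)
  expect_equal(unique(r08$points$gamma), 0.08 / 0.06, tolerance = 1e-12)
  expect_equal(r05$passing_rate, 100)
  expect_equal(r08$passing_rate, 0)
})

test_that("the dose denominator resolves per mode and must be positive", {
  expect_equal(resolve_denominator(gamma_preset("jcog-film"), uniform_plane(1)), 2)
  crit_max <- gamma_preset("jcog-array")
  pl <- uniform_plane(1.0)
  pl$values[21, 21] <- 2.12
  expect_equal(resolve_denominator(crit_max, pl), 2.12)
  expect_error(resolve_denominator(crit_max, uniform_plane(0)),
               class = "vaudit_argument_error")
  expect_error(gamma_criteria(3, 3, denominator = -1, threshold_percent = 30,
                              pass_tolerance_percent = 90),
               class = "vaudit_argument_error")
})

test_that("threshold excludes low-dose reference points; raising it never adds points", {
  ev <- smooth_random_plane(7)
  ref <- as.data.frame(vaudit:::as_ref_points(smooth_random_plane(8)))
  n_prev <- Inf
  for (th in c(10, 30, 50, 70)) {
    crit <- gamma_criteria(3, 2, denominator = 2, threshold_percent = th,
                           pass_tolerance_percent = 95)
    res <- gamma_map(ref, ev, crit)
    expect_true(all(is.na(res$points$gamma[res$points$dose < th / 100 * 2])))
    expect_lte(res$n_evaluated, n_prev)
    n_prev <- res$n_evaluated
  }
  # nothing above threshold -> empty-analysis error
  expect_error(gamma_map(interior_points(0.1), uniform_plane(2),
                         gamma_preset("jcog-film")),
               class = "vaudit_empty_analysis_error")
})

test_that("loosening either criterion never decreases any point's pass status", {
  for (seed in c(21, 22, 23)) {
    ref <- smooth_random_plane(seed)
    ev <- smooth_random_plane(seed + 100)
    base <- gamma_criteria(3, 2, 2, 10, 95)
    loose_dose <- gamma_criteria(4.5, 2, 2, 10, 95)
    loose_dta <- gamma_criteria(3, 3, 2, 10, 95)
    g0 <- gamma_map(ref, ev, base)$points
    for (loose in list(loose_dose, loose_dta)) {
      g1 <- gamma_map(ref, ev, loose)$points
      was_pass <- !is.na(g0$gamma) & g0$gamma <= 1
      expect_true(all(g1$gamma[was_pass] <= 1, na.rm = TRUE))
    }
  }
})

test_that("pure translations score as shift/DTA and flip pass/fail across the DTA", {
  # cone field: constant |gradient| almost everywhere above threshold
  n <- 81
  x <- (seq_len(n) - (n + 1) / 2)
  cone <- function(cx) {
    r <- sqrt(outer((x - cx)^2, x^2, `+`))
    dose_grid_2d(2 * pmax(1 - r / 50, 0), origin = c(x[1], x[1]),
                 spacing = c(1, 1))
  }
  crit <- gamma_preset("jcog-array")
  ev <- cone(0)
  # interior points only: at the grid boundary the exact match can fall
  # outside the evaluated support, which is an edge effect, not the property
  interior <- function(pts, margin) pts[abs(pts$u) <= max(x) - margin &
                                          abs(pts$v) <= max(x) - margin, ]
  for (s in c(0.5, 1, 2)) {       # shifts within the 2 mm DTA
    shifted <- cone(s)            # dose values unchanged, position shifted
    res <- gamma_map(interior(vaudit:::as_ref_points(shifted), s + 1), ev, crit)
    expect_lte(max(res$points$gamma, na.rm = TRUE), s / 2 + 0.05)
  }
  res5 <- gamma_map(interior(vaudit:::as_ref_points(cone(5)), 6), ev, crit)
  expect_identical(passing_rate_verdict(res5), "fail")
  res1 <- gamma_map(interior(vaudit:::as_ref_points(cone(1)), 2), ev, crit)
  expect_identical(passing_rate_verdict(res1), "pass")
})

test_that("the exhaustive oracle agrees with the engine on random smooth fields", {
  for (seed in 1:6) {
    ref <- smooth_random_plane(seed)
    ev <- smooth_random_plane(seed + 50)
    for (preset in c("jcog-film", "jcog-array")) {
      crit <- gamma_preset(preset)
      a <- gamma_map(ref, ev, crit)
      b <- gamma_bruteforce(ref, ev, crit)
      dif <- abs(a$points$gamma - b$points$gamma)
      expect_gte(mean(dif <= 1e-3, na.rm = TRUE), 0.99)
    }
  }
  # the oracle reproduces the uniform-offset closed form exactly too
  rb <- gamma_bruteforce(interior_points(2.0), uniform_plane(2.08),
                         gamma_preset("jcog-film"))
  expect_lt(max(abs(rb$points$gamma - 0.08 / 0.06)), 1e-9)
  expect_error(
    gamma_bruteforce(interior_points(2, extent = 60, spacing = 1),
                     uniform_plane(2), gamma_preset("jcog-film")),
    class = "vaudit_argument_error")  # instance-size guard
})

test_that("gamma values are nonnegative and vanish only on exact matches", {
  for (seed in c(31, 32)) {
    ref <- smooth_random_plane(seed)
    ev <- smooth_random_plane(seed + 7)
    g <- gamma_map(ref, ev, gamma_preset("jcog-array"))$points$gamma
    expect_true(all(g >= 0, na.rm = TRUE))
  }
  # exact match at a lattice point -> exactly zero
  ev <- uniform_plane(1.5)
  g0 <- gamma_map(data.frame(u = 0, v = 0, dose = 1.5), ev,
                  gamma_preset("jcog-film"))
  expect_identical(g0$points$gamma, 0)
})

test_that("verdicts compare the rate to the tolerance inclusively", {
  fake <- function(rate) structure(
    list(n_evaluated = 1000L, passing_rate = rate,
         criteria = gamma_preset("jcog-film")), class = "gamma_result")
  expect_identical(passing_rate_verdict(fake(100)), "pass")
  expect_identical(passing_rate_verdict(fake(89.9)), "fail")
  expect_identical(passing_rate_verdict(fake(90.0)), "pass")
  arr <- structure(list(n_evaluated = 10L, passing_rate = 94.9,
                        criteria = gamma_preset("jcog-array")),
                   class = "gamma_result")
  expect_identical(passing_rate_verdict(arr), "fail")
})

test_that("gamma results serialize to JSON with the full map", {
  res <- gamma_map(interior_points(2, extent = 2), uniform_plane(2.05),
                   gamma_preset("jcog-film"))
  j <- jsonlite::fromJSON(gamma_result_json(res))
  expect_equal(j$passing_rate_percent, 100)
  expect_equal(j$denominator_gy, 2)
  expect_equal(nrow(j$points), nrow(res$points))
  expect_equal(j$points$gamma, res$points$gamma, tolerance = 1e-12)
})
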