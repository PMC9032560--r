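# Capnogram construction, phase segmentation and feature extraction.

test_that("volume integration matches the trapezoid rule", {
  expect_equal(integrate_volume(c(0, 0, 0), 200), c(0, 0, 0))
  # constant 1 L/s at 200 Hz: 5 mL per step
  expect_equal(integrate_volume(c(1, 1, 1), 200), c(0, 5, 10))
  # ramp 0 -> 1 L/s over 1 s: triangle area = 0.5 L
  ramp <- seq(0, 1, length.out = 201)
  v <- integrate_volume(ramp, 200)
  expect_equal(v[201], 500, tolerance = 1e-6)
  # independent oracle: pracma's cumulative trapezoid
  skip_if_not_installed("pracma")
  f <- sin(seq(0, pi, length.out = 100))^2
  expect_equal(integrate_volume(f, 50),
               as.numeric(pracma::cumtrapz(seq(0, 99) / 50, f)) * 1000)
  expect_error(integrate_volume(numeric(0), 200),
               class = "capnopred_invalid_argument")
  expect_error(integrate_volume(c(1, 1), 0),
               class = "capnopred_invalid_argument")
})

test_that("capno_trace enforces its invariants", {
  expect_error(capno_trace(c(1, 2), c(1, 1, 1)),
               class = "capnopred_invalid_argument")
  expect_error(capno_trace(c(1, -2, 3), c(1, 1, 1)),
               class = "capnopred_invalid_argument")
  expect_error(capno_trace(c(1, 2, 3), c(1, -2, 1)),
               class = "capnopred_invalid_argument") # decreasing volume
  tr <- capno_trace(c(0, 1, 2), c(1, 1, 1))
  expect_equal(tr$volume[1], 0)
  expect_true(all(diff(tr$volume) >= 0))
})

test_that("noiseless phase lines are recovered to high precision", {
  tr <- make_piecewise_trace(s2 = 75, s3 = 5)
  fit <- fit_phase_lines(tr)
  expect_equal(fit$phase2$slope, 75, tolerance = 0.01)
  expect_equal(fit$phase3$slope, 5, tolerance = 0.01)
})

test_that("flat traces fail extraction with an informative condition", {
  n <- 4200
  tr <- capno_trace(rep(0, n), rep(0.1, n))
  err <- tryCatch(fit_phase_lines(tr), condition = identity)
  expect_s3_class(err, "capnopred_extraction_failure")
  expect_match(conditionMessage(err), "phase II|phase III")
})

test_that("feature extraction reproduces the closed-form geometry", {
  tr <- make_piecewise_trace(s2 = 75, s3 = 5, c12 = 2.5, v12 = 276,
                             v23 = 757, v3 = 2061)
  f <- compute_features(tr)
  expect_equal(f$Angle23, 180 - atan(75) * 180 / pi + atan(5) * 180 / pi,
               tolerance = 0.01)
  expect_equal(f$Angle23, 169.5, tolerance = 0.1)
  expect_equal(f$C12, 2.5, tolerance = 0.01)
  expect_equal(f$V12, 276, tolerance = 1)
  expect_equal(f$V23, 757, tolerance = 1)
  expect_equal(f$V2, f$V23 - f$V12)
  expect_equal(f$V3, 2061, tolerance = 2)
  expect_equal(f$S3_over_S2, f$S3 / f$S2)
})

test_that("V12 + V2 = V23 holds for every successful extraction", {
  set.seed(14)
  for (i in 1:5) {
    tr <- make_piecewise_trace(s2 = runif(1, 40, 110), s3 = runif(1, 2, 10),
                               noise_sd = 0.3)
    f <- compute_features(tr)
    expect_equal(f$V12 + f$V2, f$V23, tolerance = 1e-9)
  }
})

test_that("Angle23 decreases as the phase II slope steepens", {
  angles <- vapply(c(40, 60, 80, 100, 120), function(s2) {
    compute_features(make_piecewise_trace(s2 = s2, s3 = 5))$Angle23
  }, numeric(1))
  expect_true(all(diff(angles) < 0))
})

test_that("generator round trip: noiseless cohort features match drawn values", {
  co <- cached_cohort(25, seed = 11, noise_sd = 0)
  co_t <- generate_cohort(cohort_config(25, seed = 11, noise_sd = 0),
                          keep_traces = TRUE)
  for (s in co_t$subjects) {
    f <- compute_features(s$trace)
    for (nm in capno_feature_names) {
      expect_equal(f[[nm]], s$features[[nm]], tolerance = 0.01,
                   label = sprintf("subject %d %s (extracted)", s$id, nm),
                   expected.label = "drawn value")
    }
  }
})

test_that("noisy generator traces recover slopes within 10%", {
  set.seed(8)
  tr <- make_piecewise_trace(s2 = 74.63, s3 = 5.44, noise_sd = 0.3)
  f <- compute_features(tr)
  expect_equal(f$S2, 74.63, tolerance = 0.10 * 74.63)
  expect_equal(f$S3, 5.44, tolerance = 0.10 * 5.44)
})

test_that("breath CSV round trip preserves the trace", {
  tr <- make_piecewise_trace(s2 = 60, s3 = 4, n = 4000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_breath_csv(tr, path)
  tr2 <- read_breath_csv(path)
  expect_equal(tr2$co2, tr$co2)
  expect_equal(tr2$fs, tr$fs, tolerance = 1e-6)
  expect_error(read_breath_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1:3), p)
    p
  }), class = "capnopred_invalid_argument")
})
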