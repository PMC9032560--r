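# Synthetic cohort generator: marginal calibration, obstruction
# structure, determinism.

test_that("demographic marginals match the configured cohort", {
  cfg <- cohort_config(10000, seed = 2)
  set.seed(99)
  d <- sample_demographics(cfg)
  expect_equal(mean(d$height), 166, tolerance = 0.5)
  expect_equal(mean(d$weight), 69, tolerance = 0.5)
  expect_equal(mean(d$male), 0.531, tolerance = 0.02)
  expect_true(all(d$age >= 17 & d$age <= 70))
  expect_equal(d$bmi, d$weight / (d$height / 100)^2, tolerance = 1e-12)
})

test_that("degenerate configs collapse as expected", {
  cfg0 <- cohort_config(50, seed = 1, age_sd = 0, weight_sd = 0,
                        height_base_sd = 0, male_fraction = 1)
  set.seed(1)
  d <- sample_demographics(cfg0)
  expect_true(all(d$male))
  expect_equal(unique(d$age), 56)
  expect_equal(unique(d$weight), 69)
  expect_equal(unique(d$height), 160 + 11.3)
})

test_that("structural FVC model matches its plug-in arithmetic", {
  cfg <- cohort_config(1, seed = 1, fvc_sigma = 0)
  demo <- data.frame(male = TRUE, age = 56, height = 166, weight = 70,
                     bmi = 25.4)
  set.seed(1)
  sp <- simulate_spirometry(demo, obstructed = FALSE, cfg)
  # -6.4 + 0.065*166 - 0.022*56 + 0.6, with a calibrated intercept
  expect_equal(sp$fvc, -6.4 + 0.065 * 166 - 0.022 * 56 + 0.6,
               tolerance = 1e-9)
  expect_true(sp$fev1 < sp$fvc)
})

test_that("spirometric marginals hit the cohort targets", {
  cfg <- cohort_config(10000, seed = 3)
  set.seed(123)
  d <- sample_demographics(cfg)
  obst <- runif(10000) < cfg$obstruction_prevalence
  sp <- simulate_spirometry(d, obst, cfg)
  expect_equal(mean(sp$fvc), 3.49, tolerance = 0.1)
  expect_equal(mean(sp$fev1), 2.53, tolerance = 0.15)
  expect_true(all(sp$fev1 > 0 & sp$fev1 <= sp$fvc))
  # strict "<" at the boundary: non-obstructed ratios stay above 0.7
  expect_true(all((sp$ratio < 0.7) == obst))
})

test_that("obstruction labeling is strict at 0.7", {
  expect_false(label_obstruction(2.8, 4.0))
  expect_true(label_obstruction(2.0, 4.0))
  expect_false(label_obstruction(3.5, 4.0))
})

test_that("capnogram feature marginals track the cohort table", {
  co <- cached_cohort(1007)
  f <- cohort_features(co)
  expect_equal(mean(f$S3), 5.44, tolerance = 0.5)
  expect_equal(mean(f$Angle23[1:500]), 168.26, tolerance = 2)
  expect_equal(mean(f$V12), 276, tolerance = 25)
  expect_equal(mean(f$S2), 74.63, tolerance = 3)
  expect_equal(sum(f$male), 535, tolerance = 40)
  expect_true(all(lengths(lapply(co$subjects, `[[`, "sequence")) >= 4000))
})

test_that("obstruction shifts the phase III slope family upward", {
  co <- cached_cohort(1007)
  f <- cohort_features(co)
  expect_gt(mean(f$S3[f$obstructed]), mean(f$S3[!f$obstructed]))
  expect_gt(mean(f$S3_over_S2[f$obstructed]), mean(f$S3_over_S2[!f$obstructed]))
  expect_gt(mean(f$V3[f$obstructed] / f$fvc_l[f$obstructed]),
            mean(f$V3[!f$obstructed] / f$fvc_l[!f$obstructed]))
  expect_true(all((f$fev1_l / f$fvc_l < 0.7) == f$obstructed))
})

test_that("zero-noise capnograms round-trip the drawn slopes", {
  cfg <- cohort_config(4, seed = 6, noise_sd = 0)
  set.seed(6)
  sp <- data.frame(fvc = 3.5)
  cap <- simulate_capnogram(sp, obstructed = FALSE, cfg)
  f <- compute_features(cap$trace)
  expect_equal(f$S2, cap$features$S2, tolerance = 0.01 * cap$features$S2)
  expect_equal(f$S3, cap$features$S3, tolerance = 0.01 * cap$features$S3)
})

test_that("cohorts are deterministic and prefix-stable in n", {
  c1 <- generate_cohort(cohort_config(10, seed = 33))
  c2 <- generate_cohort(cohort_config(10, seed = 33))
  expect_identical(c1$subjects, c2$subjects)
  c3 <- generate_cohort(cohort_config(4, seed = 33))
  expect_identical(c3$subjects, c1$subjects[1:4])
  c4 <- generate_cohort(cohort_config(10, seed = 34))
  expect_false(identical(c4$subjects, c1$subjects))
})

test_that("invalid cohort sizes are rejected", {
  expect_error(cohort_config(0), class = "capnopred_invalid_argument")
  expect_error(cohort_config(10, nonsense_field = 1),
               class = "capnopred_invalid_argument")
})

test_that("cohort files round-trip through the CSV export", {
  co <- generate_cohort(cohort_config(3, seed = 12), keep_traces = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "features.csv")))
  expect_length(list.files(dir, pattern = "^breath_"), 3)
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_match(manifest[1], "seed: 12")
  tr <- read_breath_csv(file.path(dir, "breath_0001.csv"))
  expect_equal(tr$co2, co$subjects[[1]]$sequence)
})
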