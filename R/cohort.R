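# Synthetic capnography cohort generator.
#
# Produces cohorts of subject records (demographics, capnogram features,
# raw CO2 sequence, spirometry) with marginal distributions calibrated to
# a mixed clinical population of obstructed (FEV1/FVC < 0.7) and
# non-obstructed adults. The generator is first-class, tested code: it is
# the only data source for the pipeline, since no clinical recordings ship
# with the package. Only marginals and monotone obstruction effects are
# emulated; no inter-feature covariance structure is fitted.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the marginal structure of a mixed adult cohort:
#' 53.1% male; age 56 (14) years clipped to 17--70; height 166 (9) cm
#' (sex-structured: female base 160 (7) cm plus a male shift of 11.3 cm);
#' weight 69 (14) kg; obstruction prevalence 0.35. Spirometry follows a
#' structural model `FVC = b0 + bh*height + ba*age + bs*male + eps` with
#' `eps ~ N(0, 0.35 L)`, floored at 1 L, and `FEV1 = ratio * FVC` with the
#' ratio drawn per class (non-obstructed: N(0.80, 0.05) truncated to
#' (0.70, 0.95]; obstructed: N(0.60, 0.08) truncated to (0.30, 0.70)).
#' Capnogram features are drawn from marginals with cohort means C12 2.49
#' mmHg, V12 276 mL, V23 757 mL, S2 74.63 mmHg/L, S3 5.44 mmHg/L, V3 2061
#' mL; S3 and V3 are log-normal (right-skewed, strictly positive) with
#' obstructed subjects scaled by `s3_ob_mult` (1.6) and `v3_ob_mult` (1.2),
#' the base means chosen so the class mixture matches the cohort mean.
#' Volume features scale with each subject's FVC (larger lungs, larger
#' phase volumes), which is what makes the raw CO2 sequence informative
#' about FVC.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Base RNG seed; each subject uses a derived sub-seed, so the
#'   first `m` records of a cohort of size `n > m` equal a cohort of size
#'   `m` with the same seed.
#' @param male_fraction Probability a subject is male.
#' @param obstruction_prevalence Probability of airflow limitation.
#' @param noise_sd Gaussian noise added to the CO2 samples (mmHg).
#' @param fs Sampling frequency (Hz).
#' @param n_samples CO2 sequence length (>= 4000 samples).
#' @param ... Override any element of the default parameter list
#'   (see the source of this function for the full set of names).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n, seed = 1, male_fraction = 0.531,
                          obstruction_prevalence = 0.35,
                          noise_sd = 0.3, fs = 200, n_samples = 4200, ...) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_invalid("n must be a single integer >= 1")
  }
  cfg <- list(
    n = as.integer(n), seed = seed,
    male_fraction = male_fraction,
    obstruction_prevalence = obstruction_prevalence,
    noise_sd = noise_sd, fs = fs, n_samples = as.integer(n_samples),
    # demographics
    age_mean = 56, age_sd = 14, age_range = c(17, 70),
    height_base_mean = 160, height_base_sd = 7,
    height_male_shift = 11.3, height_range = c(140, 185),
    weight_mean = 69, weight_sd = 14, weight_range = c(40, 120),
    # spirometry structural model
    fvc_coef = c(intercept = -6.4, height = 0.065, age = -0.022, male = 0.6),
    fvc_sigma = 0.35, fvc_floor = 1.0, fvc_ref = 3.49,
    ratio_nonob = c(mean = 0.80, sd = 0.05, lo = 0.70, hi = 0.95),
    ratio_ob = c(mean = 0.60, sd = 0.08, lo = 0.30, hi = 0.70),
    # capnogram feature marginals. Volume features decompose into an
    # FVC-driven component ((FVC/3.49)^0.7) and an independent residual;
    # the residual SDs below are chosen so the *marginal* SDs match the
    # cohort table (V12 58, V23 157, V3 903) once the FVC scaling and the
    # obstruction mixture are folded in.
    c12 = c(mean = 2.49, sd = 0.80, lo = 0.2, hi = 5.5),
    v12 = c(mean = 276, sd = 29, lo = 170, hi = 400),
    v23 = c(mean = 757, sd = 79, lo = 520, hi = 1050),
    s2 = c(mean = 74.63, sd = 25.19, lo = 25, hi = 160),
    s3_mean = 5.44, s3_sdlog = 0.45, s3_ob_mult = 1.6,
    v3_mean = 2061, v3_sdlog = 0.40, v3_ob_mult = 1.2,
    fvc_volume_exponent = 0.7,
    min_v2 = 100, max_redraws = 100
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort_invalid(paste0("unknown config field(s): ",
                         paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (cfg$obstruction_prevalence < 0 || cfg$obstruction_prevalence > 1) {
    abort_invalid("obstruction_prevalence must be in [0, 1]")
  }
  if (cfg$n_samples < 4000) abort_invalid("n_samples must be >= 4000")
  structure(cfg, class = "cohort_config")
}

#' Sample demographic covariates
#'
#' Draws sex, age, height and weight from the configured marginals (age is
#' clipped to its range, height and weight use truncated normals) and
#' computes BMI from height and weight.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects to draw (default `config$n`). Draws come
#'   from the current RNG stream; seed externally for reproducibility.
#' @return A data.frame with columns `male` (logical), `age` (years),
#'   `height` (cm), `weight` (kg), `bmi` (kg/m^2).
#' @export
sample_demographics <- function(config, n = config$n) {
  stopifnot(inherits(config, "cohort_config"))
  male <- stats::runif(n) < config$male_fraction
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  height <- rtruncnorm(n, config$height_base_mean, config$height_base_sd,
                       config$height_range[1], config$height_range[2]) +
    config$height_male_shift * male
  weight <- rtruncnorm(n, config$weight_mean, config$weight_sd,
                       config$weight_range[1], config$weight_range[2])
  data.frame(male = male, age = age, height = height, weight = weight,
             bmi = weight / (height / 100)^2)
}

#' Simulate spirometry for sampled subjects
#'
#' Applies the structural FVC model and the class-conditional FEV1/FVC
#' ratio distributions of [cohort_config()].
#'
#' @param demographics Data.frame from [sample_demographics()].
#' @param obstructed Logical vector, one entry per subject.
#' @param config A [cohort_config()].
#' @return Data.frame with columns `fev1`, `fvc` (liters) and `ratio`.
#' @export
simulate_spirometry <- function(demographics, obstructed, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(demographics)
  b <- config$fvc_coef
  fvc <- b[["intercept"]] + b[["height"]] * demographics$height +
    b[["age"]] * demographics$age + b[["male"]] * demographics$male +
    stats::rnorm(n, 0, config$fvc_sigma)
  fvc <- pmax(fvc, config$fvc_floor)
  rn <- config$ratio_nonob
  ro <- config$ratio_ob
  ratio <- ifelse(
    obstructed,
    rtruncnorm(n, ro[["mean"]], ro[["sd"]], ro[["lo"]], ro[["hi"]]),
    rtruncnorm(n, rn[["mean"]], rn[["sd"]], rn[["lo"]], rn[["hi"]])
  )
  data.frame(fev1 = ratio * fvc, fvc = fvc, ratio = ratio)
}

# Draw one subject's capnogram feature set, enforcing geometric
# consistency (positive phase II volume; the plateau window of the
# extractor must start beyond the phase II/III boundary). Inconsistent
# draws are redrawn up to config$max_redraws times.
draw_capno_features <- function(fvc, obstructed, config) {
  sfvc <- (fvc / config$fvc_ref)^config$fvc_volume_exponent
  s3_base <- config$s3_mean /
    (1 - config$obstruction_prevalence +
       config$obstruction_prevalence * config$s3_ob_mult)
  v3_base <- config$v3_mean /
    (1 - config$obstruction_prevalence +
       config$obstruction_prevalence * config$v3_ob_mult)
  for (attempt in seq_len(config$max_redraws)) {
    c12 <- rtruncnorm(1, config$c12[["mean"]], config$c12[["sd"]],
                      config$c12[["lo"]], config$c12[["hi"]])
    v12 <- rtruncnorm(1, config$v12[["mean"]], config$v12[["sd"]],
                      config$v12[["lo"]], config$v12[["hi"]]) * sfvc
    v23 <- rtruncnorm(1, config$v23[["mean"]], config$v23[["sd"]],
                      config$v23[["lo"]], config$v23[["hi"]]) * sfvc
    s2 <- rtruncnorm(1, config$s2[["mean"]], config$s2[["sd"]],
                     config$s2[["lo"]], config$s2[["hi"]])
    s3 <- exp(stats::rnorm(1, log(s3_base) - config$s3_sdlog^2 / 2,
                           config$s3_sdlog))
    v3 <- exp(stats::rnorm(1, log(v3_base) - config$v3_sdlog^2 / 2,
                           config$v3_sdlog)) * sfvc
    if (obstructed) {
      s3 <- s3 * config$s3_ob_mult
      v3 <- v3 * config$v3_ob_mult
    }
    # consistency: positive phase II volume; plateau fit window (60% of
    # expired volume onward) past the II/III knee; phase I plateau long
    # enough to cover the baseline window (first 5% of expired volume)
    ok <- (v23 - v12) >= config$min_v2 &&
      v23 <= 0.58 * (v23 + v3) &&
      v12 >= 0.06 * (v23 + v3)
    if (ok) {
      c23 <- c12 + s2 * (v23 - v12) / 1000
      feats <- list(
        C12 = c12, C23 = c23, V12 = v12, V23 = v23,
        V2 = v23 - v12, V3 = v3, S2 = s2, S3 = s3,
        S3_over_S2 = s3 / s2,
        Angle23 = 180 - atan(s2) * 180 / pi + atan(s3) * 180 / pi
      )
      return(structure(feats, class = "capno_features"))
    }
  }
  abort_state(sprintf(
    "could not draw a geometrically consistent capnogram in %d attempts",
    config$max_redraws
  ))
}

#' Synthesize one subject's capnogram
#'
#' Draws a feature set consistent with the subject's FVC and obstruction
#' status, then renders the corresponding CO2-vs-volume curve as a
#' piecewise-linear capnogram (phase I plateau at C12, phase II line of
#' slope S2, phase III line of slope S3) sampled along a half-sine
#' expiratory flow profile at `config$fs` Hz, with additive Gaussian
#' noise of `config$noise_sd` mmHg (clamped at 0). Expiration duration
#' scales with the total expired volume at a roughly constant peak flow
#' (a larger vital capacity takes longer to exhale), so `config$n_samples`
#' is the sequence length at the reference expired volume of ~2.8 L; the
#' per-subject length is proportional to expired volume, floored at 4000
#' samples.
#'
#' @param spirometry One row of [simulate_spirometry()] output (or a list
#'   with an `fvc` element).
#' @param obstructed Logical scalar.
#' @param config A [cohort_config()].
#' @return List with elements `features` (a `capno_features`) and `trace`
#'   (a [capno_trace()]).
#' @export
simulate_capnogram <- function(spirometry, obstructed, config) {
  stopifnot(inherits(config, "cohort_config"))
  feats <- draw_capno_features(spirometry$fvc, obstructed, config)
  vend <- feats$V23 + feats$V3
  vend_ref <- config$v23[["mean"]] + config$v3_mean # ~2818 mL
  n <- max(4000L, as.integer(round(config$n_samples * vend / vend_ref)))
  # half-sine flow profile: volume(t) = vend * (1 - cos(pi * t/T)) / 2
  u <- seq(0, 1, length.out = n)
  vol <- vend * (1 - cos(pi * u)) / 2
  total_t <- (n - 1) / config$fs
  flow <- vend / 1000 * pi / (2 * total_t) * sin(pi * u)
  co2 <- ifelse(
    vol <= feats$V12, feats$C12,
    ifelse(vol <= feats$V23,
           feats$C12 + feats$S2 * (vol - feats$V12) / 1000,
           feats$C23 + feats$S3 * (vol - feats$V23) / 1000)
  )
  if (config$noise_sd > 0) {
    co2 <- co2 + stats::rnorm(n, 0, config$noise_sd)
  }
  co2 <- pmax(co2, 0)
  list(features = feats, trace = capno_trace(co2, flow, fs = config$fs))
}

#' Generate a complete synthetic cohort
#'
#' Draws `config$n` subject records. Each subject uses a deterministic
#' sub-seed derived from `config$seed`, so cohorts are reproducible and
#' records are independent of the cohort size.
#'
#' @param config A [cohort_config()].
#' @param keep_traces Keep each subject's full `capno_trace` (flow and
#'   volume included) in the record. Off by default to bound memory; the
#'   CO2 sequence is always kept.
#' @return Object of class `capno_cohort`: a list with `subjects` (list of
#'   records: `id`, `male`, `age`, `height`, `weight`, `bmi`, `features`,
#'   `sequence`, `fev1`, `fvc`, `obstructed`) and `config`.
#' @export
generate_cohort <- function(config, keep_traces = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    set.seed(sub_seed(config$seed, i))
    demo <- sample_demographics(config, n = 1)
    obstructed <- stats::runif(1) < config$obstruction_prevalence
    spiro <- simulate_spirometry(demo, obstructed, config)
    cap <- simulate_capnogram(spiro, obstructed, config)
    rec <- list(
      id = i, male = demo$male, age = demo$age, height = demo$height,
      weight = demo$weight, bmi = demo$bmi,
      features = cap$features, sequence = cap$trace$co2,
      fev1 = spiro$fev1, fvc = spiro$fvc,
      obstructed = obstructed
    )
    if (keep_traces) rec$trace <- cap$trace
    subjects[[i]] <- rec
  }
  structure(list(subjects = subjects, config = config),
            class = "capno_cohort")
}

#' @export
print.capno_cohort <- function(x, ...) {
  obs <- mean(vapply(x$subjects, `[[`, logical(1), "obstructed"))
  cat(sprintf("<capno_cohort> %d subjects (%.0f%% obstructed), seed %s\n",
              length(x$subjects), 100 * obs, format(x$config$seed)))
  invisible(x)
}

#' Tabulate a cohort's per-subject features
#'
#' @param cohort A [generate_cohort()] result.
#' @return Data.frame with demographics, the ten capnogram features,
#'   `fev1_l`, `fvc_l` and `obstructed`.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "capno_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    cbind(
      data.frame(id = s$id, male = s$male, age = s$age, height = s$height,
                 weight = s$weight, bmi = s$bmi),
      as.data.frame(s$features),
      data.frame(fev1_l = s$fev1, fvc_l = s$fvc, obstructed = s$obstructed)
    )
  })
  do.call(rbind, rows)
}

#' Stack a cohort's CO2 sequences into a matrix
#'
#' Sequence lengths vary with expired volume; shorter sequences are
#' right-padded with their final (end-tidal) value to the cohort
#' maximum, matching the padding rule of [preprocess_sequence()].
#'
#' @param cohort A [generate_cohort()] result.
#' @return Numeric matrix, one row per subject (mmHg).
#' @export
cohort_sequences <- function(cohort) {
  stopifnot(inherits(cohort, "capno_cohort"))
  seqs <- lapply(cohort$subjects, `[[`, "sequence")
  nmax <- max(lengths(seqs))
  do.call(rbind, lapply(seqs, function(s) {
    c(s, rep(s[length(s)], nmax - length(s)))
  }))
}

#' Write a cohort to disk
#'
#' Writes `features.csv` (one row per subject), one breath CSV per subject
#' (`breath_<id>.csv`, schema `time_s, co2_mmHg, flow_lps`; flow is only
#' available when the cohort was generated with `keep_traces = TRUE`,
#' otherwise a flow of NA is written) and a `manifest.txt` recording the
#' seed and a config fingerprint.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "capno_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort_features(cohort),
                   file.path(dir, "features.csv"), row.names = FALSE)
  fs <- cohort$config$fs
  for (s in cohort$subjects) {
    n <- length(s$sequence)
    flow <- if (!is.null(s$trace)) s$trace$flow else rep(NA_real_, n)
    utils::write.csv(
      data.frame(time_s = (seq_len(n) - 1) / fs, co2_mmHg = s$sequence,
                 flow_lps = flow),
      file.path(dir, sprintf("breath_%04d.csv", s$id)), row.names = FALSE
    )
  }
  writeLines(c(
    sprintf("seed: %s", format(cohort$config$seed)),
    sprintf("n: %d", length(cohort$subjects)),
    sprintf("config_hash: %s", config_hash(unclass(cohort$config)))
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}
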