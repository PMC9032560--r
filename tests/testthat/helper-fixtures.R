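# Shared fixtures, built in code at test time.

# Build an exact piecewise-linear volumetric capnogram from its geometric
# parameters, independently of the package's cohort generator: phase I
# flat at c12 up to v12 (mL), phase II line of slope s2 (mmHg/L) up to
# v23, phase III line of slope s3 up to v23 + v3. Sampled along a
# half-sine flow profile.
make_piecewise_trace <- function(s2, s3, c12 = 2.5, v12 = 276, v23 = 757,
                                 v3 = 2061, fs = 200, n = 4200,
                                 noise_sd = 0) {
  vend <- v23 + v3
  u <- seq(0, 1, length.out = n)
  vol <- vend * (1 - cos(pi * u)) / 2
  total_t <- (n - 1) / fs
  flow <- vend / 1000 * pi / (2 * total_t) * sin(pi * u)
  c23 <- c12 + s2 * (v23 - v12) / 1000
  co2 <- ifelse(vol <= v12, c12,
                ifelse(vol <= v23, c12 + s2 * (vol - v12) / 1000,
                       c23 + s3 * (vol - v23) / 1000))
  if (noise_sd > 0) co2 <- pmax(co2 + rnorm(n, 0, noise_sd), 0)
  capno_trace(co2, flow, fs = fs)
}

# Cohorts are expensive; cache them per (n, seed, noise) within a test run.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed = 42, noise_sd = 0.3, ...) {
  key <- paste(n, seed, noise_sd, ..., sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      cohort_config(n, seed = seed, noise_sd = noise_sd, ...))
  }
  .cohort_cache[[key]]
}

# Small deterministic regression problem with a linearly separable
# obstruction structure, for the medical-structure unit tests.
toy_medical_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  feats <- data.frame(
    male = rep(c(TRUE, FALSE), length.out = n),
    age = runif(n, 20, 70), height = runif(n, 150, 190),
    weight = runif(n, 50, 100)
  )
  feats$bmi <- feats$weight / (feats$height / 100)^2
  for (nm in setdiff(medical_feature_names, names(feats))) {
    feats[[nm]] <- runif(n, 1, 2)
  }
  fvc <- 0.05 * feats$height - 4.5 + rnorm(n, 0, 0.1)
  ratio <- ifelse(seq_len(n) %% 3 == 0, 0.60, 0.80)
  feats$S3 <- ifelse(ratio < 0.7, 9, 4) # separable obstruction marker
  list(features = feats, targets = cbind(fvc * ratio, fvc),
       obstructed = ratio < 0.7)
}
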