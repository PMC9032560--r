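# Volumetric capnogram construction and feature extraction.
#
# A single expiration is represented as paired CO2 partial pressure (mmHg)
# and expiratory flow (L/s) samples at a fixed sampling frequency. Plotting
# CO2 against cumulative expired volume gives the volumetric capnogram,
# conventionally divided into phase I (airway dead-space gas, near-baseline
# CO2), phase II (the steep transition as alveolar gas reaches the sensor)
# and phase III (the alveolar plateau with a shallow positive slope).

#' Canonical order of the capnogram feature set
#'
#' C12/C23: CO2 (mmHg) at the phase I/II and II/III boundaries; V12/V23:
#' expired volume (mL) at those boundaries; V2/V3: phase II and III volumes
#' (mL); S2/S3: least-squares slopes of phases II and III (mmHg/L);
#' S3_over_S2: their ratio; Angle23: the interior angle (degrees) between
#' the fitted phase II and III lines.
#' @export
capno_feature_names <- c(
  "C12", "C23", "V12", "V23", "V2", "V3",
  "S2", "S3", "S3_over_S2", "Angle23"
)

#' Construct a single-breath capnogram trace
#'
#' Bundles the CO2 and flow samples of one expiration with the derived
#' cumulative expired volume (via [integrate_volume()]).
#'
#' @param co2 CO2 partial pressure samples (mmHg), all non-negative.
#' @param flow Expiratory flow samples (L/s), same length as `co2`.
#' @param fs Sampling frequency in Hz (default 200).
#' @return An object of class `capno_trace` with elements `co2`, `flow`,
#'   `fs` and `volume` (mL, non-decreasing, starting at 0).
#' @export
capno_trace <- function(co2, flow, fs = 200) {
  if (length(co2) < 2 || length(co2) != length(flow)) {
    abort_invalid("co2 and flow must have equal length >= 2")
  }
  if (!all(is.finite(co2)) || !all(is.finite(flow))) {
    abort_invalid("co2 and flow must be finite")
  }
  if (any(co2 < 0)) abort_invalid("co2 values must be >= 0 mmHg")
  volume <- integrate_volume(flow, fs)
  if (any(diff(volume) < -1e-9)) {
    abort_invalid("expired volume must be non-decreasing (negative flow)")
  }
  structure(list(co2 = co2, flow = flow, fs = fs, volume = volume),
            class = "capno_trace")
}

#' @export
print.capno_trace <- function(x, ...) {
  cat(sprintf(
    "<capno_trace> %d samples @ %g Hz, expired volume %.0f mL, end CO2 %.1f mmHg\n",
    length(x$co2), x$fs, max(x$volume), x$co2[length(x$co2)]
  ))
  invisible(x)
}

#' Cumulative expired volume from a flow signal
#'
#' Trapezoidal integration of expiratory flow over time, converted to mL.
#'
#' @param flow Flow samples (L/s).
#' @param fs Sampling frequency (Hz).
#' @return Numeric vector of cumulative volumes (mL); first element 0.
#' @export
integrate_volume <- function(flow, fs = 200) {
  if (length(flow) == 0) abort_invalid("flow must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort_invalid("fs must be a single positive number")
  }
  n <- length(flow)
  if (n == 1) return(0)
  steps <- (flow[-n] + flow[-1]) / 2 / fs
  c(0, cumsum(steps)) * 1000
}

#' Fit the phase II and phase III regression lines of a capnogram
#'
#' Two-pass segmentation. The phase III (alveolar plateau) line is fitted
#' first, by least squares over the samples between `phase3_window[1]` and
#' `phase3_window[2]` of total expired volume. The phase II line is then
#' fitted over the samples whose CO2 lies between `phase2_band[1]` and
#' `phase2_band[2]` of the end-tidal value, excluding samples lying on the
#' already-fitted plateau line (within `plateau_tol` mmHg of its
#' prediction); the exclusion keeps early plateau samples out of the
#' transition fit when the plateau is steep enough to enter the CO2 band.
#' Both lines are expressed in (volume in L, CO2 in mmHg) coordinates so
#' slopes are in mmHg/L.
#'
#' @param trace A [capno_trace()] covering one full expiration.
#' @param phase3_window Fractions of total expired volume bounding the
#'   plateau fit (default 60--95%).
#' @param phase2_band Fractions of end-tidal CO2 bounding the transition
#'   fit (default 25--75%).
#' @param plateau_tol Exclusion tolerance below the plateau line, mmHg.
#' @return Object of class `capno_phase_fit`: lists `phase2` and `phase3`
#'   with `intercept` (mmHg) and `slope` (mmHg/L), plus `vend` (end-expired
#'   volume, mL), `et` (end-tidal CO2, mmHg) and `baseline` (phase I CO2,
#'   mmHg, mean over the first 5% of expired volume).
#' @export
fit_phase_lines <- function(trace, phase3_window = c(0.60, 0.95),
                            phase2_band = c(0.25, 0.75),
                            plateau_tol = 1.0) {
  stopifnot(inherits(trace, "capno_trace"))
  vol <- trace$volume
  co2 <- trace$co2
  vend <- vol[length(vol)]
  if (vend <= 0) {
    abort("no expired volume recorded", "capnopred_extraction_failure")
  }

  # End-tidal CO2: mean over the last 2% of expired volume (noise robust).
  et <- mean(co2[vol >= 0.98 * vend])
  baseline <- mean(co2[vol <= 0.05 * vend])

  i3 <- which(vol >= phase3_window[1] * vend & vol <= phase3_window[2] * vend)
  if (length(i3) < 3) {
    abort(sprintf(
      "fewer than 3 samples in the phase III window (%g-%g%% of expired volume)",
      100 * phase3_window[1], 100 * phase3_window[2]
    ), "capnopred_extraction_failure")
  }
  f3 <- stats::lm.fit(cbind(1, vol[i3] / 1000), co2[i3])$coefficients

  in_band <- co2 >= phase2_band[1] * et & co2 <= phase2_band[2] * et
  below_plateau <- co2 < (f3[1] + f3[2] * vol / 1000) - plateau_tol
  i2 <- which(in_band & below_plateau)
  if (length(i2) < 3) {
    abort(sprintf(
      "fewer than 3 samples in the phase II band (%g-%g%% of end-tidal CO2, below the plateau line)",
      100 * phase2_band[1], 100 * phase2_band[2]
    ), "capnopred_extraction_failure")
  }
  f2 <- stats::lm.fit(cbind(1, vol[i2] / 1000), co2[i2])$coefficients
  if (!is.finite(f2[2]) || f2[2] <= 0) {
    abort("phase II slope is not positive; not a valid expiration",
          "capnopred_extraction_failure")
  }

  structure(list(
    phase2 = list(intercept = unname(f2[1]), slope = unname(f2[2])),
    phase3 = list(intercept = unname(f3[1]), slope = unname(f3[2])),
    vend = vend, et = et, baseline = baseline
  ), class = "capno_phase_fit")
}

#' Extract the capnogram feature set from a trace
#'
#' Computes the ten features in [capno_feature_names] from the fitted
#' phase lines: the phase I/II boundary is the intersection of the phase II
#' line with the phase I baseline; the phase II/III boundary is the
#' intersection of the phase II and phase III lines; `Angle23` is the
#' interior angle at that knee, `180 - atan(S2) + atan(S3)` in degrees with
#' the slopes taken in mmHg/L (no axis renormalization).
#'
#' @param trace A [capno_trace()].
#' @param fit Optional precomputed [fit_phase_lines()] result.
#' @param ... Passed on to [fit_phase_lines()].
#' @return Object of class `capno_features`: a named list of the ten
#'   feature values (units as in [capno_feature_names]).
#' @export
compute_features <- function(trace, fit = NULL, ...) {
  stopifnot(inherits(trace, "capno_trace"))
  if (is.null(fit)) fit <- fit_phase_lines(trace, ...)
  s2 <- fit$phase2$slope
  s3 <- fit$phase3$slope
  c12 <- fit$baseline
  v12 <- (c12 - fit$phase2$intercept) / s2 * 1000
  if (abs(s2 - s3) < 1e-12) {
    abort("phase II and III lines are parallel", "capnopred_extraction_failure")
  }
  v23 <- (fit$phase3$intercept - fit$phase2$intercept) / (s2 - s3) * 1000
  c23 <- fit$phase2$intercept + s2 * v23 / 1000
  if (v23 < v12) {
    abort("phase II/III boundary precedes phase I/II boundary",
          "capnopred_extraction_failure")
  }
  v3 <- fit$vend - v23
  if (v3 < 0) {
    abort("phase II/III boundary beyond end-expired volume",
          "capnopred_extraction_failure")
  }
  feats <- list(
    C12 = c12, C23 = c23, V12 = v12, V23 = v23,
    V2 = v23 - v12, V3 = v3, S2 = s2, S3 = s3,
    S3_over_S2 = s3 / s2,
    Angle23 = 180 - atan(s2) * 180 / pi + atan(s3) * 180 / pi
  )
  structure(feats, class = "capno_features")
}

#' @export
print.capno_features <- function(x, ...) {
  cat("<capno_features>\n")
  print(unlist(x[capno_feature_names]))
  invisible(x)
}

#' @export
as.data.frame.capno_features <- function(x, ...) {
  as.data.frame(x[capno_feature_names], ...)
}

#' Read a single-breath device export
#'
#' Expects the per-breath CSV schema `time_s, co2_mmHg, flow_lps`.
#'
#' @param path Path to the CSV file.
#' @return A [capno_trace()]. The sampling frequency is inferred from the
#'   median time step.
#' @export
read_breath_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "co2_mmHg", "flow_lps")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_invalid(paste0("breath CSV missing column(s): ",
                         paste(missing, collapse = ", ")))
  }
  dt <- stats::median(diff(df$time_s))
  capno_trace(df$co2_mmHg, df$flow_lps, fs = 1 / dt)
}

#' Write a single-breath trace as a device-format CSV
#'
#' @param trace A [capno_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breath_csv <- function(trace, path) {
  stopifnot(inherits(trace, "capno_trace"))
  n <- length(trace$co2)
  utils::write.csv(data.frame(
    time_s = (seq_len(n) - 1) / trace$fs,
    co2_mmHg = trace$co2,
    flow_lps = trace$flow
  ), path, row.names = FALSE)
  invisible(path)
}
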