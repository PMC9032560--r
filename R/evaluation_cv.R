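# Repeated stratified k-fold cross-validation harness.
#
# Each repeat re-partitions the cohort into k obstruction-stratified
# folds. Within an outer fold, three algorithm variants are trained on
# the k-1 training folds and evaluated on the held-out fold:
#   medical     - the two-level SVM + boosted-trees structure,
#   sequence    - the 1D convolutional network on the raw CO2 series,
#   combination - both structures plus KNN error correction. The quads
#                 the corrector is trained on come from inner
#                 out-of-fold predictions of the two structures (inner
#                 5-fold by default), so the corrector never sees quads
#                 produced by models trained on their own subjects.
# Metrics are computed per fold, then averaged over folds and repeats.

#' Cross-validation plan
#'
#' @param k Fold count (default 10).
#' @param repeats Number of independent repetitions (default 10).
#' @param seed Base seed; each repeat derives its own shuffle seed.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(k = 10, repeats = 10, seed = 1) {
  if (k < 2) abort_invalid("k must be >= 2")
  if (repeats < 1) abort_invalid("repeats must be >= 1")
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = seed), class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Subjects are shuffled within each stratum and dealt round-robin into
#' folds, with the deal position carried across strata, so fold sizes
#' differ by at most one overall and each fold's stratum fraction is
#' within one subject of the global fraction.
#'
#' @param labels Stratification labels (e.g. the obstruction indicator),
#'   one per subject.
#' @param k Fold count; requires `length(labels) >= k`.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  n <- length(labels)
  if (n < k) abort_invalid(sprintf("need at least k = %d subjects, got %d", k, n))
  set.seed(seed)
  fold <- integer(n)
  pos <- sample.int(k, 1) - 1 # random deal offset
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (pos + seq_along(idx) - 1) %% k + 1
    pos <- pos + length(idx)
  }
  fold
}

# Default pipeline configuration for run_cv.
pipeline_config <- function(epochs = 20, input_length = 2400, knn_k = 5,
                            inner_folds = 5, stage1_cost = 1,
                            stage2_params = list(), network = NULL,
                            seed = 1) {
  list(epochs = epochs, input_length = input_length, knn_k = knn_k,
       inner_folds = inner_folds, stage1_cost = stage1_cost,
       stage2_params = stage2_params, network = network, seed = seed)
}

# Train medical + sequence structures on `tr` rows and return the n_test
# x 4 quad matrix (FEV1_med, FVC_med, FEV1_seq, FVC_seq) for `te` rows.
predict_quads <- function(data, tr, te, config, seed) {
  med <- train_medical(data$features[tr, , drop = FALSE],
                       data$targets[tr, , drop = FALSE],
                       stage1_cost = config$stage1_cost,
                       stage2_params = config$stage2_params, seed = seed)
  med_pred <- predict_medical(med, data$features[te, , drop = FALSE])
  net_cfg <- config$network
  if (is.null(net_cfg)) {
    net_cfg <- network_config(input_length = config$input_length,
                              epochs = config$epochs, seed = seed)
  } else {
    net_cfg$seed <- seed
  }
  net <- build_network(net_cfg)
  net <- train_network(net, data$x_seq[tr, , drop = FALSE],
                       data$targets[tr, , drop = FALSE])
  seq_pred <- predict_sequence(net, data$x_seq[te, , drop = FALSE])
  cbind(FEV1_med = med_pred[, 1], FVC_med = med_pred[, 2],
        FEV1_seq = seq_pred[, 1], FVC_seq = seq_pred[, 2])
}

#' Run the cross-validation experiment
#'
#' Evaluates the medical, sequence and combination variants under a
#' repeated stratified k-fold plan and reports the averaged metric table
#' (one row per variant x parameter).
#'
#' @param cohort A [generate_cohort()] cohort (size >= 20).
#' @param plan A [cv_plan()].
#' @param epochs Network training epochs per fold.
#' @param knn_k Neighbor count of the correction stage.
#' @param inner_folds Inner fold count for the out-of-fold quads.
#' @param input_length Network input length (samples).
#' @param stage1_cost,stage2_params Medical-structure hyperparameters.
#' @param network Optional [network_config()] overriding the default.
#' @param variant_fns Optional named list of custom variants for harness
#'   testing: each element is `function(data, tr, te)` returning an
#'   n_test x 2 prediction matrix; replaces the built-in variants.
#' @return A data.frame of class `cv_report`: `variant`, `parameter`,
#'   `RMSE`, `R2`, `MPE`, `MAPE`, `RMSPE`, `CPE`, `ACC`, averaged over
#'   folds and repeats.
#' @export
run_cv <- function(cohort, plan = cv_plan(), epochs = 20, knn_k = 5,
                   inner_folds = 5, input_length = 2400, stage1_cost = 1,
                   stage2_params = list(), network = NULL,
                   variant_fns = NULL) {
  stopifnot(inherits(cohort, "capno_cohort"), inherits(plan, "cv_plan"))
  feats <- cohort_features(cohort)
  n <- nrow(feats)
  if (n < 20) abort_invalid("cohort size must be >= 20")
  data <- list(
    features = feats[medical_feature_names],
    targets = as.matrix(feats[c("fev1_l", "fvc_l")]),
    labels = feats$obstructed,
    x_seq = if (is.null(variant_fns)) {
      preprocess_batch(cohort_sequences(cohort), input_length = input_length)
    } else NULL
  )
  config <- pipeline_config(epochs = epochs, input_length = input_length,
                            knn_k = knn_k, inner_folds = inner_folds,
                            stage1_cost = stage1_cost,
                            stage2_params = stage2_params, network = network)

  rows <- list()
  for (r in seq_len(plan$repeats)) {
    fold <- make_folds(data$labels, plan$k, seed = sub_seed(plan$seed, r))
    for (f in seq_len(plan$k)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      seed_rf <- sub_seed(plan$seed, r * 1000 + f)
      preds <- if (is.null(variant_fns)) {
        cv_fold_predictions(data, tr, te, config, seed_rf)
      } else {
        lapply(variant_fns, function(fn) fn(data, tr, te))
      }
      for (v in names(preds)) {
        for (j in 1:2) {
          rep_row <- metric_report(preds[[v]][, j], data$targets[te, j])
          rows[[length(rows) + 1]] <- cbind(
            data.frame(variant = v, parameter = c("FEV1", "FVC")[j],
                       repeat_id = r, fold = f),
            rep_row
          )
        }
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("RMSE", "R2", "MPE", "MAPE", "RMSPE", "CPE", "ACC")
  agg <- stats::aggregate(per_fold[metric_cols],
                          per_fold[c("variant", "parameter")], mean)
  agg <- agg[order(agg$parameter, agg$variant), ]
  rownames(agg) <- NULL
  attr(agg, "per_fold") <- per_fold
  class(agg) <- c("cv_report", "data.frame")
  agg
}

# Built-in variant predictions for one outer fold.
cv_fold_predictions <- function(data, tr, te, config, seed) {
  # full-fold models give both single-structure predictions and the
  # test-time quads
  quads_te <- predict_quads(data, tr, te, config, seed)

  # out-of-fold quads for the correction stage's training set
  inner <- make_folds(data$labels[tr], config$inner_folds, seed = seed)
  quads_tr <- matrix(NA_real_, length(tr), 4)
  for (g in seq_len(config$inner_folds)) {
    itr <- tr[inner != g]
    ite <- tr[inner == g]
    quads_tr[inner == g, ] <- predict_quads(data, itr, ite, config,
                                            seed = seed + g)
  }
  corr <- fit_correction(quads_tr, data$targets[tr, , drop = FALSE],
                         k = config$knn_k)
  list(
    medical = quads_te[, 1:2],
    sequence = quads_te[, 3:4],
    combination = predict_corrected(corr, quads_te)
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validated results (averaged over folds and repeats)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df)
  invisible(x)
}

#' Write a cross-validation report as CSV and a formatted table
#'
#' @param report A [run_cv()] report.
#' @param path Output CSV path; a `.txt` table with the same stem is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(path)
}
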