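# Two-level medical feature regression.
#
# Stage 1 is a radial-kernel maximum-margin classifier (SVM) trained on
# standardized demographic + capnogram features against the fixed-ratio
# airflow-limitation label FEV1/FVC < 0.7. Its real-valued decision score
# z is mapped through the logistic sigmoid 1/(1 + exp(-z)) (no fitted
# Platt scaling) to an obstruction probability, which is appended to the
# raw features. Stage 2 fits one gradient-boosted regression-tree
# ensemble per target (FEV1, FVC) on the fused 16-feature vectors. Solver
# internals (the margin optimizer, the tree boosting) are delegated to
# e1071/libsvm and xgboost; this module owns labeling, standardization,
# probabilization, fusion, hyperparameter search and composition.

#' Canonical order of the medical feature vector
#'
#' Five demographic fields followed by the ten capnogram features; the
#' fused vector appends `obstruction_prob` as feature 16.
#' @export
medical_feature_names <- c("male", "age", "height", "weight", "bmi",
                           capno_feature_names)

#' Label airflow limitation from spirometry
#'
#' The fixed-ratio criterion: obstructed iff `fev1 / fvc < 0.7`
#' (strictly; a ratio of exactly 0.7 is not obstructed).
#'
#' @param fev1,fvc Measured values in liters; `fvc` must be positive.
#' @return Logical vector.
#' @export
label_obstruction <- function(fev1, fvc) {
  if (any(fvc <= 0)) abort_invalid("fvc must be > 0")
  fev1 / fvc < 0.7
}

# Validate and coerce a feature table to the canonical 15-column matrix.
medical_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    missing <- setdiff(medical_feature_names, names(features))
    if (length(missing)) {
      abort_invalid(paste0("feature table missing column(s): ",
                           paste(missing, collapse = ", ")))
    }
    features <- features[medical_feature_names]
    features$male <- as.numeric(features$male)
    features <- as.matrix(features)
  } else {
    features <- as.matrix(features)
    if (ncol(features) != length(medical_feature_names)) {
      abort_invalid(sprintf("expected %d feature columns, got %d",
                            length(medical_feature_names), ncol(features)))
    }
  }
  if (anyNA(features) || !all(is.finite(features))) {
    abort_invalid("feature matrix contains missing or non-finite values")
  }
  storage.mode(features) <- "double"
  features
}

#' Train the stage-1 obstruction classifier
#'
#' Standardizes the features (statistics learned here, i.e. on training
#' data only), fits a radial-kernel SVM, and orients the decision score
#' so larger z means more likely obstructed.
#'
#' @param features Feature table or matrix in [medical_feature_names]
#'   order.
#' @param labels Logical obstruction labels (both classes must occur).
#' @param cost Soft-margin cost C.
#' @param gamma Kernel width; default `1 / n_features` on the
#'   standardized scale.
#' @return Object of class `stage1_model`.
#' @export
train_stage1 <- function(features, labels, cost = 1, gamma = NULL) {
  x <- medical_feature_matrix(features)
  if (nrow(x) == 0) abort_invalid("empty training set")
  if (length(labels) != nrow(x)) abort_invalid("labels must match rows")
  if (length(unique(labels)) < 2) {
    abort("stage-1 training requires both obstruction classes",
          "capnopred_degenerate_labels")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center, scale)
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  fit <- e1071::svm(xs, factor(labels, levels = c(FALSE, TRUE)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  model <- structure(list(svm = fit, center = center, scale = scale,
                          sign = 1), class = "stage1_model")
  z <- decision_score(model, x)
  if (mean(z[labels]) < mean(z[!labels])) model$sign <- -1
  model
}

#' Decision score of the stage-1 classifier
#'
#' @param model A [train_stage1()] model.
#' @param features Feature table or matrix.
#' @return Numeric vector of oriented decision scores z (larger = more
#'   likely obstructed).
#' @export
decision_score <- function(model, features) {
  stopifnot(inherits(model, "stage1_model"))
  x <- medical_feature_matrix(features)
  xs <- scale(x, model$center, model$scale)
  dv <- attr(stats::predict(model$svm, xs, decision.values = TRUE),
             "decision.values")
  z <- as.numeric(dv) * model$sign
  # libsvm reports the margin for the first factor level (FALSE); flip so
  # positive z favors obstruction
  if (colnames(dv)[1] == "FALSE/TRUE") z <- -z
  z
}

#' Obstruction probability via the logistic sigmoid
#'
#' `p = 1 / (1 + exp(-z))` applied to the raw decision score (strictly
#' monotone in z).
#'
#' @inheritParams decision_score
#' @return Probabilities in (0, 1).
#' @export
obstruction_probability <- function(model, features) {
  1 / (1 + exp(-decision_score(model, features)))
}

#' Fuse the stage-1 probability into the feature vector
#'
#' Appends `p` as the last feature (`obstruction_prob`, feature 16).
#'
#' @param features Feature table or matrix (15 columns).
#' @param p Obstruction probabilities, one per row.
#' @return Matrix with 16 columns.
#' @export
fuse_features <- function(features, p) {
  x <- medical_feature_matrix(features)
  if (length(p) != nrow(x)) abort_invalid("p must have one value per row")
  cbind(x, obstruction_prob = as.numeric(p))
}

# Default stage-2 boosting hyperparameters.
stage2_defaults <- function() {
  list(nrounds = 200, eta = 0.1, max_depth = 4, subsample = 1,
       colsample_bytree = 0.8, lambda = 1, gamma = 0)
}

fit_booster <- function(x, y, params, seed) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  max_depth = params$max_depth, subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  lambda = params$lambda, gamma = params$gamma,
                  seed = seed, nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = params$nrounds, verbose = 0
  )
}

#' Train the stage-2 boosted regression ensembles
#'
#' One independent gradient-boosted tree ensemble per target (FEV1, FVC)
#' on the fused 16-feature vectors.
#'
#' @param fused Matrix from [fuse_features()].
#' @param targets Matrix n x 2 of measured FEV1, FVC (liters).
#' @param params Hyperparameter list (see `stage2_defaults` in the
#'   source): `nrounds`, `eta`, `max_depth`, `subsample`,
#'   `colsample_bytree`, `lambda`, `gamma`. Partial lists are completed
#'   with the defaults.
#' @param seed Seed for the boosting RNG (column subsampling).
#' @return Object of class `stage2_model`.
#' @export
train_stage2 <- function(fused, targets, params = list(), seed = 1) {
  fused <- as.matrix(fused)
  targets <- as.matrix(targets)
  if (nrow(fused) < 10) abort_invalid("stage-2 training requires n >= 10")
  if (nrow(targets) != nrow(fused) || ncol(targets) != 2) {
    abort_invalid("targets must be an n x 2 matrix matching the features")
  }
  full <- utils::modifyList(stage2_defaults(), params)
  boosters <- list(
    fev1 = fit_booster(fused, targets[, 1], full, seed),
    fvc = fit_booster(fused, targets[, 2], full, seed + 1)
  )
  structure(list(boosters = boosters, params = full,
                 feature_names = colnames(fused)),
            class = "stage2_model")
}

#' Normalized gain-based feature importance of stage 2
#'
#' All 16 fused features are listed (zero gain for unused ones) and each
#' target's importances sum to 1.
#'
#' @param model A [train_stage2()] model.
#' @return Data.frame: `feature`, `gain_fev1`, `gain_fvc`.
#' @export
stage2_importance <- function(model) {
  stopifnot(inherits(model, "stage2_model"))
  one <- function(b) {
    imp <- xgboost::xgb.importance(model = b)
    gain <- stats::setNames(rep(0, length(model$feature_names)),
                            model$feature_names)
    gain[imp$Feature] <- imp$Gain
    gain / sum(gain)
  }
  data.frame(feature = model$feature_names,
             gain_fev1 = unname(one(model$boosters$fev1)),
             gain_fvc = unname(one(model$boosters$fvc)))
}

#' Coarse-to-fine hyperparameter search for stage 2
#'
#' Evaluates each candidate by inner k-fold cross-validated RMSE
#' (averaged over the two targets), then refines once around the best
#' point (halved/doubled learning rate, depth +/- 1) and re-evaluates.
#' Ties are broken by fewer boosting rounds, then smaller depth.
#'
#' @param grid List of (partial) hyperparameter lists; must be non-empty.
#' @param fused,targets Training data as in [train_stage2()].
#' @param folds Inner fold count (default 3).
#' @param seed Seed controlling fold assignment and boosting.
#' @return The selected hyperparameter list (completed with defaults).
#' @export
heuristic_search <- function(grid, fused, targets, folds = 3, seed = 1) {
  if (length(grid) == 0) abort_invalid("hyperparameter grid is empty")
  fused <- as.matrix(fused)
  targets <- as.matrix(targets)
  n <- nrow(fused)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  cv_rmse <- function(params) {
    full <- utils::modifyList(stage2_defaults(), params)
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      preds <- vapply(1:2, function(j) {
        b <- fit_booster(fused[tr, , drop = FALSE], targets[tr, j], full, seed)
        stats::predict(b, xgboost::xgb.DMatrix(fused[!tr, , drop = FALSE]))
      }, numeric(sum(!tr)))
      sqrt(mean((preds - targets[!tr, ])^2))
    }, numeric(1))
    mean(errs)
  }

  evaluate <- function(cands) {
    scores <- vapply(cands, cv_rmse, numeric(1))
    full <- lapply(cands, function(p) utils::modifyList(stage2_defaults(), p))
    nr <- vapply(full, `[[`, numeric(1), "nrounds")
    dp <- vapply(full, `[[`, numeric(1), "max_depth")
    best <- order(scores, nr, dp)[1]
    list(params = full[[best]], score = scores[best])
  }

  coarse <- evaluate(grid)
  refine <- list()
  for (eta_m in c(0.5, 2)) {
    refine <- c(refine, list(utils::modifyList(
      coarse$params, list(eta = coarse$params$eta * eta_m))))
  }
  for (dd in c(-1, 1)) {
    d <- coarse$params$max_depth + dd
    if (d >= 1) {
      refine <- c(refine, list(utils::modifyList(
        coarse$params, list(max_depth = d))))
    }
  }
  fine <- evaluate(c(list(coarse$params), refine))
  fine$params
}

#' Train the full two-level medical structure
#'
#' Labels obstruction from the targets, trains stage 1, probabilizes and
#' fuses, then trains stage 2.
#'
#' @param features Feature table or matrix in [medical_feature_names]
#'   order.
#' @param targets Matrix n x 2 of measured FEV1, FVC (liters).
#' @param stage1_cost,stage1_gamma Stage-1 SVM hyperparameters.
#' @param stage2_params Stage-2 hyperparameter list (see
#'   [train_stage2()]).
#' @param seed Seed for the boosting RNG.
#' @return Object of class `medical_model`.
#' @export
train_medical <- function(features, targets, stage1_cost = 1,
                          stage1_gamma = NULL, stage2_params = list(),
                          seed = 1) {
  targets <- as.matrix(targets)
  labels <- label_obstruction(targets[, 1], targets[, 2])
  stage1 <- train_stage1(features, labels, cost = stage1_cost,
                         gamma = stage1_gamma)
  p <- obstruction_probability(stage1, features)
  fused <- fuse_features(features, p)
  stage2 <- train_stage2(fused, targets, params = stage2_params, seed = seed)
  structure(list(stage1 = stage1, stage2 = stage2), class = "medical_model")
}

#' Predict spirometry from medical features
#'
#' Pipeline composition: decision score, sigmoid probability, fusion,
#' boosted regression. Outputs are floored at 0.1 L.
#'
#' @param model A [train_medical()] model.
#' @param features Feature table or matrix.
#' @return Matrix n x 2 with columns `FEV1`, `FVC` (liters).
#' @export
predict_medical <- function(model, features) {
  if (!inherits(model, "medical_model") ||
      !inherits(model$stage2, "stage2_model")) {
    abort_state("predict_medical requires a fitted medical_model")
  }
  p <- obstruction_probability(model$stage1, features)
  fused <- fuse_features(features, p)
  dm <- xgboost::xgb.DMatrix(fused)
  out <- cbind(
    FEV1 = stats::predict(model$stage2$boosters$fev1, dm),
    FVC = stats::predict(model$stage2$boosters$fvc, dm)
  )
  pmax(out, 0.1)
}
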