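# K-nearest-neighbor error correction.
#
# The two first-stage structures each emit (FEV1, FVC), giving every
# subject a four-dimensional prediction vector (FEV1_med, FVC_med,
# FEV1_seq, FVC_seq). The corrector stores the training subjects' vectors
# together with their measured spirometry; a test subject's final estimate
# is the plain mean of the measured (FEV1, FVC) of its K nearest training
# vectors under Euclidean distance. All four coordinates share units of
# liters, so no standardization is applied before distance computation.

#' Minkowski distance
#'
#' `(sum |x_i - y_i|^p)^(1/p)`; `p = 2` (Euclidean) is used by the
#' correction stage.
#'
#' @param x,y Numeric vectors of equal length.
#' @param p Order, >= 1.
#' @return The distance.
#' @export
minkowski_distance <- function(x, y, p = 2) {
  if (length(x) != length(y)) abort_invalid("x and y must have equal length")
  if (p < 1) abort_invalid("p must be >= 1")
  sum(abs(x - y)^p)^(1 / p)
}

#' Fit the KNN correction model
#'
#' Storage-only "fit": keeps the training prediction quads and the paired
#' measured spirometry.
#'
#' @param quads Numeric matrix, n x 4: columns `FEV1_med`, `FVC_med`,
#'   `FEV1_seq`, `FVC_seq` (liters).
#' @param truths Numeric matrix, n x 2: measured `FEV1`, `FVC` (liters).
#' @param k Neighbor count, `1 <= k <= n` (default 5).
#' @return Object of class `knn_correction`.
#' @export
fit_correction <- function(quads, truths, k = 5) {
  quads <- as.matrix(quads)
  truths <- as.matrix(truths)
  if (ncol(quads) != 4) abort_invalid("quads must have 4 columns")
  if (ncol(truths) != 2) abort_invalid("truths must have 2 columns")
  if (nrow(quads) != nrow(truths)) {
    abort_invalid("quads and truths must have the same number of rows")
  }
  if (!all(is.finite(quads)) || !all(is.finite(truths))) {
    abort_invalid("quads and truths must be finite")
  }
  if (k < 1 || k > nrow(quads)) {
    abort_invalid(sprintf("k (%d) must be between 1 and the training size (%d)",
                          k, nrow(quads)))
  }
  structure(list(quads = quads, truths = truths, k = as.integer(k)),
            class = "knn_correction")
}

#' Corrected prediction for test quads
#'
#' For each test vector, Euclidean distances to all stored training
#' vectors are computed, the K smallest are selected (ties broken by
#' training-set index order), and the output is the arithmetic mean of
#' those neighbors' measured (FEV1, FVC).
#'
#' @param model A [fit_correction()] model.
#' @param quads Numeric matrix (m x 4) or a single length-4 vector.
#' @return Numeric matrix m x 2 with columns `FEV1`, `FVC`.
#' @export
predict_corrected <- function(model, quads) {
  stopifnot(inherits(model, "knn_correction"))
  if (is.null(dim(quads))) quads <- matrix(quads, nrow = 1)
  quads <- as.matrix(quads)
  if (ncol(quads) != 4) abort_invalid("test quads must have 4 columns")
  out <- matrix(NA_real_, nrow(quads), 2,
                dimnames = list(NULL, c("FEV1", "FVC")))
  for (i in seq_len(nrow(quads))) {
    d2 <- rowSums((model$quads - matrix(quads[i, ], nrow(model$quads), 4,
                                        byrow = TRUE))^2)
    nb <- order(d2)[seq_len(model$k)] # order() is stable: index-order ties
    out[i, ] <- colMeans(model$truths[nb, , drop = FALSE])
  }
  out
}
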