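# Sequence feature regression: a small one-dimensional convolutional
# network mapping a fixed-length raw CO2 sequence to (FEV1, FVC).
#
# Architecture (three stacked blocks, then a linear head):
#   [Conv1D(k = 5, valid) -> ReLU -> MaxPool(5) -> Dropout] x 3
#   -> Flatten -> Dense(2), minimizing mean squared error.
# With the default input length of 2400 samples and 32/64/32 filters the
# per-block lengths are 2396 -> 479, 475 -> 95, 91 -> 18, giving a
# flattened width of 18 * 32 = 576 features.
#
# The production forward/backward passes live in compiled code
# (src/cnn.cpp: single-precision im2col + BLAS); this file owns the
# configuration, shape algebra, weight containers, the Adam training
# loop (exponentially decaying learning rate, global gradient-norm
# clipping), and an R reference implementation of the same network used
# by the tests as an independent oracle for the compiled path. At this
# model size (~22k parameters) a few-hundred-subject cohort trains in
# seconds.

#' Sequence network configuration
#'
#' @param input_length Input sequence length in samples (default 2400,
#'   i.e. 12 s at 200 Hz).
#' @param filters Filter counts of the three convolution blocks.
#' @param kernel Convolution kernel width (valid convolution, stride 1).
#' @param pool Max-pooling width (= stride).
#' @param dropout Dropout rate in [0, 1), applied after each pool during
#'   training only.
#' @param epochs Training epochs (default 100).
#' @param lr Initial Adam learning rate (default 3e-3; inputs are scaled
#'   to order 1 by [preprocess_sequence()]).
#' @param lr_decay Per-epoch exponential decay of the learning rate.
#' @param adam_beta1,adam_beta2 Moment decay rates of the Adam updates.
#' @param batch_size Mini-batch size.
#' @param val_fraction Fraction of training subjects held out for the
#'   per-epoch validation loss (0 disables).
#' @param grad_clip Global gradient-norm clip (stabilizer).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A list of class `network_config`.
#' @export
network_config <- function(input_length = 2400, filters = c(32, 64, 32),
                           kernel = 5, pool = 5, dropout = 0.2,
                           epochs = 100, lr = 3e-3, lr_decay = 0.97,
                           adam_beta1 = 0.9, adam_beta2 = 0.999,
                           batch_size = 32,
                           val_fraction = 0.1, grad_clip = 5, seed = 1) {
  if (kernel < 1) abort_invalid("kernel width must be >= 1")
  if (any(filters < 1)) abort_invalid("filter counts must be >= 1")
  if (dropout < 0 || dropout >= 1) abort_invalid("dropout must be in [0, 1)")
  if (lr <= 0 || lr_decay <= 0 || lr_decay > 1) {
    abort_invalid("lr must be > 0 and lr_decay in (0, 1]")
  }
  structure(list(input_length = as.integer(input_length), filters = filters,
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dropout = dropout, epochs = as.integer(epochs), lr = lr,
                 lr_decay = lr_decay,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, grad_clip = grad_clip,
                 seed = seed),
            class = "network_config")
}

# Length recurrence of one block: valid conv then pool.
block_lengths <- function(l, kernel, pool) {
  lc <- l - kernel + 1
  c(conv = lc, pool = lc %/% pool)
}

#' Build (initialize) the sequence network
#'
#' Validates the shape algebra (each block needs at least `kernel`
#' samples of input and a non-empty pooled output) and initializes
#' weights (He-scaled normal for convolutions, Glorot-scaled for the
#' dense head; biases zero).
#'
#' @param config A [network_config()].
#' @return Object of class `capno_cnn`: the config, the weight list, a
#'   per-layer shape table, and a `trained` flag.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  k <- config$kernel
  chans <- c(1, config$filters)
  l <- config$input_length
  shapes <- data.frame(layer = character(0), out_length = integer(0),
                       channels = integer(0), params = integer(0))
  set.seed(config$seed)
  layers <- list()
  for (b in seq_along(config$filters)) {
    if (l < k) {
      abort_invalid(sprintf(
        "input_length too short: block %d receives %d samples but the kernel needs %d",
        b, l, k))
    }
    len <- block_lengths(l, k, config$pool)
    if (len["pool"] < 1) {
      abort_invalid(sprintf("input_length too short: block %d pools to zero length", b))
    }
    cin <- chans[b]
    f <- chans[b + 1]
    w <- array(stats::rnorm(k * cin * f, 0, sqrt(2 / (k * cin))),
               dim = c(k, cin, f))
    layers[[paste0("conv", b)]] <- list(w = w, b = numeric(f))
    shapes <- rbind(
      shapes,
      data.frame(layer = paste0("C", b), out_length = len[["conv"]],
                 channels = f, params = k * cin * f + f),
      data.frame(layer = paste0("P", b), out_length = len[["pool"]],
                 channels = f, params = 0L),
      data.frame(layer = paste0("D", b), out_length = len[["pool"]],
                 channels = f, params = 0L)
    )
    l <- len[["pool"]]
  }
  flat <- l * chans[length(chans)]
  lim <- sqrt(6 / (flat + 2))
  layers$dense <- list(w = matrix(stats::runif(flat * 2, -lim, lim), flat, 2),
                       b = numeric(2))
  shapes <- rbind(
    shapes,
    data.frame(layer = "F1", out_length = flat, channels = 1L, params = 0L),
    data.frame(layer = "F2", out_length = 2L, channels = 1L,
               params = flat * 2 + 2)
  )
  rownames(shapes) <- NULL
  pooled <- shapes[grepl("^P", shapes$layer), ]
  structure(list(config = config, layers = layers, shapes = shapes,
                 flat_dim = flat,
                 mask_dim = sum(pooled$out_length * pooled$channels),
                 trained = FALSE),
            class = "capno_cnn")
}

#' @export
print.capno_cnn <- function(x, ...) {
  cat(sprintf("<capno_cnn> input %d, %s trainable parameters%s\n",
              x$config$input_length,
              format(sum(x$shapes$params), big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  print(x$shapes)
  invisible(x)
}

#' Per-layer trainable parameter counts
#'
#' Counted from the network's weight containers (convolution:
#' `kernel * in_channels * filters + filters`; dense: `in * out + out`;
#' pooling, dropout and flatten layers hold no parameters).
#'
#' @param network A [build_network()] result.
#' @return Data.frame with columns `layer`, `out_length`, `channels`,
#'   `params`.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "capno_cnn"))
  counts <- network$shapes
  # recount from the actual weight arrays as a self-check
  actual <- vapply(network$layers, function(l) length(l$w) + length(l$b),
                   numeric(1))
  stopifnot(sum(counts$params) == sum(actual))
  counts
}

#' Prepare a raw CO2 series for the network
#'
#' Trims the series to `input_length` samples starting at expiration
#' onset (the first sample where CO2 exceeds `onset_threshold` mmHg);
#' shorter series are right-padded with their final value. Values are
#' scaled by `scale` so a typical end-tidal pressure of ~40 mmHg maps to
#' order 1.
#'
#' @param co2 Raw CO2 series (mmHg), length >= 2.
#' @param input_length Target length (default 2400).
#' @param onset_threshold Onset detection level (mmHg).
#' @param scale Multiplicative scaling (default 1/40 per mmHg).
#' @return Numeric vector of exactly `input_length` scaled samples.
#' @export
preprocess_sequence <- function(co2, input_length = 2400,
                                onset_threshold = 2, scale = 1 / 40) {
  if (length(co2) < 2) abort_invalid("co2 series must have length >= 2")
  onset <- which(co2 > onset_threshold)[1]
  if (is.na(onset)) {
    abort(sprintf("no expiration onset: CO2 never exceeds %g mmHg",
                  onset_threshold), "capnopred_preprocessing_error")
  }
  x <- co2[onset:length(co2)]
  if (length(x) < input_length) {
    x <- c(x, rep(x[length(x)], input_length - length(x)))
  }
  x[seq_len(input_length)] * scale
}

#' Preprocess many series into a network input matrix
#'
#' @param sequences A matrix (one series per row) or list of series.
#' @param ... Passed to [preprocess_sequence()].
#' @return Matrix with one preprocessed row per series.
#' @export
preprocess_batch <- function(sequences, ...) {
  if (is.matrix(sequences)) {
    sequences <- lapply(seq_len(nrow(sequences)), function(i) sequences[i, ])
  }
  do.call(rbind, lapply(sequences, preprocess_sequence, ...))
}

## ---- internal reference forward / backward (R implementation) ----
#
# The production forward/backward lives in compiled code (src/cnn.cpp,
# reached through .cnn_batch_cpp). The R implementation below computes
# the same network and serves as the independent reference the test
# suite checks the compiled path against (at dropout 0; the two paths
# draw dropout masks in different element orders). Activations live as
# (batch, length, channels) arrays; each convolution is a single matrix
# product against an im2col matrix whose last column of ones fuses the
# bias add. Max-pooling runs before the (commuting) ReLU. The flatten
# order is channel fastest, then pooled position, matching the compiled
# layout.

# Flatten w (k, Cin, F) to ((k*Cin) x F) with channel fastest per offset.
flatten_kernel <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(2, 1, 3)), d[1] * d[2], d[3])
}

# x: (B, L, Cin) -> list(z = (B, Lout, F) pre-activation, ic = im2col).
conv1d_forward <- function(x, w, bias) {
  dm <- dim(x)
  bsz <- dm[1]; l <- dm[2]; cin <- dm[3]
  k <- dim(w)[1]; f <- dim(w)[3]
  lout <- l - k + 1
  ic <- matrix(1, bsz * lout, k * cin + 1)
  for (kk in seq_len(k)) {
    xs <- x[, kk:(kk + lout - 1), , drop = FALSE]
    dim(xs) <- c(bsz * lout, cin)
    ic[, ((kk - 1) * cin + 1):(kk * cin)] <- xs
  }
  z <- ic %*% rbind(flatten_kernel(w), bias)
  dim(z) <- c(bsz, lout, f)
  list(z = z, ic = ic)
}

# Backward through one convolution. dz: (B, Lout, F) gradient at the
# pre-activation. Returns dw/db plus (optionally) dx for the chain.
conv1d_backward <- function(ic, w, dz, need_dx = TRUE) {
  k <- dim(w)[1]; cin <- dim(w)[2]; f <- dim(w)[3]
  dm <- dim(dz)
  bsz <- dm[1]; lout <- dm[2]
  dim(dz) <- c(bsz * lout, f)
  dwm <- crossprod(ic, dz)
  dw <- aperm(array(dwm[seq_len(k * cin), ], c(cin, k, f)), c(2, 1, 3))
  db <- dwm[k * cin + 1, ]
  dx <- NULL
  if (need_dx) {
    dic <- dz %*% t(flatten_kernel(w))
    l <- lout + k - 1
    dx <- array(0, c(bsz, l, cin))
    for (kk in seq_len(k)) {
      sl <- dic[, ((kk - 1) * cin + 1):(kk * cin)]
      dim(sl) <- c(bsz, lout, cin)
      dx[, kk:(kk + lout - 1), ] <- dx[, kk:(kk + lout - 1), , drop = FALSE] + sl
    }
  }
  list(dw = dw, db = db, dx = dx)
}

# Max-pool (width = stride = p) then ReLU. Trailing samples beyond
# p * floor(L/p) are dropped. Returns the activated pooled tensor plus
# the caches needed for backprop (argmax, pre-ReLU maxima).
pool_relu_forward <- function(z, p) {
  dm <- dim(z)
  bsz <- dm[1]; l <- dm[2]; ch <- dm[3]
  lp <- l %/% p
  m <- matrix(0, bsz * lp * ch, p)
  for (j in seq_len(p)) {
    xs <- z[, seq(j, p * lp, by = p), , drop = FALSE]
    m[, j] <- xs
  }
  idx <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_along(idx), idx)]
  out <- pmax(mx, 0)
  dim(out) <- c(bsz, lp, ch)
  list(out = out, idx = idx, mx = mx, in_len = l)
}

pool_relu_backward <- function(pool, dout, p) {
  dm <- dim(dout)
  bsz <- dm[1]; lp <- dm[2]; ch <- dm[3]
  dmx <- as.vector(dout) * (pool$mx > 0)
  r0 <- seq_along(dmx) - 1
  b <- r0 %% bsz
  lpos <- (r0 %/% bsz) %% lp          # pooled position - 1
  cc <- r0 %/% (bsz * lp)             # channel - 1
  l <- lpos * p + pool$idx - 1        # conv position - 1
  dz <- numeric(bsz * pool$in_len * ch)
  dz[b + bsz * l + bsz * pool$in_len * cc + 1] <- dmx
  dim(dz) <- c(bsz, pool$in_len, ch)
  dz
}

# Full forward pass. training = TRUE applies (inverted) dropout and
# returns the caches needed for backprop; inference is dropout-free and
# deterministic.
cnn_forward_ref <- function(net, x, training = FALSE) {
  cfg <- net$config
  bsz <- nrow(x)
  a <- x
  dim(a) <- c(bsz, ncol(x), 1)
  caches <- list()
  for (b in seq_along(cfg$filters)) {
    ly <- net$layers[[paste0("conv", b)]]
    cv <- conv1d_forward(a, ly$w, ly$b)
    pool <- pool_relu_forward(cv$z, cfg$pool)
    out <- pool$out
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- array((stats::runif(length(out)) >= cfg$dropout) /
                      (1 - cfg$dropout), dim(out))
      out <- out * mask
    }
    caches[[b]] <- list(ic = if (training) cv$ic, pool = pool, mask = mask)
    a <- out
  }
  flat <- aperm(a, c(1, 3, 2)) # channel fastest, as in the compiled core
  dim(flat) <- c(bsz, net$flat_dim)
  pred <- flat %*% net$layers$dense$w +
    rep(net$layers$dense$b, each = bsz)
  list(pred = pred, flat = flat, caches = caches)
}

# Backward pass from d(pred); returns gradients in the layer structure.
cnn_backward_ref <- function(net, fw, dpred) {
  cfg <- net$config
  bsz <- nrow(dpred)
  grads <- list()
  grads$dense <- list(w = crossprod(fw$flat, dpred), b = colSums(dpred))
  da <- dpred %*% t(net$layers$dense$w)
  last <- fw$caches[[length(cfg$filters)]]
  dm <- dim(last$pool$out)
  dim(da) <- c(bsz, dm[3], dm[2]) # undo the channel-fastest flatten
  da <- aperm(da, c(1, 3, 2))
  for (b in rev(seq_along(cfg$filters))) {
    cache <- fw$caches[[b]]
    if (!is.null(cache$mask)) da <- da * cache$mask
    dz <- pool_relu_backward(cache$pool, da, cfg$pool)
    bk <- conv1d_backward(cache$ic, net$layers[[paste0("conv", b)]]$w, dz,
                          need_dx = b > 1)
    grads[[paste0("conv", b)]] <- list(w = bk$dw, b = bk$db)
    if (b > 1) {
      da <- bk$dx
    }
  }
  grads
}

#' Train the sequence network
#'
#' Mini-batch Adam on the mean squared error of the two outputs, with a
#' per-epoch exponentially decaying learning rate and global
#' gradient-norm clipping. The output bias is initialized to the
#' training-target means so the network starts from the constant-mean
#' predictor. An optional validation split (taken from the front of a
#' seeded permutation) tracks generalization per epoch.
#'
#' @param network A [build_network()] result.
#' @param x Input matrix, one preprocessed sequence per row (use
#'   [preprocess_batch()]).
#' @param y Target matrix, n x 2: FEV1, FVC in liters.
#' @return The trained network, with a `history` data.frame
#'   (`epoch`, `train_loss`, `val_loss`, `lr`) attached.
#' @export
train_network <- function(network, x, y) {
  stopifnot(inherits(network, "capno_cnn"))
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != network$config$input_length) {
    abort_invalid(sprintf("input has %d columns; the network expects %d",
                          ncol(x), network$config$input_length))
  }
  if (nrow(x) < 2) abort_invalid("at least 2 training subjects required")
  if (nrow(x) != nrow(y) || ncol(y) != 2) {
    abort_invalid("y must be an n x 2 matrix matching x")
  }
  cfg <- network$config
  set.seed(cfg$seed)
  n <- nrow(x)
  n_val <- floor(cfg$val_fraction * n)
  perm <- sample.int(n)
  val_idx <- if (n_val >= 1) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  network$layers$dense$b <- colMeans(y[tr_idx, , drop = FALSE])
  adam_m <- lapply(network$layers, function(ly) {
    list(w = ly$w * 0, b = ly$b * 0)
  })
  adam_v <- adam_m
  adam_t <- 0
  b1 <- cfg$adam_beta1
  b2 <- cfg$adam_beta2
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_loss = NA_real_, lr = NA_real_)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * cfg$lr_decay^(epoch - 1)
    ord <- tr_idx[sample.int(length(tr_idx))]
    batch_starts <- seq(1, length(ord), by = cfg$batch_size)
    tot_loss <- 0
    for (s in batch_starts) {
      rows <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
      unifs <- if (cfg$dropout > 0) {
        stats::runif(length(rows) * network$mask_dim)
      }
      step <- .cnn_batch_cpp(x[rows, , drop = FALSE],
                             y[rows, , drop = FALSE],
                             network$layers, cfg$pool, cfg$dropout,
                             training = TRUE, grads_wanted = TRUE,
                             dropout_unifs = unifs)
      if (!is.finite(step$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
              "capnopred_divergence")
      }
      tot_loss <- tot_loss + step$loss * length(rows)
      grads <- step$grads
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g$w^2) + sum(g$b^2),
                               numeric(1))))
      scl <- if (gnorm > cfg$grad_clip) cfg$grad_clip / gnorm else 1
      adam_t <- adam_t + 1
      corr1 <- 1 - b1^adam_t
      corr2 <- 1 - b2^adam_t
      for (nm in names(grads)) {
        for (slot in c("w", "b")) {
          g <- scl * grads[[nm]][[slot]]
          adam_m[[nm]][[slot]] <- b1 * adam_m[[nm]][[slot]] + (1 - b1) * g
          adam_v[[nm]][[slot]] <- b2 * adam_v[[nm]][[slot]] + (1 - b2) * g^2
          network$layers[[nm]][[slot]] <- network$layers[[nm]][[slot]] -
            lr * (adam_m[[nm]][[slot]] / corr1) /
              (sqrt(adam_v[[nm]][[slot]] / corr2) + 1e-8)
        }
      }
    }
    history$train_loss[epoch] <- tot_loss / length(ord)
    history$lr[epoch] <- lr
    if (length(val_idx)) {
      vstep <- .cnn_batch_cpp(x[val_idx, , drop = FALSE],
                              y[val_idx, , drop = FALSE],
                              network$layers, cfg$pool, cfg$dropout,
                              training = FALSE, grads_wanted = FALSE)
      history$val_loss[epoch] <- vstep$loss
    }
  }
  network$trained <- TRUE
  network$history <- history
  network
}

#' Predict spirometry from preprocessed sequences
#'
#' Dropout-free deterministic inference; outputs are floored at 0.1 L.
#'
#' @param network A trained [capno_cnn] network.
#' @param x Input matrix, one preprocessed sequence per row.
#' @return Matrix n x 2 with columns `FEV1`, `FVC` (liters).
#' @export
predict_sequence <- function(network, x) {
  stopifnot(inherits(network, "capno_cnn"))
  x <- as.matrix(x)
  if (ncol(x) != network$config$input_length) {
    abort_invalid(sprintf("input has %d columns; the network expects %d",
                          ncol(x), network$config$input_length))
  }
  pred <- .cnn_batch_cpp(x, NULL, network$layers, network$config$pool,
                         network$config$dropout, training = FALSE,
                         grads_wanted = FALSE)$pred
  pred <- pmax(pred, 0.1)
  colnames(pred) <- c("FEV1", "FVC")
  pred
}
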