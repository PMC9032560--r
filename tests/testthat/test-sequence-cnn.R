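# One-dimensional convolutional sequence regressor.

test_that("default architecture reproduces the published shape table", {
  net <- build_network(network_config())
  sh <- count_parameters(net)
  get <- function(layer, col) sh[sh$layer == layer, col]
  expect_equal(get("C1", "out_length"), 2396)
  expect_equal(get("C1", "params"), 192)
  expect_equal(get("P1", "out_length"), 479)
  expect_equal(get("C2", "out_length"), 475)
  expect_equal(get("C2", "params"), 10304)
  expect_equal(get("P2", "out_length"), 95)
  expect_equal(get("C3", "out_length"), 91)
  expect_equal(get("C3", "params"), 10272)
  expect_equal(get("P3", "out_length"), 18)
  expect_equal(get("F1", "out_length"), 576)
  expect_equal(get("F2", "params"), 1154)
  expect_equal(sum(sh$params[sh$layer %in% c("P1", "P2", "P3",
                                             "D1", "D2", "D3", "F1")]), 0)
})

test_that("shape algebra matches the length recurrence for random configs", {
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:7, 1)
    p <- sample(2:5, 1)
    filters <- sample(2:12, 3, replace = TRUE)
    len <- sample(300:3000, 1)
    # oracle: one-line recurrence L <- floor((L - k + 1) / p)
    l <- len
    ok <- TRUE
    for (b in 1:3) {
      if (l < k) { ok <- FALSE; break }
      l <- (l - k + 1) %/% p
      if (l < 1) { ok <- FALSE; break }
    }
    cfg <- network_config(input_length = len, filters = filters,
                          kernel = k, pool = p)
    if (!ok) {
      expect_error(build_network(cfg), class = "capnopred_invalid_argument")
    } else {
      net <- build_network(cfg)
      sh <- count_parameters(net)
      expect_equal(sh[sh$layer == "F1", "out_length"], l * filters[3])
      # parameter formula vs the actual weight containers
      expect_equal(sh[sh$layer == "C2", "params"],
                   length(net$layers$conv2$w) + length(net$layers$conv2$b))
    }
  }
  expect_error(build_network(network_config(input_length = 10)),
               class = "capnopred_invalid_argument")
})

test_that("sequence preprocessing trims at onset, pads and rescales", {
  out <- preprocess_sequence(rep(10, 5000))
  expect_length(out, 2400)
  expect_equal(unique(out), 0.25)
  # onset detection skips the sub-threshold head
  x <- c(rep(0, 100), seq(3, 50, length.out = 4100))
  out2 <- preprocess_sequence(x)
  expect_equal(out2[1], 3 / 40)
  # short series: right-padded with the final value
  x3 <- rep(c(5, 30), each = 1000)
  out3 <- preprocess_sequence(x3)
  expect_equal(unique(out3[2001:2400]), 30 / 40)
  expect_error(preprocess_sequence(rep(0, 5000)),
               class = "capnopred_preprocessing_error")
})

test_that("compiled forward/backward agrees with the R reference", {
  cfg <- network_config(input_length = 400, filters = c(4, 6, 4),
                        dropout = 0, seed = 7)
  net <- build_network(cfg)
  set.seed(3)
  x <- matrix(rnorm(6 * 400), 6)
  y <- matrix(rnorm(12) + 3, 6)
  fw <- capnopred:::cnn_forward_ref(net, x, training = TRUE)
  st <- capnopred:::.cnn_batch_cpp(x, y, net$layers, cfg$pool, 0, TRUE, TRUE)
  expect_equal(unname(st$pred), unname(fw$pred), tolerance = 1e-4)
  gr <- capnopred:::cnn_backward_ref(net, fw,
                                     2 * (fw$pred - y) / length(fw$pred))
  for (nm in names(gr)) {
    expect_equal(st$grads[[nm]]$w, gr[[nm]]$w, tolerance = 1e-4,
                 label = paste("compiled grad", nm))
    expect_equal(as.numeric(st$grads[[nm]]$b), as.numeric(gr[[nm]]$b),
                 tolerance = 1e-4, label = paste("compiled bias grad", nm))
  }
})

test_that("R reference gradients match finite differences on a tiny net", {
  cfg <- network_config(input_length = 40, filters = c(2, 3, 2), kernel = 3,
                        pool = 2, dropout = 0, seed = 4)
  net <- build_network(cfg)
  set.seed(9)
  x <- matrix(rnorm(3 * 40), 3)
  y <- matrix(rnorm(6), 3)
  fw <- capnopred:::cnn_forward_ref(net, x, training = TRUE)
  grads <- capnopred:::cnn_backward_ref(net, fw,
                                        2 * (fw$pred - y) / length(fw$pred))
  lossfn <- function(n2) {
    mean((capnopred:::cnn_forward_ref(n2, x)$pred - y)^2)
  }
  eps <- 1e-6
  for (nm in names(net$layers)) {
    arr <- net$layers[[nm]]$w
    for (i in seq_len(min(length(arr), 10))) {
      n2 <- net
      n2$layers[[nm]]$w[i] <- arr[i] + eps
      up <- lossfn(n2)
      n2$layers[[nm]]$w[i] <- arr[i] - eps
      dn <- lossfn(n2)
      expect_equal(grads[[nm]]$w[i], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible, tracked, and guards its inputs", {
  set.seed(20)
  n <- 40
  x <- matrix(runif(n * 600), n)
  y <- cbind(2 + 2 * rowMeans(x[, 1:50]), 3 + 3 * rowMeans(x[, 1:50]))
  cfg <- network_config(input_length = 600, filters = c(4, 8, 4),
                        epochs = 8, seed = 5)
  n1 <- train_network(build_network(cfg), x, y)
  n2 <- train_network(build_network(cfg), x, y)
  expect_identical(n1$history, n2$history)
  expect_true(n1$trained)
  expect_lte(tail(n1$history$train_loss, 1), n1$history$train_loss[1])
  expect_error(train_network(build_network(cfg), x[, 1:100], y),
               class = "capnopred_invalid_argument")
})

test_that("zero-variance targets are fit to near-zero loss", {
  set.seed(6)
  x <- matrix(runif(24 * 600), 24)
  y <- cbind(rep(2.5, 24), rep(3.5, 24))
  cfg <- network_config(input_length = 600, filters = c(4, 8, 4),
                        epochs = 150, dropout = 0, lr = 0.01, lr_decay = 1,
                        seed = 3)
  net <- train_network(build_network(cfg), x, y)
  expect_lt(tail(net$history$train_loss, 1), 1e-3)
})

test_that("training loss trends downward on a small synthetic cohort", {
  co <- cached_cohort(50, seed = 19)
  xs <- preprocess_batch(cohort_sequences(co))
  f <- cohort_features(co)
  net <- build_network(network_config(epochs = 30, seed = 9))
  net <- train_network(net, xs, as.matrix(f[c("fev1_l", "fvc_l")]))
  h <- net$history$train_loss
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  expect_true(all(is.finite(h)))
})

test_that("the sequence structure generalizes beyond the constant predictor", {
  co <- cached_cohort(300, seed = 42)
  xs <- preprocess_batch(cohort_sequences(co))
  f <- cohort_features(co)
  y <- as.matrix(f[c("fev1_l", "fvc_l")])
  tr <- 1:240
  te <- 241:300
  net <- build_network(network_config(epochs = 60, seed = 11))
  net <- train_network(net, xs[tr, ], y[tr, ])
  p <- predict_sequence(net, xs[te, ])
  # held-out R2 strictly positive: the raw CO2 sequence carries real
  # spirometric signal through the network
  expect_gt(rmse_r2(p[, 2], y[te, 2])$r2, 0)
})

test_that("inference is deterministic, shaped and floored", {
  cfg <- network_config(input_length = 600, filters = c(4, 8, 4), seed = 2)
  net <- build_network(cfg)
  x <- matrix(runif(8 * 600), 8)
  p1 <- predict_sequence(net, x)
  p2 <- predict_sequence(net, x)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(8, 2))
  expect_equal(colnames(p1), c("FEV1", "FVC"))
  expect_true(all(p1 >= 0.1))
  # duplicate rows yield identical predictions
  pd <- predict_sequence(net, x[c(1, 1), ])
  expect_equal(pd[1, ], pd[2, ])
  expect_error(predict_sequence(net, x[, 1:99]),
               class = "capnopred_invalid_argument")
})
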