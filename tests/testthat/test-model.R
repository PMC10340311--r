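test_that("build_model enforces the 1200 -> 300 time-length ledger", {
  expect_error(build_model(model_config(input_len = 1000L)), "strides")
  m <- build_model(model_config_reduced(), seed = 1)
  expect_s3_class(m, "sdb_model")
  expect_equal(m$config$output_len, 300L)
  # tiny variant for fast shape checks
  mt <- build_model(model_config(gru_width = 3, dense_width = 4,
                                 input_len = 8L, output_len = 2L), seed = 1)
  expect_equal(ncol(mt$params$dense1$W), 4L)
})

test_that("forward pass maps (B, 1200, 2) to (B, 300) probabilities", {
  m <- build_model(model_config_reduced(), seed = 2)
  X <- array(rnorm(4 * 2 * 1200), c(4, 2, 1200))
  fw <- sdbreath:::.model_forward(m, X, train = FALSE)
  expect_equal(dim(fw$probs), c(4L, 300L))
  expect_true(all(fw$probs > 0 & fw$probs < 1))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- model_config(gru_width = 3, dense_width = 4, dropout = 0,
                      l2_kernel = 0, input_len = 8L, output_len = 2L)
  m <- build_model(cfg, seed = 9)
  B <- 2
  X <- array(rnorm(B * 2 * 8), c(B, 2, 8))
  Y <- matrix(rbinom(B * 2, 1, 0.5), B, 2)
  W <- matrix(make_weights(Y), B, 2)
  loss_of <- function(model) {
    fw <- sdbreath:::.model_forward(model, X, train = TRUE)
    sdbreath:::.wbce_loss(fw$probs, Y, W)$loss
  }
  fw <- sdbreath:::.model_forward(m, X, train = TRUE)
  ls <- sdbreath:::.wbce_loss(fw$probs, Y, W)
  grads <- sdbreath:::.model_backward(m, fw$caches, ls$dlogit)
  eps <- 1e-6
  for (ln in names(m$params)) {
    for (pn in names(m$params[[ln]])) {
      g <- grads[[ln]][[pn]]
      w <- m$params[[ln]][[pn]]
      for (k in sample(length(w), min(3, length(w)))) {
        mp <- m; mp$params[[ln]][[pn]][k] <- w[k] + eps
        mm <- m; mm$params[[ln]][[pn]][k] <- w[k] - eps
        num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        ana <- as.numeric(g)[k]
        expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-4,
                  label = sprintf("gradient %s$%s[%d]", ln, pn, k))
      }
    }
  }
})

test_that("early stopping fires at best-epoch + patience", {
  # strictly increasing from epoch 1, patience 2 -> stop at epoch 3
  expect_equal(early_stop_epoch(c(1, 2, 3, 4, 5), patience = 2), 3)
  expect_equal(early_stop_epoch(c(3, 2, 1), patience = 2), 3)     # no trigger
  expect_equal(early_stop_epoch(c(5, 4, 6, 7, 8, 9), patience = 3), 5)
})

test_that("training reduces loss on a separable toy problem", {
  set.seed(3)
  # channel-2 amplitude drop marks the event seconds
  make_seg <- function() {
    target <- integer(300)
    ev_start <- sample(40:200, 1)
    target[ev_start:(ev_start + 39)] <- 1L
    amp <- rep(1, 1200)
    amp[(ev_start * 4):(ev_start * 4 + 159)] <- 0.1
    ch2 <- amp * sin(2 * pi * 0.25 * seq_len(1200) / 4)
    ch1 <- 1 + 0.05 * rnorm(1200)
    list(inputs = cbind(soft_minmax(ch1), soft_minmax(ch2)),
         target = target, weights = make_weights(target), start_s = 0)
  }
  segs <- replicate(24, make_seg(), simplify = FALSE)
  m <- build_model(model_config_reduced(), seed = 4)
  tr <- train_model(m, segs[1:18], segs[19:24],
                    train_config(batch_size = 18, patience = 9,
                                 max_epochs = 10, seed = 5))
  expect_lt(tail(tr$history$train_loss, 1), 0.5 * tr$history$train_loss[1])
  expect_true(all(is.finite(tr$history$val_loss)))
})

test_that("inference is deterministic and batching-invariant", {
  m <- build_model(model_config_reduced(), seed = 6)
  segs <- lapply(1:5, function(i) {
    target <- integer(300)
    list(inputs = matrix(rnorm(2400), 1200, 2), target = target,
         weights = make_weights(target), start_s = 0)
  })
  p1 <- predict_segments(m, segs)
  p2 <- predict_segments(m, segs)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(5L, 300L))
  p_single <- predict_segments(m, segs[3])
  expect_equal(p_single[1, ], p1[3, ], tolerance = 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(10)
  segs <- lapply(1:8, function(i) {
    target <- integer(300); target[100:150] <- 1L
    list(inputs = matrix(rnorm(2400), 1200, 2), target = target,
         weights = make_weights(target), start_s = 0)
  })
  run <- function() {
    m <- build_model(model_config_reduced(), seed = 7)
    train_model(m, segs[1:6], segs[7:8],
                train_config(batch_size = 6, patience = 2, max_epochs = 3,
                             seed = 8))$history
  }
  expect_identical(run(), run())
})
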