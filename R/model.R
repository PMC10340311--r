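#' Model configuration for the bidirectional-GRU sequence labeler
#'
#' Architecture (per the recurrent sequence-labeling design this package
#' implements): two feature blocks, each `[BiGRU, BiGRU, batch-norm,
#' max-pool(stride 2, time axis), ReLU, dropout]`, followed by a dense-ReLU
#' layer and a dense-sigmoid output. Two stride-2 pools map 1200 input
#' samples (4 Hz x 300 s) to 300 outputs (1 Hz).
#'
#' @param gru_width hidden units per GRU direction (default 128).
#' @param dense_width units of the penultimate dense layer (default 512).
#' @param dropout dropout rate (default 0.5).
#' @param l2_kernel L2 kernel-regularization coefficient applied to all
#'   recurrent and dense kernels (default 1e-5).
#' @param input_len input timesteps per segment (default 1200).
#' @param n_channels input channels (default 2).
#' @param output_len required output timesteps (default 300); building fails
#'   if the pooling strides cannot produce it.
#' @return list of class `model_config`.
#' @export
model_config <- function(gru_width = 128L, dense_width = 512L, dropout = 0.5,
                         l2_kernel = 1e-5, input_len = 1200L, n_channels = 2L,
                         output_len = 300L) {
  cfg <- list(gru_width = as.integer(gru_width),
              dense_width = as.integer(dense_width), dropout = dropout,
              l2_kernel = l2_kernel, input_len = as.integer(input_len),
              n_channels = as.integer(n_channels),
              output_len = as.integer(output_len))
  class(cfg) <- "model_config"
  cfg
}

#' Reduced-scale model preset for desk-scale runs
#' @param ... overrides passed to [model_config()].
#' @export
model_config_reduced <- function(...) {
  model_config(gru_width = 16L, dense_width = 64L, ...)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay decoupled weight decay on kernels (default 0.0001).
#' @param batch_size minibatch size (default 128).
#' @param patience early-stopping patience in epochs on validation loss
#'   (default 20).
#' @param max_epochs maximum training epochs.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.0001,
                         batch_size = 128L, patience = 20L, max_epochs = 100L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            patience >= 1, patience < max_epochs)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

# --- array helpers ---------------------------------------------------------
# Activations are arrays (B, F, T); dense/batch-norm work on (B*T, F).

.cube_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
}

.mat_to_cube <- function(m, B, T) {
  aperm(array(m, c(B, T, ncol(m))), c(1, 3, 2))
}

.flip_time <- function(x) x[, , rev(seq_len(dim(x)[3])), drop = FALSE]

# --- initialization --------------------------------------------------------
# Variance-scaling initialization: Glorot-uniform for GRU kernels and the
# output layer, He-normal for the ReLU dense layer.

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.init_gru <- function(n_in, H) {
  list(Wx = .glorot(n_in, 3 * H) , Wh = .glorot(H, 3 * H), b = rep(0, 3 * H))
}

.init_bn <- function(Fdim) {
  list(gamma = rep(1, Fdim), beta = rep(0, Fdim))
}

#' Build the sequence-labeling model
#'
#' Initializes all parameters with variance-scaling schemes and verifies the
#' time-length ledger: `input_len -> /2 -> /2 -> output_len`.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for initialization.
#' @return list of class `sdb_model` with `params`, `bn_state`, `config`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  if (config$input_len %% 4L != 0L || config$input_len %/% 4L != config$output_len) {
    stop(sprintf("build_model: strides 2x2 map %d -> %d timesteps, not %d",
                 config$input_len, config$input_len %/% 4L, config$output_len))
  }
  set.seed(seed)
  H <- config$gru_width; C <- config$n_channels; D <- config$dense_width
  F2 <- 2L * H
  params <- list(
    gru1a_f = .init_gru(C, H),  gru1a_b = .init_gru(C, H),
    gru1b_f = .init_gru(F2, H), gru1b_b = .init_gru(F2, H),
    bn1 = .init_bn(F2),
    gru2a_f = .init_gru(F2, H), gru2a_b = .init_gru(F2, H),
    gru2b_f = .init_gru(F2, H), gru2b_b = .init_gru(F2, H),
    bn2 = .init_bn(F2),
    dense1 = list(W = matrix(stats::rnorm(F2 * D, 0, sqrt(2 / F2)), F2, D),
                  b = rep(0, D)),
    dense2 = list(W = .glorot(D, 1L), b = 0)
  )
  bn_state <- list(bn1 = list(mean = rep(0, F2), var = rep(1, F2)),
                   bn2 = list(mean = rep(0, F2), var = rep(1, F2)))
  structure(list(params = params, bn_state = bn_state, config = config),
            class = "sdb_model")
}

#' @export
print.sdb_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<sdb_model> BiGRU width %d, dense %d, %d parameters\n",
              x$config$gru_width, x$config$dense_width, np))
  invisible(x)
}

# --- layers ----------------------------------------------------------------

.bigru_forward <- function(x, pf, pb) {
  ff <- gru_seq_forward(x, pf$Wx, pf$Wh, pf$b)
  bb <- gru_seq_forward(.flip_time(x), pb$Wx, pb$Wh, pb$b)
  B <- dim(x)[1]; T <- dim(x)[3]; H <- ncol(pf$Wh) / 3
  out <- array(0, c(B, 2 * H, T))
  out[, seq_len(H), ] <- ff$H
  out[, H + seq_len(H), ] <- .flip_time(bb$H)
  list(out = out, cache = list(f = ff$cache, b = bb$cache, H = H))
}

.bigru_backward <- function(dout, cache, pf, pb) {
  H <- cache$H
  dHf <- dout[, seq_len(H), , drop = FALSE]
  dHb <- .flip_time(dout[, H + seq_len(H), , drop = FALSE])
  gf <- gru_seq_backward(cache$f, pf$Wx, pf$Wh, dHf)
  gb <- gru_seq_backward(cache$b, pb$Wx, pb$Wh, dHb)
  dx <- gf$dX + .flip_time(gb$dX)
  list(dx = dx,
       gf = list(Wx = gf$dWx, Wh = gf$dWh, b = as.numeric(gf$db)),
       gb = list(Wx = gb$dWx, Wh = gb$dWh, b = as.numeric(gb$db)))
}

.bn_forward <- function(x, p, state, train, momentum = 0.9, eps = 1e-5) {
  B <- dim(x)[1]; T <- dim(x)[3]
  m <- .cube_to_mat(x)
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean; v <- state$var
  }
  xhat <- sweep(sweep(m, 2, mu), 2, sqrt(v + eps), "/")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = .mat_to_cube(y, B, T), state = state,
       cache = list(xhat = xhat, v = v, eps = eps, B = B, T = T))
}

.bn_backward <- function(dout, cache, p) {
  dm <- .cube_to_mat(dout)
  xhat <- cache$xhat
  n <- nrow(dm)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  dxhat <- sweep(dm, 2, p$gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dm), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(dm), byrow = TRUE),
              2, inv_sd, "*")
  list(dx = .mat_to_cube(dx, cache$B, cache$T),
       grads = list(gamma = dgamma, beta = dbeta))
}

.pool_forward <- function(x) {
  T <- dim(x)[3]
  odd <- x[, , seq(1, T, by = 2), drop = FALSE]
  even <- x[, , seq(2, T, by = 2), drop = FALSE]
  mask <- odd >= even                      # ties -> earlier timestep
  list(out = pmax(odd, even), cache = mask)
}

.pool_backward <- function(dout, mask) {
  d <- dim(dout)
  dx <- array(0, c(d[1], d[2], 2 * d[3]))
  dx[, , seq(1, 2 * d[3], by = 2)] <- dout * mask
  dx[, , seq(2, 2 * d[3], by = 2)] <- dout * !mask
  dx
}

.dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  keep <- 1 - rate
  mask <- array(stats::runif(length(x)) < keep, dim(x)) / keep
  list(out = x * mask, cache = mask)
}

.dense_forward <- function(x, p, act = c("relu", "sigmoid")) {
  act <- match.arg(act)
  B <- dim(x)[1]; T <- dim(x)[3]
  m <- .cube_to_mat(x)
  z <- sweep(m %*% p$W, 2, p$b, "+")
  y <- if (act == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
  list(out = .mat_to_cube(y, B, T), cache = list(m = m, y = y, B = B, T = T))
}

.dense_backward <- function(dout_mat, cache, p, act) {
  dz <- if (act == "relu") dout_mat * (cache$y > 0) else dout_mat  # sigmoid grad folded into loss
  dW <- crossprod(cache$m, dz)
  db <- colSums(dz)
  dx <- tcrossprod(dz, p$W)
  list(dx = .mat_to_cube(dx, cache$B, cache$T), grads = list(W = dW, b = db))
}

# Full forward pass. x: array (B, n_channels, input_len).
.model_forward <- function(model, x, train = FALSE) {
  p <- model$params
  caches <- list()
  h <- .bigru_forward(x, p$gru1a_f, p$gru1a_b); caches$g1a <- h$cache
  h <- .bigru_forward(h$out, p$gru1b_f, p$gru1b_b); caches$g1b <- h$cache
  bn <- .bn_forward(h$out, p$bn1, model$bn_state$bn1, train)
  if (train) model$bn_state$bn1 <- bn$state
  caches$bn1 <- bn$cache
  pl <- .pool_forward(bn$out); caches$pool1 <- pl$cache
  rl <- pmax(pl$out, 0); caches$relu1 <- pl$out > 0
  dr <- .dropout_forward(rl, model$config$dropout, train); caches$drop1 <- dr$cache

  h <- .bigru_forward(dr$out, p$gru2a_f, p$gru2a_b); caches$g2a <- h$cache
  h <- .bigru_forward(h$out, p$gru2b_f, p$gru2b_b); caches$g2b <- h$cache
  bn <- .bn_forward(h$out, p$bn2, model$bn_state$bn2, train)
  if (train) model$bn_state$bn2 <- bn$state
  caches$bn2 <- bn$cache
  pl <- .pool_forward(bn$out); caches$pool2 <- pl$cache
  rl <- pmax(pl$out, 0); caches$relu2 <- pl$out > 0
  dr <- .dropout_forward(rl, model$config$dropout, train); caches$drop2 <- dr$cache

  d1 <- .dense_forward(dr$out, p$dense1, "relu"); caches$d1 <- d1$cache
  d2 <- .dense_forward(d1$out, p$dense2, "sigmoid"); caches$d2 <- d2$cache
  probs <- matrix(d2$out[, 1, ], dim(x)[1], model$config$output_len)
  list(probs = probs, caches = caches, model = model)
}

# Weighted binary cross-entropy; returns loss and d(loss)/d(logit) as the
# (B*T, 1) matrix expected by .dense_backward on the sigmoid output.
.wbce_loss <- function(probs, y, w) {
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  n <- length(p)
  loss <- sum(w * (-y * log(p) - (1 - y) * log(1 - p))) / n
  dlogit <- w * (p - y) / n
  list(loss = loss, dlogit = dlogit)
}

# Full backward pass; dlogit: (B, T_out) matrix of d(loss)/d(pre-sigmoid).
.model_backward <- function(model, caches, dlogit) {
  p <- model$params
  grads <- list()
  B <- nrow(dlogit)
  dl <- matrix(as.numeric(aperm(array(dlogit, c(B, 1, ncol(dlogit))), c(1, 3, 2))),
               B * ncol(dlogit), 1)
  bk <- .dense_backward(dl, caches$d2, p$dense2, "sigmoid")
  grads$dense2 <- bk$grads
  bk2 <- .dense_backward(.cube_to_mat(bk$dx), caches$d1, p$dense1, "relu")
  grads$dense1 <- bk2$grads
  dx <- bk2$dx
  if (!is.null(caches$drop2)) dx <- dx * caches$drop2
  dx <- dx * caches$relu2
  dx <- .pool_backward(dx, caches$pool2)
  bb <- .bn_backward(dx, caches$bn2, p$bn2); grads$bn2 <- bb$grads
  gg <- .bigru_backward(bb$dx, caches$g2b, p$gru2b_f, p$gru2b_b)
  grads$gru2b_f <- gg$gf; grads$gru2b_b <- gg$gb
  gg <- .bigru_backward(gg$dx, caches$g2a, p$gru2a_f, p$gru2a_b)
  grads$gru2a_f <- gg$gf; grads$gru2a_b <- gg$gb
  dx <- gg$dx
  if (!is.null(caches$drop1)) dx <- dx * caches$drop1
  dx <- dx * caches$relu1
  dx <- .pool_backward(dx, caches$pool1)
  bb <- .bn_backward(dx, caches$bn1, p$bn1); grads$bn1 <- bb$grads
  gg <- .bigru_backward(bb$dx, caches$g1b, p$gru1b_f, p$gru1b_b)
  grads$gru1b_f <- gg$gf; grads$gru1b_b <- gg$gb
  gg <- .bigru_backward(gg$dx, caches$g1a, p$gru1a_f, p$gru1a_b)
  grads$gru1a_f <- gg$gf; grads$gru1a_b <- gg$gb
  grads
}

# --- optimizer -------------------------------------------------------------
# Adam with decoupled weight decay and L2 kernel regularization. Kernels are
# the Wx/Wh/W matrices; biases and batch-norm parameters are exempt.

.adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0), how = "list")
}

.is_kernel <- function(name) name %in% c("Wx", "Wh", "W")

.adam_step <- function(params, grads, state, lr, wd, l2, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      g <- grads[[ln]][[pn]]
      if (is.null(g)) next
      w <- params[[ln]][[pn]]
      if (.is_kernel(pn) && l2 > 0) g <- g + 2 * l2 * w
      st <- state[[ln]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      w <- w - lr * mhat / (sqrt(vhat) + eps)
      if (.is_kernel(pn) && wd > 0) w <- w - lr * wd * w
      params[[ln]][[pn]] <- w
      state[[ln]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

#' Epoch at which early stopping halts training
#'
#' Training stops after the first epoch whose distance from the best
#' validation loss so far reaches `patience`.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience non-improvement tolerance in epochs.
#' @return the 1-based stopping epoch, or `length(val_losses)` if the rule
#'   never fires.
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- 1L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best]) best <- e
    if (e - best >= patience) return(e)
  }
  length(val_losses)
}

# Stack a list of segments into arrays: X (N, 2, L), Y (N, T), W (N, T).
.stack_segments <- function(segments) {
  N <- length(segments)
  L <- nrow(segments[[1]]$inputs)
  T_out <- length(segments[[1]]$target)
  X <- array(0, c(N, 2, L))
  Y <- matrix(0, N, T_out); W <- matrix(1, N, T_out)
  for (i in seq_len(N)) {
    X[i, 1, ] <- segments[[i]]$inputs[, 1]
    X[i, 2, ] <- segments[[i]]$inputs[, 2]
    Y[i, ] <- segments[[i]]$target
    W[i, ] <- segments[[i]]$weights
  }
  list(X = X, Y = Y, W = W)
}

.eval_loss <- function(model, data, batch_size) {
  n <- dim(data$X)[1]
  total <- 0; cnt <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- .model_forward(model, data$X[b, , , drop = FALSE], train = FALSE)
    ls <- .wbce_loss(fw$probs, data$Y[b, , drop = FALSE], data$W[b, , drop = FALSE])
    total <- total + ls$loss * length(b); cnt <- cnt + length(b)
  }
  total / cnt
}

#' Train the sequence labeler
#'
#' Optimizes per-timestep weighted binary cross-entropy with Adam (decoupled
#' weight decay, L2 kernel regularization), stopping early when validation
#' loss fails to improve for `patience` epochs and restoring the
#' best-validation weights.
#'
#' @param model an `sdb_model` from [build_model()].
#' @param train_segments,val_segments lists of segments
#'   (see [segment_record()]).
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the trained model with a `history` data.frame attached.
#' @export
train_model <- function(model, train_segments, val_segments,
                        tcfg = train_config(), verbose = FALSE) {
  stopifnot(length(train_segments) > 0, length(val_segments) > 0)
  set.seed(tcfg$seed)
  tr <- .stack_segments(train_segments)
  va <- .stack_segments(val_segments)
  n <- dim(tr$X)[1]
  adam <- .adam_init(model$params)
  best <- list(loss = Inf, params = model$params, bn = model$bn_state)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  step <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (b in split(idx, ceiling(seq_along(idx) / tcfg$batch_size))) {
      fw <- .model_forward(model, tr$X[b, , , drop = FALSE], train = TRUE)
      model <- fw$model
      ls <- .wbce_loss(fw$probs, tr$Y[b, , drop = FALSE], tr$W[b, , drop = FALSE])
      if (!is.finite(ls$loss)) {
        stop(sprintf("train_model: non-finite loss at epoch %d (divergence)", epoch))
      }
      grads <- .model_backward(model, fw$caches, ls$dlogit)
      step <- step + 1L
      upd <- .adam_step(model$params, grads, adam, tcfg$learning_rate,
                        tcfg$weight_decay, model$config$l2_kernel, step)
      model$params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + ls$loss * length(b); ep_n <- ep_n + length(b)
    }
    val_loss <- .eval_loss(model, va, tcfg$batch_size)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / ep_n, val_loss))
    }
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = model$params, bn = model$bn_state)
    }
    if (epoch - which.min(history$val_loss) >= tcfg$patience) break
  }
  model$params <- best$params
  model$bn_state <- best$bn
  model$history <- history
  model
}

#' Predict 1 Hz event probabilities for segments
#'
#' Inference is deterministic: dropout is disabled and batch-norm uses its
#' running statistics.
#'
#' @param model a trained `sdb_model`.
#' @param segments list of segments.
#' @param batch_size inference batch size.
#' @return matrix `length(segments) x output_len` of probabilities in (0,1).
#' @export
predict_segments <- function(model, segments, batch_size = 128L) {
  stopifnot(length(segments) > 0)
  if (nrow(segments[[1]]$inputs) != model$config$input_len) {
    stop("predict_segments: segment length does not match model input_len")
  }
  data <- .stack_segments(segments)
  n <- dim(data$X)[1]
  out <- matrix(0, n, model$config$output_len)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- .model_forward(model, data$X[b, , , drop = FALSE], train = FALSE)
    out[b, ] <- fw$probs
  }
  out
}
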