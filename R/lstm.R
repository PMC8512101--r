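#' LSTM classifier configuration
#'
#' Hyperparameters of the recurrent fatigue classifier. The network is the
#' five-layer-type stack LSTM -> fully connected -> ReLU -> dropout ->
#' softmax output; the recurrent cell follows the standard gate equations
#' (input, forget and output gates with a tanh candidate state).
#'
#' @param units LSTM hidden units (default 100).
#' @param fc_units Width of the fully connected ReLU layer (default 32).
#' @param epochs Maximum training epochs (default 50).
#' @param batch_size Minibatch size (default 70).
#' @param learning_rate Initial learning rate (default 0.001).
#' @param dropout Dropout probability on the ReLU layer during training,
#'   in \[0, 1) (default 0.5).
#' @param optimizer `"adam"` (default) or `"sgdm"` (stochastic gradient
#'   descent with momentum).
#' @param momentum SGDM momentum coefficient (default 0.9).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 10). `Inf` disables early stopping.
#' @param seed Integer RNG seed controlling initialisation, shuffling and
#'   dropout masks.
#' @param verbose If `TRUE`, log per-epoch losses via `message()`.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(units = 100L, fc_units = 32L, epochs = 50L,
                        batch_size = 70L, learning_rate = 0.001,
                        dropout = 0.5, optimizer = c("adam", "sgdm"),
                        momentum = 0.9, patience = 10L, seed = 1L,
                        verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(units >= 1, fc_units >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, dropout >= 0, dropout < 1)
  structure(
    list(units = as.integer(units), fc_units = as.integer(fc_units),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, dropout = dropout,
         optimizer = optimizer, momentum = momentum, patience = patience,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "lstm_config"
  )
}

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

lstm_init <- function(d, H, F2) {
  params <- list(
    Wx = glorot(d, 4L * H),
    Wh = glorot(H, 4L * H),
    b = numeric(4L * H),
    W1 = glorot(H, F2),
    b1 = numeric(F2),
    W2 = glorot(F2, 2L),
    b2 = numeric(2L)
  )
  params$b[(H + 1L):(2L * H)] <- 1  # forget-gate bias init
  params
}

sigm <- function(z) 1 / (1 + exp(-z))

# Forward pass over a batch. X is an array n_batch x T x d. Returns class
# probabilities and (when `training`) the caches needed for BPTT. Dropout
# masks are drawn from the current RNG stream.
lstm_forward <- function(params, X, dropout = 0, training = FALSE) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  H <- ncol(params$Wh)/4L
  hs <- vector("list", TT + 1L)
  cs <- vector("list", TT + 1L)
  gates <- vector("list", TT)
  hs[[1]] <- matrix(0, B, H)
  cs[[1]] <- matrix(0, B, H)
  ii <- seq_len(H); ff <- H + ii; oo <- 2L * H + ii; gg <- 3L * H + ii
  for (t in seq_len(TT)) {
    Xt <- matrix(X[, t, ], B)
    Z <- Xt %*% params$Wx + hs[[t]] %*% params$Wh +
      matrix(params$b, B, 4L * H, byrow = TRUE)
    i <- sigm(Z[, ii, drop = FALSE])
    f <- sigm(Z[, ff, drop = FALSE])
    o <- sigm(Z[, oo, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE])
    cs[[t + 1L]] <- f * cs[[t]] + i * g
    hs[[t + 1L]] <- o * tanh(cs[[t + 1L]])
    gates[[t]] <- list(i = i, f = f, o = o, g = g)
  }
  hT <- hs[[TT + 1L]]
  A1 <- hT %*% params$W1 + matrix(params$b1, B, length(params$b1), byrow = TRUE)
  R <- pmax(A1, 0)
  if (training && dropout > 0) {
    M <- matrix(stats::rbinom(length(R), 1L, 1 - dropout), nrow(R)) /
      (1 - dropout)
  } else {
    M <- matrix(1, nrow(R), ncol(R))
  }
  Rd <- R * M
  O <- Rd %*% params$W2 + matrix(params$b2, B, 2L, byrow = TRUE)
  Om <- O - apply(O, 1, max)
  P <- exp(Om) / rowSums(exp(Om))
  out <- list(P = P)
  if (training) {
    out$cache <- list(X = X, hs = hs, cs = cs, gates = gates, A1 = A1,
                      M = M, Rd = Rd, hT = hT)
  }
  out
}

lstm_loss <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
}

# Backpropagation through time; returns gradients with the same shapes as
# the parameters.
lstm_backward <- function(params, fw, y) {
  cache <- fw$cache
  X <- cache$X
  B <- dim(X)[1]; TT <- dim(X)[2]
  H <- ncol(params$Wh)/4L
  ii <- seq_len(H); ff <- H + ii; oo <- 2L * H + ii; gg <- 3L * H + ii

  Yh <- matrix(0, B, 2L)
  Yh[cbind(seq_len(B), y + 1L)] <- 1
  dO <- (fw$P - Yh) / B
  g <- list(
    W2 = t(cache$Rd) %*% dO, b2 = colSums(dO),
    W1 = NULL, b1 = NULL, Wx = matrix(0, nrow(params$Wx), ncol(params$Wx)),
    Wh = matrix(0, H, 4L * H), b = numeric(4L * H)
  )
  dRd <- dO %*% t(params$W2)
  dR <- dRd * cache$M
  dA1 <- dR * (cache$A1 > 0)
  g$W1 <- t(cache$hT) %*% dA1
  g$b1 <- colSums(dA1)
  dh <- dA1 %*% t(params$W1)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    gt <- cache$gates[[t]]
    c_t <- cache$cs[[t + 1L]]
    c_prev <- cache$cs[[t]]
    tc <- tanh(c_t)
    do_ <- dh * tc
    dc <- dc + dh * gt$o * (1 - tc^2)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * c_prev
    dc <- dc * gt$f
    dZ <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                do_ * gt$o * (1 - gt$o),
                dg * (1 - gt$g^2))
    Xt <- matrix(X[, t, ], B)
    g$Wx <- g$Wx + t(Xt) %*% dZ
    g$Wh <- g$Wh + t(cache$hs[[t]]) %*% dZ
    g$b <- g$b + colSums(dZ)
    dh <- dZ %*% t(params$Wh)
  }
  g[names(params)]
}

# --- optimizers shared by the LSTM and CNN trainers -----------------------

opt_init <- function(params, optimizer) {
  zeros <- lapply(params, function(p) p * 0)
  if (optimizer == "adam") list(m = zeros, v = zeros, t = 0L)
  else list(v = zeros)
}

opt_step <- function(params, grads, state, optimizer, lr, momentum = 0.9,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (optimizer == "adam") {
    state$t <- state$t + 1L
    for (nm in names(params)) {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    for (nm in names(params)) {
      state$v[[nm]] <- momentum * state$v[[nm]] - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + state$v[[nm]]
    }
  }
  list(params = params, state = state)
}

dataset_to_array <- function(data) {
  n <- length(data$x)
  TT <- nrow(data$x[[1]])
  d <- ncol(data$x[[1]])
  A <- array(0, c(n, TT, d))
  for (i in seq_len(n)) A[i, , ] <- data$x[[i]]
  A
}

#' Train the LSTM fatigue classifier
#'
#' Standardizes the features (statistics fit on the training set only),
#' then trains the LSTM -> fully connected -> ReLU -> dropout -> softmax
#' stack by backpropagation through time with minibatch Adam (or SGDM).
#' Validation loss is tracked every epoch; the returned model carries the
#' parameters from the best validation epoch (early stopping with the
#' configured patience). All sequences must share the same length;
#' length-1 sequences reduce the model to per-window classification.
#'
#' @param train,val `labeled_dataset`s; the training set must contain both
#'   classes.
#' @param cfg An [lstm_config()].
#' @return An object of class `lstm_model` with elements `params`,
#'   `scaler`, `cfg` and `history` (per-epoch train/validation loss and
#'   validation accuracy).
#' @export
train_lstm <- function(train, val, cfg = lstm_config()) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(val, "labeled_dataset"),
            inherits(cfg, "lstm_config"))
  if (length(unique(train$y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  lens <- vapply(train$x, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all training sequences must share the same length", call. = FALSE)
  }
  scaler <- fit_step_scaler(train)
  tr <- labeled_dataset(scale_sequences(train, scaler), train$y,
                        train$feature_names)
  vl <- labeled_dataset(scale_sequences(val, scaler), val$y,
                        val$feature_names)
  Xtr <- dataset_to_array(tr)
  Xvl <- dataset_to_array(vl)
  d <- dim(Xtr)[3]
  n <- dim(Xtr)[1]

  with_seed(cfg$seed, {
    params <- lstm_init(d, cfg$units, cfg$fc_units)
    state <- opt_init(params, cfg$optimizer)
    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- data.frame()
    wait <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      tr_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        take <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- Xtr[take, , , drop = FALSE]
        yb <- tr$y[take]
        fw <- lstm_forward(params, Xb, cfg$dropout, training = TRUE)
        grads <- lstm_backward(params, fw, yb)
        upd <- opt_step(params, grads, state, cfg$optimizer,
                        cfg$learning_rate, cfg$momentum)
        params <- upd$params
        state <- upd$state
        tr_loss <- tr_loss + lstm_loss(fw$P, yb)
        nb <- nb + 1L
      }
      fwv <- lstm_forward(params, Xvl)
      val_loss <- lstm_loss(fwv$P, vl$y)
      val_acc <- mean(max.col(fwv$P) - 1L == vl$y)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss / nb,
        val_loss = val_loss, val_acc = val_acc))
      if (cfg$verbose) {
        message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val acc %.3f",
                        epoch, tr_loss / nb, val_loss, val_acc))
      }
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    structure(
      list(params = best$params, scaler = scaler, cfg = cfg,
           history = history, best_epoch = best$epoch),
      class = "lstm_model"
    )
  })
}

#' @export
predict_fatigue.lstm_model <- function(model, data) {
  ds <- labeled_dataset(scale_sequences(data, model$scaler),
                        if (is.null(data$y)) rep(0L, length(data$x)) else data$y,
                        data$feature_names)
  X <- dataset_to_array(ds)
  fw <- lstm_forward(model$params, X)
  as.integer(max.col(fw$P) - 1L)
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> %d units, best epoch %d (val loss %.4f)\n",
              x$cfg$units, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}
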