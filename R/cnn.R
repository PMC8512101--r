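#' CNN baseline configuration
#'
#' A small 1-D convolutional baseline over the window-feature sequence:
#' input, two convolutional layers (ReLU, same padding) and two fully
#' connected layers ending in softmax, trained with cross-entropy.
#'
#' @param filters1,filters2 Channels of the two convolutional layers
#'   (defaults 8 and 16).
#' @param kernel Convolution kernel width along the time axis (default 3;
#'   clipped to the sequence length and forced odd).
#' @param fc_units Width of the first fully connected layer (default 32).
#' @param epochs,batch_size,learning_rate,optimizer,momentum,patience,seed,verbose
#'   As in [lstm_config()]; the default learning rate is 0.1 with SGDM.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(filters1 = 8L, filters2 = 16L, kernel = 3L,
                       fc_units = 32L, epochs = 50L, batch_size = 70L,
                       learning_rate = 0.1, optimizer = c("sgdm", "adam"),
                       momentum = 0.9, patience = 10L, seed = 1L,
                       verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(filters1 >= 1, filters2 >= 1, kernel >= 1, fc_units >= 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(
    list(filters1 = as.integer(filters1), filters2 = as.integer(filters2),
         kernel = as.integer(kernel), fc_units = as.integer(fc_units),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         momentum = momentum, patience = patience, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "cnn_config"
  )
}

cnn_kernel_width <- function(kernel, TT) {
  k <- min(kernel, TT)
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 1L)
}

cnn_init <- function(d, TT, cfg) {
  k <- cnn_kernel_width(cfg$kernel, TT)
  list(
    K1 = array(stats::runif(k * d * cfg$filters1,
                            -sqrt(6 / (k * d + cfg$filters1)),
                            sqrt(6 / (k * d + cfg$filters1))),
               c(k, d, cfg$filters1)),
    b1 = numeric(cfg$filters1),
    K2 = array(stats::runif(k * cfg$filters1 * cfg$filters2,
                            -sqrt(6 / (k * cfg$filters1 + cfg$filters2)),
                            sqrt(6 / (k * cfg$filters1 + cfg$filters2))),
               c(k, cfg$filters1, cfg$filters2)),
    b2 = numeric(cfg$filters2),
    W1 = glorot(TT * cfg$filters2, cfg$fc_units),
    c1 = numeric(cfg$fc_units),
    W2 = glorot(cfg$fc_units, 2L),
    c2 = numeric(2L)
  )
}

# Same-padded 1-D convolution of X (B x T x Cin) with kernel K (k x Cin x
# Cout); returns B x T x Cout.
conv1d_forward <- function(X, K, bias) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  k <- dim(K)[1]; Cout <- dim(K)[3]
  pad <- (k - 1L) %/% 2L
  Y <- array(0, c(B, TT, Cout))
  for (t in seq_len(TT)) {
    acc <- matrix(bias, B, Cout, byrow = TRUE)
    for (o in seq_len(k)) {
      s <- t + o - 1L - pad
      if (s < 1L || s > TT) next
      acc <- acc + matrix(X[, s, ], B) %*% matrix(K[o, , ], dim(K)[2])
    }
    Y[, t, ] <- acc
  }
  Y
}

conv1d_backward <- function(X, K, dY) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  k <- dim(K)[1]; Cout <- dim(K)[3]
  pad <- (k - 1L) %/% 2L
  dK <- K * 0
  db <- numeric(Cout)
  dX <- X * 0
  for (t in seq_len(TT)) {
    dYt <- matrix(dY[, t, ], B)
    db <- db + colSums(dYt)
    for (o in seq_len(k)) {
      s <- t + o - 1L - pad
      if (s < 1L || s > TT) next
      Xs <- matrix(X[, s, ], B)
      dK[o, , ] <- matrix(dK[o, , ], dim(K)[2]) + t(Xs) %*% dYt
      dX[, s, ] <- matrix(dX[, s, ], B) + dYt %*% t(matrix(K[o, , ], dim(K)[2]))
    }
  }
  list(dK = dK, db = db, dX = dX)
}

cnn_forward <- function(params, X, training = FALSE) {
  B <- dim(X)[1]; TT <- dim(X)[2]
  A1 <- conv1d_forward(X, params$K1, params$b1)
  R1 <- pmax(A1, 0)
  A2 <- conv1d_forward(R1, params$K2, params$b2)
  R2 <- pmax(A2, 0)
  Zf <- matrix(aperm(R2, c(1, 3, 2)), B)   # flatten channels x time
  F1 <- Zf %*% params$W1 + matrix(params$c1, B, length(params$c1), byrow = TRUE)
  RF <- pmax(F1, 0)
  O <- RF %*% params$W2 + matrix(params$c2, B, 2L, byrow = TRUE)
  Om <- O - apply(O, 1, max)
  P <- exp(Om) / rowSums(exp(Om))
  out <- list(P = P)
  if (training) {
    out$cache <- list(X = X, A1 = A1, R1 = R1, A2 = A2, R2 = R2, Zf = Zf,
                      F1 = F1, RF = RF)
  }
  out
}

cnn_backward <- function(params, fw, y) {
  cache <- fw$cache
  B <- dim(cache$X)[1]; TT <- dim(cache$X)[2]
  Yh <- matrix(0, B, 2L)
  Yh[cbind(seq_len(B), y + 1L)] <- 1
  dO <- (fw$P - Yh) / B
  g <- list()
  g$W2 <- t(cache$RF) %*% dO
  g$c2 <- colSums(dO)
  dRF <- dO %*% t(params$W2)
  dF1 <- dRF * (cache$F1 > 0)
  g$W1 <- t(cache$Zf) %*% dF1
  g$c1 <- colSums(dF1)
  dZf <- dF1 %*% t(params$W1)
  C2 <- dim(cache$R2)[3]
  dR2 <- aperm(array(dZf, c(B, C2, TT)), c(1, 3, 2))
  dA2 <- dR2 * (cache$A2 > 0)
  bk2 <- conv1d_backward(cache$R1, params$K2, dA2)
  g$K2 <- bk2$dK
  g$b2 <- bk2$db
  dA1 <- bk2$dX * (cache$A1 > 0)
  bk1 <- conv1d_backward(cache$X, params$K1, dA1)
  g$K1 <- bk1$dK
  g$b1 <- bk1$db
  g[names(params)]
}

#' Train the CNN baseline fatigue classifier
#'
#' Standardizes features on train-set statistics and trains the two-conv,
#' two-dense network with cross-entropy loss. Early stopping mirrors
#' [train_lstm()].
#'
#' @param train,val `labeled_dataset`s; training set must contain both
#'   classes.
#' @param cfg A [cnn_config()].
#' @return An object of class `cnn_model`.
#' @export
train_cnn <- function(train, val, cfg = cnn_config()) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(val, "labeled_dataset"),
            inherits(cfg, "cnn_config"))
  if (length(unique(train$y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  scaler <- fit_step_scaler(train)
  tr <- labeled_dataset(scale_sequences(train, scaler), train$y)
  vl <- labeled_dataset(scale_sequences(val, scaler), val$y)
  Xtr <- dataset_to_array(tr)
  Xvl <- dataset_to_array(vl)
  n <- dim(Xtr)[1]

  with_seed(cfg$seed, {
    params <- cnn_init(dim(Xtr)[3], dim(Xtr)[2], cfg)
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
        fw <- cnn_forward(params, Xtr[take, , , drop = FALSE], training = TRUE)
        grads <- cnn_backward(params, fw, tr$y[take])
        upd <- opt_step(params, grads, state, cfg$optimizer,
                        cfg$learning_rate, cfg$momentum)
        params <- upd$params
        state <- upd$state
        tr_loss <- tr_loss + lstm_loss(fw$P, tr$y[take])
        nb <- nb + 1L
      }
      fwv <- cnn_forward(params, Xvl)
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
      class = "cnn_model"
    )
  })
}

#' @export
predict_fatigue.cnn_model <- function(model, data) {
  ds <- labeled_dataset(scale_sequences(data, model$scaler), data$y)
  X <- dataset_to_array(ds)
  fw <- cnn_forward(model$params, X)
  as.integer(max.col(fw$P) - 1L)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d+%d filters, best epoch %d\n",
              x$cfg$filters1, x$cfg$filters2, x$best_epoch))
  invisible(x)
}
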