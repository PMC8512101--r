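#' Holdout split specification
#'
#' @param train_frac,val_frac,test_frac Subset fractions, each strictly in
#'   (0, 1) and summing to 1 (within 1e-9). Default 0.7 / 0.1 / 0.2.
#' @param seed Integer RNG seed driving the (stratified) shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.7, val_frac = 0.1, test_frac = 0.2,
                       seed = 1L) {
  fr <- c(train_frac, val_frac, test_frac)
  if (!is.numeric(fr) || any(fr <= 0) || any(fr >= 1)) {
    stop("each fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Partitions the dataset into three disjoint subsets whose class ratios
#' match the global fatigue/non-fatigue ratio up to integer rounding
#' (largest-remainder allocation within each class). Deterministic given
#' the seed in `spec`.
#'
#' @param data A `labeled_dataset`.
#' @param spec A [split_spec()].
#' @return A list with `train`, `val`, `test` (`labeled_dataset`s) and
#'   `indices` (the original indices of each subset).
#' @export
stratified_split <- function(data, spec = split_spec()) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(spec, "split_spec"))
  if (length(unique(data$y)) < 2L) {
    stop("both classes must be present to stratify", call. = FALSE)
  }
  fr <- c(spec$train_frac, spec$val_frac, spec$test_frac)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(spec$seed, {
    for (cls in c(0L, 1L)) {
      members <- sample(which(data$y == cls))
      n_c <- length(members)
      sizes <- floor(n_c * fr)
      rem <- n_c - sum(sizes)
      if (rem > 0) {
        extra <- order(n_c * fr - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      if (any(sizes == 0L)) {
        stop(sprintf(
          "class %d has too few samples (%d) to appear in every subset",
          cls, n_c), call. = FALSE)
      }
      cuts <- cumsum(sizes)
      idx$train <- c(idx$train, members[seq_len(cuts[1])])
      idx$val <- c(idx$val, members[(cuts[1] + 1L):cuts[2]])
      idx$test <- c(idx$test, members[(cuts[2] + 1L):cuts[3]])
    }
  })
  list(train = subset_dataset(data, idx$train),
       val = subset_dataset(data, idx$val),
       test = subset_dataset(data, idx$test),
       indices = idx)
}

#' Classification metrics from confusion counts
#'
#' With fatigue as the positive class: accuracy `(TF+TN)/total`,
#' sensitivity `TF/(TF+FN)`, specificity `TN/(TN+FF)` and precision
#' `TF/(TF+FF)`. A metric whose denominator is zero is returned as `NA`.
#'
#' @param tf,tn,ff,fn Confusion counts: true fatigue, true non-fatigue,
#'   false fatigue, false non-fatigue.
#' @return A list with `counts` and `acc`, `sn`, `sp`, `pr`.
#' @export
eval_metrics <- function(tf, tn, ff, fn) {
  counts <- c(TF = tf, TN = tn, FF = ff, FN = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(counts = counts,
         acc = safe_div(tf + tn, tf + tn + ff + fn),
         sn = safe_div(tf, tf + fn),
         sp = safe_div(tn, tn + ff),
         pr = safe_div(tf, tf + ff)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> TF=%d TN=%d FF=%d FN=%d | Acc %.4f Sn %.4f Sp %.4f Pr %.4f\n",
    x$counts["TF"], x$counts["TN"], x$counts["FF"], x$counts["FN"],
    x$acc, x$sn, x$sp, x$pr))
  invisible(x)
}

#' Evaluate a trained classifier on a test set
#'
#' Predicts every test sequence, tallies the confusion counts with fatigue
#' as the positive class, and derives accuracy, sensitivity, specificity
#' and precision.
#'
#' @param model A model from [train_lstm()], [train_cnn()] or
#'   [train_svm()].
#' @param test A non-empty `labeled_dataset`.
#' @return An `eval_report` (see [eval_metrics()]).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "labeled_dataset"))
  if (length(test$x) == 0L) stop("test set is empty", call. = FALSE)
  pred <- predict_fatigue(model, test)
  y <- test$y
  eval_metrics(tf = sum(pred == 1L & y == 1L),
               tn = sum(pred == 0L & y == 0L),
               ff = sum(pred == 1L & y == 0L),
               fn = sum(pred == 0L & y == 1L))
}

#' Predict fatigue labels
#'
#' @param model A trained fatigue classifier.
#' @param data A `labeled_dataset` (labels, if present, are ignored).
#' @return Integer vector of predicted labels (1 = fatigue).
#' @export
predict_fatigue <- function(model, data) UseMethod("predict_fatigue")

#' Train an RBF-kernel SVM fatigue classifier
#'
#' Flattens each sequence into a single feature vector, standardizes using
#' train-set statistics, and fits a Gaussian-kernel support vector machine
#' (via \pkg{e1071}). Deterministic given the data.
#'
#' @param train A `labeled_dataset` containing both classes.
#' @param cost SVM cost parameter; default 1.
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @return An object of class `svm_fatigue_model`.
#' @export
train_svm <- function(train, cost = 1, gamma = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (length(unique(train$y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- flatten_sequences(train)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  fit <- e1071::svm(x = Xs, y = factor(train$y, levels = c(0, 1)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, scaler = scaler), class = "svm_fatigue_model")
}

#' @export
predict_fatigue.svm_fatigue_model <- function(model, data) {
  X <- apply_scaler(flatten_sequences(data), model$scaler)
  as.integer(as.character(stats::predict(model$fit, X)))
}

flatten_sequences <- function(data) {
  t(vapply(data$x, function(m) as.numeric(t(m)),
           numeric(nrow(data$x[[1]]) * ncol(data$x[[1]]))))
}

# Feature standardization fit on training data only.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mu, `-`), 2, scaler$sd, `/`)
}

# Per-timestep scaling for sequence models: statistics over all train
# timesteps, applied to each row of each sequence matrix.
fit_step_scaler <- function(data) {
  allrows <- do.call(rbind, data$x)
  fit_scaler(allrows)
}

scale_sequences <- function(data, scaler) {
  lapply(data$x, function(m) apply_scaler(m, scaler))
}
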