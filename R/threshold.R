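#' Hard threshold shrinkage
#'
#' Keep-or-kill rule: coefficients with magnitude at or above the threshold
#' pass unchanged, the rest are zeroed.
#'
#' @param w Numeric vector of coefficients.
#' @param lam Threshold, a single number >= 0.
#' @return Thresholded vector, same length as `w`.
#' @export
threshold_hard <- function(w, lam) {
  check_lambda(lam)
  w <- as.numeric(w)
  ifelse(abs(w) >= lam, w, 0)
}

#' Soft threshold shrinkage
#'
#' Coefficients at or above the threshold are shrunk toward zero by the
#' threshold amount; the rest are zeroed.
#'
#' @inheritParams threshold_hard
#' @return Thresholded vector, same length as `w`.
#' @export
threshold_soft <- function(w, lam) {
  check_lambda(lam)
  w <- as.numeric(w)
  ifelse(abs(w) >= lam, sign(w) * (abs(w) - lam), 0)
}

#' Improved threshold shrinkage
#'
#' A smooth compromise between hard and soft thresholding. Above the
#' threshold the coefficient is shrunk by a fraction that decays
#' logarithmically with magnitude, so large coefficients pass almost
#' unchanged (less bias than soft); below the threshold the coefficient is
#' attenuated by a power-law taper rather than zeroed outright (less
#' oscillation than hard). Both branches meet continuously at the threshold
#' with value `(1 - m) * lam`.
#'
#' For `|w| >= lam`:  `w - m * w / (1 + log(|w| / lam))`.
#' For `0 < |w| < lam`:  `(1 - m) * sign(w) * |w|^(k+1) * (1 - log(|w| / lam)) / lam^k`.
#' At `w = 0` the output is 0 (the continuity limit). `lam = 0` degenerates
#' to the identity. Logarithms are natural.
#'
#' @inheritParams threshold_hard
#' @param k Integer taper sharpness, >= 1. Larger `k` suppresses
#'   sub-threshold coefficients more aggressively.
#' @param m Shrinkage fraction at the threshold, strictly in (0, 1).
#'   `m` near 0 behaves like hard thresholding, near 1 like a deep notch.
#' @return Thresholded vector, same length as `w`.
#' @export
threshold_improved <- function(w, lam, k = 2L, m = 0.5) {
  check_lambda(lam)
  check_km(k, m)
  w <- as.numeric(w)
  if (lam == 0) return(w)
  out <- numeric(length(w))
  aw <- abs(w)
  hi <- aw >= lam
  if (any(hi)) {
    out[hi] <- w[hi] - m * w[hi] / (1 + log(aw[hi] / lam))
  }
  lo <- !hi & aw > 0
  if (any(lo)) {
    r <- aw[lo] / lam                      # in (0, 1)
    out[lo] <- (1 - m) * sign(w[lo]) * lam * r^(k + 1) * (1 - log(r))
  }
  out
}

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0) {
    stop("threshold `lam` must be a single number >= 0", call. = FALSE)
  }
}

check_km <- function(k, m) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m <= 0 || m >= 1) {
    stop("`m` must lie strictly in (0, 1)", call. = FALSE)
  }
}

#' Heuristic SURE-style threshold estimation
#'
#' Candidate thresholds are the square roots of the sorted squared
#' coefficients. Each candidate `i` is scored with the risk
#' `risk(i) = (N - 2i + sum_{j<=i} Ws(j) + (N - i + 1) * Ws(N - i + 1)) / N`
#' where `Ws` is the ascending sort of the squared coefficients, and the
#' threshold is the candidate minimising the risk (ties go to the smallest
#' index).
#'
#' The classical heuristic fallback to the fixed `sqrt(2 log N)` threshold
#' for sparse coefficient vectors is available behind `sparse_fallback` but
#' is off by default.
#'
#' @param W Numeric vector of coefficients (non-empty, finite).
#' @param sparse_fallback If `TRUE`, use the fixed threshold
#'   `sqrt(2 log N)` when the coefficients look sparse (low excess energy),
#'   and the smaller of the fixed and risk-selected threshold otherwise.
#' @return The selected threshold (a single number >= 0).
#' @export
heursure_lambda <- function(W, sparse_fallback = FALSE) {
  W <- as.numeric(W)
  if (length(W) == 0L) stop("`W` must be non-empty", call. = FALSE)
  if (!all(is.finite(W))) stop("`W` must be finite", call. = FALSE)
  N <- length(W)
  Ws <- sort(W^2)
  i <- seq_len(N)
  risk <- (N - 2 * i + cumsum(Ws) + (N - i + 1) * Ws[N - i + 1]) / N
  ihat <- which.min(risk)              # first minimum: smallest i on ties
  lam_risk <- sqrt(Ws[ihat])
  if (!sparse_fallback) return(lam_risk)
  lam_fixed <- sqrt(2 * log(N))
  eta <- (sum(W^2) - N) / N
  crit <- (log2(N))^1.5 / sqrt(N)
  if (eta < crit) lam_fixed else min(lam_fixed, lam_risk)
}

#' Threshold configuration
#'
#' Bundles the threshold-function kind with its parameters and the rule used
#' to pick the threshold value on each wavelet-packet node.
#'
#' @param kind One of `"hard"`, `"soft"`, `"improved"`.
#' @param lambda_rule `"heursure"` (risk-based, per node) or `"fixed"`.
#' @param fixed_lambda Threshold used when `lambda_rule = "fixed"` (>= 0).
#' @param k,m Improved-threshold parameters, see [threshold_improved()].
#' @param pool `"node"` estimates a threshold from each best-tree leaf's own
#'   coefficients; `"level"` pools all best leaves of a level.
#' @param threshold_approx Whether the lowest-frequency (approximation) leaf
#'   is thresholded too (default `TRUE`). That leaf carries most signal
#'   energy, so `FALSE` is a conservative alternative.
#' @param sparse_fallback Passed to [heursure_lambda()].
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(kind = c("improved", "hard", "soft"),
                             lambda_rule = c("heursure", "fixed"),
                             fixed_lambda = 0, k = 2L, m = 0.5,
                             pool = c("node", "level"),
                             threshold_approx = TRUE,
                             sparse_fallback = FALSE) {
  kind <- match.arg(kind)
  lambda_rule <- match.arg(lambda_rule)
  pool <- match.arg(pool)
  if (lambda_rule == "fixed") check_lambda(fixed_lambda)
  check_km(k, m)
  structure(
    list(kind = kind, lambda_rule = lambda_rule,
         fixed_lambda = as.numeric(fixed_lambda), k = as.integer(k),
         m = as.numeric(m), pool = pool,
         threshold_approx = isTRUE(threshold_approx),
         sparse_fallback = isTRUE(sparse_fallback)),
    class = "threshold_config"
  )
}

apply_threshold <- function(w, lam, cfg) {
  switch(cfg$kind,
         hard = threshold_hard(w, lam),
         soft = threshold_soft(w, lam),
         improved = threshold_improved(w, lam, cfg$k, cfg$m))
}

#' Wavelet packet threshold denoising
#'
#' The full denoising chain: decompose the signal into a wavelet-packet
#' tree, select the Shannon-entropy best tree, estimate a threshold for each
#' best-tree leaf, shrink the leaf coefficients with the configured
#' threshold function, and reconstruct by the inverse transform.
#'
#' @param signal A `signal_record` (or numeric vector at 1 Hz).
#' @param config A [threshold_config()]; default improved thresholding with
#'   per-node risk-estimated thresholds.
#' @param wavelet,max_level Passed to [wp_decompose()]; defaults db45, 4.
#' @return A list of class `denoise_result` with elements `signal` (the
#'   denoised `signal_record`), `per_node_lambda` (named numeric vector of
#'   per-leaf thresholds; `NA` for leaves exempted from thresholding),
#'   `best_leaves`, and `config`.
#' @export
wp_denoise <- function(signal, config = threshold_config(),
                       wavelet = "db45", max_level = 4L) {
  stopifnot(inherits(config, "threshold_config"))
  tree <- wp_best_tree(wp_decompose(signal, wavelet, max_level))
  leaves <- tree$best_leaves
  keys <- vapply(seq_len(nrow(leaves)),
                 function(r) node_key(leaves[r, 1], leaves[r, 2]),
                 character(1))

  pick_lambda <- function(w) {
    if (config$lambda_rule == "fixed") config$fixed_lambda
    else heursure_lambda(w, config$sparse_fallback)
  }
  lam_by_leaf <- numeric(nrow(leaves))
  if (config$pool == "level" && config$lambda_rule == "heursure") {
    for (lev in unique(leaves[, 1])) {
      rows <- which(leaves[, 1] == lev)
      pooled <- unlist(lapply(keys[rows],
                              function(k) tree$nodes[[k]]$coefficients))
      lam_by_leaf[rows] <- pick_lambda(pooled)
    }
  } else {
    for (r in seq_len(nrow(leaves))) {
      lam_by_leaf[r] <- pick_lambda(tree$nodes[[keys[r]]]$coefficients)
    }
  }

  lam_out <- lam_by_leaf
  for (r in seq_len(nrow(leaves))) {
    is_approx <- leaves[r, 2] == 0
    if (is_approx && !config$threshold_approx) {
      lam_out[r] <- NA_real_
      next
    }
    key <- keys[r]
    tree$nodes[[key]]$coefficients <-
      apply_threshold(tree$nodes[[key]]$coefficients, lam_by_leaf[r], config)
  }
  denoised <- wp_reconstruct(tree)
  names(lam_out) <- keys
  structure(
    list(signal = denoised, per_node_lambda = lam_out,
         best_leaves = leaves, config = config),
    class = "denoise_result"
  )
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("<denoise_result> %s thresholding, %d best leaves\n",
              x$config$kind, length(x$per_node_lambda)))
  invisible(x)
}

#' Signal-to-noise ratio in dB
#'
#' `10 * log10(sum(ref^2) / sum((ref - est)^2))` where `ref` is the clean
#' reference and `est` the denoised estimate. A zero residual yields `Inf`.
#'
#' @param reference Clean reference signal (`signal_record` or numeric).
#' @param estimate Estimate of the same length.
#' @return SNR in dB.
#' @export
snr_db <- function(reference, estimate) {
  ref <- as_samples(reference)
  est <- as_samples(estimate)
  if (length(ref) != length(est)) {
    stop("`reference` and `estimate` must have equal length", call. = FALSE)
  }
  if (all(ref == 0)) {
    stop("`reference` must not be identically zero", call. = FALSE)
  }
  res <- sum((ref - est)^2)
  if (res == 0) return(Inf)
  10 * log10(sum(ref^2) / res)
}

#' Root-mean-square error
#'
#' `sqrt(mean((ref - est)^2))`, in signal units.
#'
#' @inheritParams snr_db
#' @return RMSE (>= 0).
#' @export
rmse <- function(reference, estimate) {
  ref <- as_samples(reference)
  est <- as_samples(estimate)
  if (length(ref) != length(est)) {
    stop("`reference` and `estimate` must have equal length", call. = FALSE)
  }
  sqrt(mean((ref - est)^2))
}
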