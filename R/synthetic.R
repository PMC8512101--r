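#' Synthetic sEMG generator configuration
#'
#' Parameters of the fatigue-modulated synthetic sEMG model: band-limited
#' shaped Gaussian noise whose spectral upper edge drifts down and whose
#' amplitude gain drifts up linearly across the fatigue phase, plus additive
#' white Gaussian noise at a requested input SNR.
#'
#' @param duration_s Record duration in seconds (default 120, the order of
#'   an incremental cycling bout).
#' @param sampling_rate Sampling rate in Hz (default 2000, matching typical
#'   research-grade sEMG hardware).
#' @param band A [band_spec()] for the clean-signal bandwidth (default
#'   20--450 Hz, the conventional sEMG energy band).
#' @param at_frac Fraction of the duration at which fatigue begins (the
#'   anaerobic-threshold surrogate), strictly in (0, 1); default 0.5.
#' @param mf_drop_frac Fractional downward drift of the band's upper edge
#'   (hence of the spectral centroid) across the fatigue phase, in \[0, 1);
#'   default 0.3.
#' @param rms_gain Amplitude multiplier reached by the end of the fatigue
#'   phase, >= 1; default 1.5.
#' @param input_snr_db Input SNR of the noisy signal in dB; default 5.
#' @param seed Integer RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 120, sampling_rate = 2000,
                         band = band_spec(20, 450), at_frac = 0.5,
                         mf_drop_frac = 0.3, rms_gain = 1.5,
                         input_snr_db = 5, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive", call. = FALSE)
  }
  stopifnot(inherits(band, "band_spec"))
  if (!is.numeric(at_frac) || at_frac <= 0 || at_frac >= 1) {
    stop("`at_frac` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(mf_drop_frac) || mf_drop_frac < 0 || mf_drop_frac >= 1) {
    stop("`mf_drop_frac` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(rms_gain) || rms_gain < 1) {
    stop("`rms_gain` must be >= 1", call. = FALSE)
  }
  if (band$f2 * (1 - mf_drop_frac) <= band$f1) {
    stop("infeasible band: upper edge drops to or below the lower edge",
         call. = FALSE)
  }
  if (band$f2 > sampling_rate / 2) {
    stop("band upper edge exceeds the Nyquist frequency", call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, sampling_rate = sampling_rate, band = band,
         at_frac = at_frac, mf_drop_frac = mf_drop_frac,
         rms_gain = rms_gain, input_snr_db = input_snr_db,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate fatigue-modulated synthetic sEMG
#'
#' The clean signal is Gaussian noise shaped block-by-block in the frequency
#' domain (Hann-windowed overlap-add, 50% overlap) to a band whose upper
#' edge decreases linearly by `mf_drop_frac` across the fatigue phase, and
#' scaled by a per-sample gain increasing linearly to `rms_gain` over the
#' same phase. This reproduces the two statistical signatures of fatiguing
#' muscle that the feature set targets -- downward spectral shift and
#' amplitude rise -- without modelling motor-unit physiology. The noisy
#' signal adds white Gaussian noise rescaled so the realized input SNR
#' equals `input_snr_db` exactly.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `semg_ground_truth` with `clean` and `noisy`
#'   (`signal_record`s of equal length), `at_time_s`, and `config`.
#' @export
generate_semg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sampling_rate
  n <- round(cfg$duration_s * fs)
  at_time <- cfg$at_frac * cfg$duration_s
  with_seed(cfg$seed, {
    block <- max(4L, min(512L, 2L * (n %/% 2L)))
    hop <- block %/% 2L
    # pad a full block on each side so every output sample gets complete
    # Hann overlap-add coverage (periodic Hann at 50% overlap sums to 1)
    n2 <- n + 2L * block
    white <- stats::rnorm(n2)
    win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(block) - 1) / block)
    acc <- numeric(n2 + block)
    freqs <- (seq_len(block) - 1) * fs / block
    freqs <- pmin(freqs, fs - freqs)    # two-sided grid folded to [0, fs/2]
    starts <- seq(1L, n2 - block + 1L, by = hop)
    for (s in starts) {
      tmid <- (s - block - 1 + block / 2) / fs   # time relative to record start
      prog <- if (tmid <= at_time) 0 else {
        min(1, (tmid - at_time) / (cfg$duration_s - at_time))
      }
      f_hi <- cfg$band$f2 * (1 - prog * cfg$mf_drop_frac)
      roll <- 10  # Hz raised-cosine edge width
      mask <- raised_cosine_mask(freqs, cfg$band$f1, f_hi, roll)
      seg <- white[s:(s + block - 1L)] * win
      shaped <- Re(stats::fft(stats::fft(seg) * mask, inverse = TRUE)) / block
      acc[s:(s + block - 1L)] <- acc[s:(s + block - 1L)] + shaped
    }
    clean <- acc[(block + 1L):(block + n)]
    # per-sample amplitude trajectory
    tt <- (seq_len(n) - 1) / fs
    prog <- pmax(0, pmin(1, (tt - at_time) / (cfg$duration_s - at_time)))
    gain <- 1 + prog * (cfg$rms_gain - 1)
    clean <- clean * gain
    # normalize the pre-fatigue portion to unit RMS
    pre <- clean[tt < at_time]
    clean <- clean / sqrt(mean(pre^2))
    # additive white noise at exactly the requested input SNR
    noise <- stats::rnorm(n)
    target_pow <- sum(clean^2) / 10^(cfg$input_snr_db / 10)
    noise <- noise * sqrt(target_pow / sum(noise^2))
    noisy <- clean + noise
    structure(
      list(clean = signal_record(clean, fs, "emg_clean"),
           noisy = signal_record(noisy, fs, "emg"),
           at_time_s = at_time, config = cfg),
      class = "semg_ground_truth"
    )
  })
}

raised_cosine_mask <- function(freqs, f_lo, f_hi, roll) {
  m <- numeric(length(freqs))
  inside <- freqs >= f_lo & freqs <= f_hi
  m[inside] <- 1
  lo_edge <- freqs >= f_lo - roll & freqs < f_lo
  m[lo_edge] <- 0.5 + 0.5 * cos(pi * (f_lo - freqs[lo_edge]) / roll)
  hi_edge <- freqs > f_hi & freqs <= f_hi + roll
  m[hi_edge] <- 0.5 + 0.5 * cos(pi * (freqs[hi_edge] - f_hi) / roll)
  m
}

#' @export
print.semg_ground_truth <- function(x, ...) {
  cat(sprintf("<semg_ground_truth> %.1f s @ %g Hz, fatigue onset %.1f s, input SNR %g dB\n",
              x$config$duration_s, x$config$sampling_rate, x$at_time_s,
              x$config$input_snr_db))
  invisible(x)
}

#' Labelled sequence dataset
#'
#' Container for classifier input: a list of equal-width numeric matrices
#' (one row per window, one column per feature) and a binary label per
#' sequence (`1` = fatigue, `0` = non-fatigue).
#'
#' @param x List of numeric matrices with identical column count.
#' @param y Integer labels in {0, 1}, one per sequence.
#' @param feature_names Optional column names.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(x, y,
                            feature_names = c("rms", "iemg", "mf_hz", "mpf_hz")) {
  if (!is.list(x) || length(x) == 0L) {
    stop("`x` must be a non-empty list of matrices", call. = FALSE)
  }
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  d <- ncol(x[[1]])
  if (!all(vapply(x, ncol, integer(1)) == d)) {
    stop("all sequences must have the same number of feature columns",
         call. = FALSE)
  }
  y <- as.integer(y)
  if (length(y) != length(x) || !all(y %in% c(0L, 1L))) {
    stop("`y` must be 0/1 labels, one per sequence", call. = FALSE)
  }
  structure(list(x = x, y = y, feature_names = feature_names),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$x)

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d sequences (%d fatigue / %d non-fatigue), %d steps x %d features\n",
              length(x$x), sum(x$y == 1L), sum(x$y == 0L),
              nrow(x$x[[1]]), ncol(x$x[[1]])))
  invisible(x)
}

subset_dataset <- function(data, idx) {
  labeled_dataset(data$x[idx], data$y[idx], data$feature_names)
}

#' Generate a feature-space dataset of controlled separability
#'
#' Draws two Gaussian classes directly in (RMS, IEMG, MF, MPF) feature space
#' with class-mean distance `separation_sd` pooled standard deviations
#' (measured in per-feature standardized units). The fatigue class has
#' higher RMS/IEMG means and lower MF/MPF means, matching the physiological
#' signatures. Each sequence stacks `seq_len` independent window draws.
#'
#' @param n_per_class Sequences per class, >= 10.
#' @param separation_sd Class-mean separation in pooled SD units, >= 0
#'   (0 gives exchangeable classes, the chance-level null).
#' @param seed Integer RNG seed.
#' @param seq_len Windows per sequence (default 5).
#' @return A `labeled_dataset`.
#' @export
generate_feature_dataset <- function(n_per_class, separation_sd, seed = 1L,
                                     seq_len = 5L) {
  if (!is.numeric(n_per_class) || n_per_class < 10) {
    stop("`n_per_class` must be >= 10", call. = FALSE)
  }
  if (!is.numeric(separation_sd) || separation_sd < 0) {
    stop("`separation_sd` must be >= 0", call. = FALSE)
  }
  seq_len <- as.integer(seq_len)
  stopifnot(seq_len >= 1L)
  mu <- c(rms = 0.5, iemg = 1.0, mf_hz = 80, mpf_hz = 90)
  sd <- c(rms = 0.1, iemg = 0.2, mf_hz = 8, mpf_hz = 8)
  u <- c(1, 1, -1, -1) / 2   # unit vector: fatigue up in amplitude, down in frequency
  with_seed(seed, {
    make_class <- function(cls) {
      shift <- (cls - 0.5) * separation_sd * u
      lapply(seq_len(n_per_class), function(i) {
        z <- matrix(stats::rnorm(seq_len * 4L), seq_len, 4L)
        m <- sweep(z, 2, shift, `+`)
        m <- sweep(m, 2, sd, `*`)
        m <- sweep(m, 2, mu, `+`)
        colnames(m) <- names(mu)
        m
      })
    }
    x0 <- make_class(0)
    x1 <- make_class(1)
    labeled_dataset(c(x0, x1), rep(c(0L, 1L), each = n_per_class))
  })
}

#' Group a feature matrix into a labelled sequence dataset
#'
#' Groups consecutive same-label windows of each channel into fixed-length
#' subsequences (remainders are dropped) so the recurrent classifier sees
#' short ordered stretches of the feature trajectory.
#'
#' @param fm A `feature_matrix` from [extract_features()] (rows from several
#'   channels may be concatenated).
#' @param seq_len Windows per sequence; default 5. Use 1 for per-window
#'   classification.
#' @return A `labeled_dataset` over the features
#'   `rms`, `iemg`, `mf_hz`, `mpf_hz`.
#' @export
features_to_dataset <- function(fm, seq_len = 5L) {
  stopifnot(is.data.frame(fm))
  seq_len <- as.integer(seq_len)
  stopifnot(seq_len >= 1L)
  feats <- c("rms", "iemg", "mf_hz", "mpf_hz")
  xs <- list()
  ys <- integer(0)
  for (ch in unique(fm$channel)) {
    sub <- fm[fm$channel == ch, , drop = FALSE]
    sub <- sub[order(sub$window_start_s), , drop = FALSE]
    runs <- rle(sub$label)
    pos <- 1L
    for (r in seq_along(runs$lengths)) {
      len <- runs$lengths[r]
      rows <- pos:(pos + len - 1L)
      pos <- pos + len
      nseq <- len %/% seq_len
      if (nseq == 0L) next
      for (sdx in seq_len(nseq)) {
        take <- rows[((sdx - 1L) * seq_len + 1L):(sdx * seq_len)]
        xs[[length(xs) + 1L]] <- as.matrix(sub[take, feats])
        ys <- c(ys, if (runs$values[r] == "fatigue") 1L else 0L)
      }
    }
  }
  if (length(xs) == 0L) {
    stop("no complete sequences could be formed", call. = FALSE)
  }
  labeled_dataset(xs, ys)
}
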