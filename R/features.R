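#' Moving-window specification
#'
#' @param width_s Window width in seconds (default 2, the conventional sEMG
#'   feature window).
#' @param step_s Step between window starts in seconds; default equal to the
#'   width, i.e. disjoint windows. Must satisfy `0 < step_s <= width_s`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width_s = 2, step_s = width_s) {
  if (!is.numeric(width_s) || width_s <= 0) {
    stop("`width_s` must be positive", call. = FALSE)
  }
  if (!is.numeric(step_s) || step_s <= 0 || step_s > width_s) {
    stop("`step_s` must satisfy 0 < step_s <= width_s", call. = FALSE)
  }
  structure(list(width_s = width_s, step_s = step_s), class = "window_spec")
}

#' Analysis band specification
#'
#' Frequency band `[f1, f2]` over which spectral features (median and mean
#' power frequency) are integrated.
#'
#' @param f1,f2 Band edges in Hz, `0 <= f1 < f2`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(f1 = 10, f2 = 500) {
  if (!is.numeric(f1) || !is.numeric(f2) || f1 < 0 || f2 <= f1) {
    stop("band must satisfy 0 <= f1 < f2", call. = FALSE)
  }
  structure(list(f1 = f1, f2 = f2), class = "band_spec")
}

#' Slice a signal into moving windows
#'
#' Windows of exactly `round(width_s * fs)` samples starting every
#' `round(step_s * fs)` samples; a trailing partial window is discarded.
#'
#' @param signal A `signal_record`.
#' @param spec A [window_spec()].
#' @return A list of numeric windows, with attribute `start_s` giving each
#'   window's start time in seconds.
#' @export
sliding_windows <- function(signal, spec = window_spec()) {
  stopifnot(inherits(signal, "signal_record"), inherits(spec, "window_spec"))
  fs <- signal$sampling_rate
  width <- round(spec$width_s * fs)
  step <- round(spec$step_s * fs)
  n <- length(signal$samples)
  if (n < width) {
    stop(sprintf("signal (%.3f s) is shorter than one %g s window",
                 n / fs, spec$width_s), call. = FALSE)
  }
  starts <- seq(1L, n - width + 1L, by = step)
  wins <- lapply(starts, function(s) signal$samples[s:(s + width - 1L)])
  attr(wins, "start_s") <- (starts - 1L) / fs
  wins
}

#' Window root-mean-square amplitude
#'
#' @param window Non-empty numeric window.
#' @return `sqrt(mean(window^2))`, in signal units. Rises with fatigue.
#' @export
emg_rms <- function(window) {
  window <- as.numeric(window)
  if (length(window) == 0L) stop("empty window", call. = FALSE)
  sqrt(mean(window^2))
}

#' Integrated EMG
#'
#' Rectangle-rule discretization of the integral of the rectified signal:
#' `sum(|x|) * dt`, in signal units times seconds. Rises with fatigue.
#'
#' @param window Non-empty numeric window.
#' @param dt Sample interval in seconds (`1 / sampling_rate`).
#' @param unitless If `TRUE`, return the bare rectified sum `sum(|x|)`
#'   without the `dt` factor.
#' @return Integrated rectified amplitude.
#' @export
emg_iemg <- function(window, dt, unitless = FALSE) {
  window <- as.numeric(window)
  if (length(window) == 0L) stop("empty window", call. = FALSE)
  if (unitless) return(sum(abs(window)))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  sum(abs(window)) * dt
}

#' One-sided periodogram power spectral density
#'
#' Plain periodogram `P(f) = |X(f)|^2 / L` on the non-negative frequency
#' grid, where `X` is the discrete Fourier transform of the (optionally
#' Hann-tapered) window and `L` its length. Interior bins are doubled so
#' the one-sided spectrum carries the full signal energy
#' (`sum(P) = sum(x^2)` for the untapered case).
#'
#' @param window Numeric window, length >= 2.
#' @param sampling_rate Sampling rate in Hz.
#' @param taper `"none"` (default, the plain periodogram) or `"hann"`.
#' @return A list with `freq` (Hz) and `power`.
#' @export
emg_psd <- function(window, sampling_rate, taper = c("none", "hann")) {
  taper <- match.arg(taper)
  window <- as.numeric(window)
  L <- length(window)
  if (L < 2L) stop("window must have at least 2 samples", call. = FALSE)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
    window <- window * w
  }
  X <- stats::fft(window)
  half <- floor(L / 2) + 1L
  P <- Mod(X[seq_len(half)])^2 / L
  # fold negative frequencies onto the positive grid (not DC, not Nyquist)
  interior <- 2:(half - 1L)
  if (L %% 2 == 1L) interior <- 2:half
  P[interior] <- 2 * P[interior]
  list(freq = (seq_len(half) - 1L) * sampling_rate / L, power = P)
}

band_select <- function(freq, power, band) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f2 > max(freq)) {
    stop("band exceeds the spectrum support", call. = FALSE)
  }
  sel <- which(freq >= band$f1 & freq <= band$f2)
  if (length(sel) == 0L || sum(power[sel]) <= 0) {
    stop("no spectral power inside the band", call. = FALSE)
  }
  sel
}

#' Median frequency of a power spectrum
#'
#' The frequency splitting the in-band power into equal halves: the smallest
#' grid frequency at which the cumulative in-band power reaches half the
#' total, with linear interpolation between the straddling bins. Falls with
#' fatigue.
#'
#' @param freq Frequency grid in Hz.
#' @param power Spectral power on that grid.
#' @param band A [band_spec()].
#' @return Median frequency in Hz, inside `[f1, f2]`.
#' @export
median_frequency <- function(freq, power, band = band_spec()) {
  sel <- band_select(freq, power, band)
  f <- freq[sel]
  p <- power[sel]
  cum <- cumsum(p)
  half <- cum[length(cum)] / 2
  j <- which(cum >= half)[1]
  if (j == 1L) return(f[1])
  prev <- cum[j - 1L]
  f[j - 1L] + (f[j] - f[j - 1L]) * (half - prev) / p[j]
}

#' Mean power frequency of a power spectrum
#'
#' Power-weighted mean frequency over the band (discrete sums as
#' quadrature). Falls with fatigue.
#'
#' @inheritParams median_frequency
#' @return Mean power frequency in Hz, inside `[f1, f2]`.
#' @export
mean_power_frequency <- function(freq, power, band = band_spec()) {
  sel <- band_select(freq, power, band)
  sum(freq[sel] * power[sel]) / sum(power[sel])
}

#' Windowed fatigue feature extraction
#'
#' Slides a window over the signal and computes the four fatigue features
#' per window: RMS and integrated EMG in the time domain, median and mean
#' power frequency of the periodogram in the frequency domain. Each window
#' is labelled `fatigue` when its start time is at or past the fatigue
#' boundary (the anaerobic-threshold time in the incremental-exercise
#' protocol the labels emulate), else `non-fatigue`.
#'
#' @param signal A `signal_record` (typically denoised).
#' @param wspec A [window_spec()]; default 2 s disjoint windows.
#' @param band A [band_spec()]; default 10--500 Hz.
#' @param at_time_s Fatigue-boundary time in seconds.
#' @param taper Periodogram taper, see [emg_psd()].
#' @return A `data.frame` (class `feature_matrix`) with columns
#'   `window_start_s`, `channel`, `rms`, `iemg`, `mf_hz`, `mpf_hz`, `label`.
#' @export
extract_features <- function(signal, wspec = window_spec(),
                             band = band_spec(), at_time_s,
                             taper = "none") {
  stopifnot(inherits(signal, "signal_record"))
  if (missing(at_time_s) || !is.numeric(at_time_s) || length(at_time_s) != 1L) {
    stop("`at_time_s` (fatigue boundary, seconds) is required", call. = FALSE)
  }
  wins <- sliding_windows(signal, wspec)
  starts <- attr(wins, "start_s")
  fs <- signal$sampling_rate
  rows <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    sp <- emg_psd(w, fs, taper)
    data.frame(
      window_start_s = starts[i],
      channel = signal$label,
      rms = emg_rms(w),
      iemg = emg_iemg(w, 1 / fs),
      mf_hz = median_frequency(sp$freq, sp$power, band),
      mpf_hz = mean_power_frequency(sp$freq, sp$power, band),
      label = if (starts[i] >= at_time_s) "fatigue" else "non-fatigue",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Write a feature matrix to CSV
#' @param fm A `feature_matrix` from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
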