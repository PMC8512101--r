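#' Uniformly sampled single-channel signal
#'
#' The basic unit every stage of the pipeline consumes and produces: a finite,
#' non-empty numeric sample vector together with its sampling rate in Hz and a
#' free-text channel label (e.g. the muscle the electrode sat on).
#'
#' @param samples Numeric vector of signal values (e.g. mV). Must be finite
#'   and non-empty.
#' @param sampling_rate Sampling rate in Hz, a single positive number.
#' @param label Channel name, a single string. Default `"emg"`.
#' @return An object of class `signal_record`.
#' @examples
#' x <- signal_record(sin(2 * pi * 50 * seq(0, 1, by = 1 / 2000)), 2000, "RF")
#' duration_s(x)
#' @export
signal_record <- function(samples, sampling_rate, label = "emg") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         label = as.character(label)[1]),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> channel '%s': %d samples @ %g Hz (%.3f s)\n",
              x$label, length(x$samples), x$sampling_rate, duration_s(x)))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param x A `signal_record`.
#' @return Duration in seconds.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  length(x$samples) / x$sampling_rate
}

# Accept either a signal_record or a bare numeric vector where only the
# samples matter; returns the numeric vector.
as_samples <- function(x) {
  if (inherits(x, "signal_record")) x$samples else as.numeric(x)
}

#' Read signals from a CSV file
#'
#' Expects a header row with first column `time_s` followed by one column per
#' channel. The sampling rate is inferred from the median spacing of
#' `time_s` unless given explicitly.
#'
#' @param path Path to the CSV file.
#' @param sampling_rate Optional sampling rate in Hz; inferred from the time
#'   column when `NULL`.
#' @return A named list of `signal_record` objects, one per channel column.
#' @export
read_signal_csv <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "time_s") {
    stop("signal CSV must have a `time_s` first column plus channel columns",
         call. = FALSE)
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop(sprintf("non-numeric values in column(s): %s",
                 paste(names(df)[bad], collapse = ", ")), call. = FALSE)
  }
  if (is.null(sampling_rate)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) {
      stop("cannot infer sampling rate from `time_s` column", call. = FALSE)
    }
    sampling_rate <- 1 / dt
  }
  chans <- names(df)[-1]
  out <- lapply(chans, function(ch) signal_record(df[[ch]], sampling_rate, ch))
  names(out) <- chans
  out
}

#' Write signals to a CSV file
#'
#' Inverse of [read_signal_csv()]: writes `time_s` plus one column per channel.
#' All signals must share length and sampling rate.
#'
#' @param signals A `signal_record` or named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signals, path) {
  if (inherits(signals, "signal_record")) signals <- list(signals)
  stopifnot(length(signals) >= 1L)
  n <- length(signals[[1]]$samples)
  fs <- signals[[1]]$sampling_rate
  for (s in signals) {
    stopifnot(inherits(s, "signal_record"))
    if (length(s$samples) != n || s$sampling_rate != fs) {
      stop("all channels must share length and sampling rate", call. = FALSE)
    }
  }
  nm <- names(signals)
  if (is.null(nm)) nm <- vapply(signals, `[[`, character(1), "label")
  df <- data.frame(time_s = (seq_len(n) - 1) / fs)
  for (i in seq_along(signals)) df[[nm[i]]] <- signals[[i]]$samples
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
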