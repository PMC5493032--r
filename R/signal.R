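#' Construct an EEG signal object
#'
#' The basic currency of the package: a uniformly sampled voltage series in
#' microvolts with its sampling rate. All processing functions accept and
#' return `eeg_signal` objects; plain numeric vectors are accepted wherever a
#' sampling rate is supplied alongside.
#'
#' @param samples numeric vector of voltages, uV. Must be finite and of
#'   length >= 2.
#' @param fs sampling rate, Hz (> 0).
#' @param label optional state tag, one of `"eyes_open"`, `"eyes_closed"`,
#'   `"synthetic"`, or `NULL`.
#' @return an object of class `eeg_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 200)), fs = 200)
#' s
#' @export
eeg_signal <- function(samples, fs, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("an EEG signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("EEG samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  if (!is.null(label))
    label <- match.arg(label, c("eyes_open", "eyes_closed", "synthetic"))
  structure(list(samples = samples, fs = as.numeric(fs), label = label),
            class = "eeg_signal")
}

#' Coerce to a plain numeric sample vector
#'
#' @param x an `eeg_signal` or numeric vector.
#' @return the numeric sample vector.
#' @export
signal_samples <- function(x) {
  if (inherits(x, "eeg_signal")) x$samples else as.numeric(x)
}

#' Number of samples in a signal
#' @param x an `eeg_signal`.
#' @return integer sample count.
#' @export
n_samples <- function(x) length(signal_samples(x))

#' Sample times of a signal
#'
#' Samples sit on the grid `t = n / fs` for `n = 0, ..., N - 1` (the grid
#' includes t = 0 and excludes the nominal duration).
#'
#' @param x an `eeg_signal`.
#' @return numeric vector of times, seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "eeg_signal"))
  (seq_len(n_samples(x)) - 1) / x$fs
}

#' @export
print.eeg_signal <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<eeg_signal> %d samples @ %g Hz (%.3f s)%s\n",
              n, x$fs, n / x$fs,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  cat(sprintf("  amplitude range [%.2f, %.2f] uV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

# internal: accept eeg_signal or numeric + fs, return eeg_signal
as_eeg_signal <- function(x, fs = NULL) {
  if (inherits(x, "eeg_signal")) return(x)
  if (is.null(fs))
    stop("a plain numeric series needs an explicit 'fs'", call. = FALSE)
  eeg_signal(x, fs)
}
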