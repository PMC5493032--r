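#' Read a single-channel EEG signal from CSV
#'
#' Accepts the package's canonical dialect: either a two-column file with
#' header `time_s,amplitude_uv` (the sampling rate is derived from the time
#' column, which must be uniform) or a single `amplitude_uv` column with the
#' rate supplied via `fs`. Voltages are microvolts throughout.
#'
#' @param path CSV file path.
#' @param fs sampling rate, Hz; required when the file has no time column.
#' @param label optional state tag attached to the signal.
#' @return an [eeg_signal()].
#' @export
read_eeg_csv <- function(path, fs = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path)
  if ("amplitude_uv" %in% names(df)) {
    amp <- df$amplitude_uv
  } else if (ncol(df) == 1L) {
    amp <- df[[1L]]
  } else {
    stop("cannot find an 'amplitude_uv' column in ", path, call. = FALSE)
  }
  if ("time_s" %in% names(df)) {
    t <- df$time_s
    dt <- diff(t)
    if (length(dt) < 1L || any(dt <= 0))
      stop("time column must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("non-uniform time column: resample before analysis",
           call. = FALSE)
    fs_file <- (length(t) - 1) / (t[length(t)] - t[1])
    if (!is.null(fs) && abs(fs - fs_file) > 1e-6 * fs)
      stop(sprintf("declared fs = %g Hz contradicts the time column (%g Hz)",
                   fs, fs_file), call. = FALSE)
    fs <- fs_file
  }
  if (is.null(fs))
    stop("sampling rate unresolved: no time column and no 'fs' given",
         call. = FALSE)
  eeg_signal(amp, fs = fs, label = label)
}

#' Write an EEG signal (and optional component columns) to CSV
#'
#' Writes the canonical `time_s,amplitude_uv` layout; extra named series of
#' the same length (per-rhythm ground truth, artifacts, ...) become
#' additional columns.
#'
#' @param x an [eeg_signal()].
#' @param path output file.
#' @param extra optional named list / data.frame of equal-length series.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(x, path, extra = NULL) {
  stopifnot(inherits(x, "eeg_signal"))
  df <- data.frame(time_s = signal_times(x), amplitude_uv = x$samples)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != nrow(df))
      stop("'extra' columns must match the signal length", call. = FALSE)
    df <- cbind(df, extra)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
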