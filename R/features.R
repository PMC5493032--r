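#' Band power of an extracted rhythm
#'
#' `P = sum(V^2) / N` over the time-domain rhythm series, in uV^2 — the mean
#' square amplitude, computed on the extracted series itself rather than by
#' integrating a spectral estimate. `N` is the segment's own sample count.
#'
#' @param x rhythm series (numeric vector or [eeg_signal()]).
#' @return power, uV^2.
#' @examples
#' band_power(c(1, 2, 3)) # 14/3
#' @export
band_power <- function(x) {
  v <- signal_samples(x)
  if (!length(v)) stop("empty series", call. = FALSE)
  sum(v^2) / length(v)
}

#' Classify eyes-open vs eyes-closed from alpha power
#'
#' The alpha rhythm weakens when the eyes open, so a segment whose alpha
#' band power is below the threshold is categorized as eyes-open, and
#' otherwise (including power exactly at the threshold) as eyes-closed.
#' The default threshold of 10 uV^2 separates the two states.
#'
#' @param power band power(s), uV^2 (>= 0); vectorized.
#' @param threshold decision threshold, uV^2; default 10.
#' @return character vector of `"eyes_open"` / `"eyes_closed"`.
#' @examples
#' classify_state(c(9.84, 50.52)) # eyes_open, eyes_closed
#' @export
classify_state <- function(power, threshold = 10) {
  if (any(!is.finite(power)) || any(power < 0))
    stop("'power' must be finite and >= 0", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0)
    stop("'threshold' must be >= 0", call. = FALSE)
  ifelse(power < threshold, "eyes_open", "eyes_closed")
}

#' Classification accuracy
#'
#' Fraction of predictions matching the true labels.
#'
#' @param predictions character vector of predicted states.
#' @param labels character vector of true states, same length.
#' @return accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(predictions, labels) {
  if (!length(labels) || length(predictions) != length(labels))
    stop("'predictions' and 'labels' must have equal positive length",
         call. = FALSE)
  mean(predictions == labels)
}

#' Alpha-power classification report for a set of segments
#'
#' Runs the full adaptive-SSA alpha extraction on each segment, computes its
#' band power and thresholds it into a state; when true labels are given the
#' accuracy is included.
#'
#' @param segments list of [eeg_signal()]s.
#' @param threshold power threshold, uV^2.
#' @param band band to score; default `"alpha"`.
#' @param labels optional character vector of true states.
#' @param ... passed to [adaptive_ssa()] (e.g. `L`, `v0`).
#' @return a `classification_report` list with `band`, `threshold`, `powers`,
#'   `predictions` and (when labelled) `accuracy`.
#' @export
classify_segments <- function(segments, threshold = 10, band = "alpha",
                              labels = NULL, ...) {
  stopifnot(length(segments) > 0)
  powers <- vapply(segments, function(s) {
    res <- adaptive_ssa(s, ...)
    if (!band %in% names(res$rhythms))
      stop(sprintf("band '%s' is not in the band table", band), call. = FALSE)
    band_power(res$rhythms[[band]])
  }, 0)
  predictions <- classify_state(powers, threshold)
  rep <- list(band = band, threshold = threshold, powers = powers,
              predictions = predictions)
  if (!is.null(labels))
    rep$accuracy <- classification_accuracy(predictions, labels)
  structure(rep, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s power, threshold %g uV^2, %d segments\n",
              x$band, x$threshold, length(x$powers)))
  tab <- table(x$predictions)
  cat("  predictions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (!is.null(x$accuracy)) cat(sprintf("  accuracy: %.3f\n", x$accuracy))
  invisible(x)
}
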