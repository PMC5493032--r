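#' Canonical EEG rhythm bands
#'
#' Half-open frequency intervals `[f_low, f_high)`: delta 1-4 Hz, theta
#' 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30 Hz to Nyquist. Half-open
#' intervals make the shared band edges unambiguous.
#'
#' @param fs sampling rate, Hz; sets the gamma band's upper edge at `fs/2`.
#' @return a data.frame with columns `name`, `f_low`, `f_high`.
#' @export
rhythm_bands <- function(fs = 200) {
  bands <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_low = c(1, 4, 8, 13, 30),
    f_high = c(4, 8, 13, 30, fs / 2),
    stringsAsFactors = FALSE)
  bands[bands$f_high > bands$f_low, , drop = FALSE]
}

check_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_low <= 0) || any(bands$f_high <= bands$f_low))
    stop("bands need 0 < f_low < f_high", call. = FALSE)
  b <- bands[order(bands$f_low), ]
  if (nrow(b) > 1 && any(b$f_high[-nrow(b)] > b$f_low[-1] + 1e-12))
    stop("bands must not overlap", call. = FALSE)
  invisible(bands)
}

#' Number of leading RCs to remove as artifacts
#'
#' The adaptive rule: when the signal amplitude `max |s|` reaches the
#' threshold `v0` the artifact level is high and the first two reconstructed
#' components are removed; otherwise only the first. The default threshold
#' of 200 uV is set at twice the usual sub-100 uV amplitude of spontaneous
#' artifact-free EEG; amplitude exactly at the threshold takes the two-RC
#' branch (conservative removal), and the amplitude is measured on `|s|`
#' because EEG is bipolar.
#'
#' @param x an [eeg_signal()] or numeric vector.
#' @param v0 amplitude threshold, uV (> 0); default 200.
#' @return integer, 1 or 2.
#' @export
artifact_rc_count <- function(x, v0 = 200) {
  s <- signal_samples(x)
  if (!length(s)) stop("empty signal", call. = FALSE)
  if (!is.finite(v0) && !identical(v0, Inf))
    stop("'v0' must be a positive number (Inf allowed)", call. = FALSE)
  if (v0 <= 0) stop("'v0' must be > 0", call. = FALSE)
  if (max(abs(s)) >= v0) 2L else 1L
}

#' Remove the leading artifact components from a signal
#'
#' Sums the first [artifact_rc_count()] reconstructed components into the
#' artifact estimate and subtracts it; `corrected + artifact` equals the
#' input exactly.
#'
#' @param decomp an [ssa()] decomposition of the signal.
#' @param x the signal the decomposition came from (defaults to the series
#'   stored in `decomp`).
#' @param v0 amplitude threshold, uV.
#' @return list with `corrected` and `artifact` ([eeg_signal()]s) and
#'   `n_artifact` (1 or 2).
#' @export
remove_artifacts <- function(decomp, x = NULL, v0 = 200) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  s <- if (is.null(x)) decomp$series else signal_samples(x)
  if (length(s) != decomp$N)
    stop("signal length does not match the decomposition", call. = FALSE)
  k <- artifact_rc_count(s, v0)
  artifact <- rowSums(decomp$rcs[, seq_len(k), drop = FALSE])
  list(corrected = eeg_signal(s - artifact, decomp$fs),
       artifact = eeg_signal(artifact, decomp$fs),
       n_artifact = k)
}

#' Pair reconstructed components by eigenvalue similarity
#'
#' A periodic (sinusoidal) component appears in SSA as a pair of RCs with
#' nearly equal eigenvalues. Scanning the non-excluded indices in descending
#' eigenvalue order, adjacent indices `(i, i+1)` are greedily paired when
#' `|1 - lam[i+1] / lam[i]| < tol`; each index joins at most one pair and
#' unpaired indices remain lone RCs. Pairing is restricted to adjacent
#' indices — the standard SSA convention for sinusoid pairs, which also
#' prevents chaining runs of similar eigenvalues into one blob.
#'
#' @param lam eigenvalues in non-increasing order.
#' @param exclude indices to skip (e.g. artifact RCs, excluded before
#'   pairing).
#' @param tol relative-eigenvalue tolerance; default 0.05.
#' @return list of integer pairs `c(i, i + 1)`.
#' @examples
#' pair_eigenvalues(c(10, 9.8, 5)) # list(c(1, 2))
#' @export
pair_eigenvalues <- function(lam, exclude = integer(), tol = 0.05) {
  if (is.unsorted(rev(lam)))
    stop("'lam' must be non-increasing", call. = FALSE)
  idx <- setdiff(seq_along(lam), exclude)
  pairs <- list()
  k <- 1L
  while (k < length(idx)) {
    i <- idx[k]; j <- idx[k + 1L]
    if (j == i + 1L && lam[i] > 0 && abs(1 - lam[j] / lam[i]) < tol) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      k <- k + 2L
    } else {
      k <- k + 1L
    }
  }
  pairs
}

#' Peak frequency of a component's Fourier spectrum
#'
#' `f_max = argmax_{f > 0} |FFT(x)|`, with the series zero-padded to at
#' least `pad_factor` times its length for frequency resolution. The DC bin
#' is excluded (a residual offset must not masquerade as a rhythm) and ties
#' break toward the lower frequency.
#'
#' @param x numeric series (length >= 2, not constant).
#' @param fs sampling rate, Hz.
#' @param pad_factor zero-padding factor; default 4.
#' @return peak frequency, Hz (in `(0, fs/2]`).
#' @examples
#' peak_frequency(sin(2 * pi * 10 * (0:1599) / 200), fs = 200) # 10 Hz
#' @export
peak_frequency <- function(x, fs, pad_factor = 4) {
  x <- signal_samples(x)
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (fs <= 0) stop("'fs' must be > 0", call. = FALSE)
  if (max(x) == min(x))
    stop("peak frequency of a constant series is undefined", call. = FALSE)
  nfft <- as.integer(ceiling(pad_factor) * length(x))
  spec <- Mod(fft(c(x, numeric(nfft - length(x)))))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  keep <- f > 0 & f <= fs / 2
  f[keep][which.max(spec[keep])]
}

#' Group the reconstructed components of a decomposition
#'
#' Applies the full adaptive grouping rule: (1) the first one or two RCs are
#' flagged as artifacts from the signal amplitude; (2) remaining RCs are
#' paired into periodic components by eigenvalue similarity; (3) every group
#' (pair or lone RC) gets the peak frequency of its summed series and is
#' assigned to the rhythm band containing it, or left unassigned when its
#' peak falls outside every band (such groups are reported and dropped from
#' the rhythms). Groups whose series is identically constant (zero
#' eigenvalue) have no defined peak and are unassigned.
#'
#' @param decomp an [ssa()] decomposition.
#' @param v0 artifact amplitude threshold, uV; `Inf` disables artifact
#'   removal entirely (no RC is flagged).
#' @param tol eigenvalue-pairing tolerance.
#' @param bands band table from [rhythm_bands()].
#' @return an object of class `ssa_grouping`: list with `artifact_indices`,
#'   `pairs`, `groups` (list of integer index vectors covering every
#'   non-artifact RC exactly once), `peak_freqs`, `band_assignment`
#'   (band name or `NA` per group), `threshold_v0`, `tol`.
#' @export
group_rcs <- function(decomp, v0 = 200, tol = 0.05,
                      bands = rhythm_bands(decomp$fs)) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  check_bands(bands)
  art <- if (identical(v0, Inf)) integer() else
    seq_len(artifact_rc_count(decomp$series, v0))
  pairs <- pair_eigenvalues(decomp$lam, exclude = art, tol = tol)
  paired <- unlist(pairs)
  lone <- setdiff(seq_len(decomp$L), c(art, paired))
  groups <- c(pairs, as.list(lone))
  # keep groups in descending-eigenvalue order of their leading index
  groups <- groups[order(vapply(groups, min, 1L))]
  peak <- rep(NA_real_, length(groups))
  assign <- rep(NA_character_, length(groups))
  for (g in seq_along(groups)) {
    comp <- rowSums(decomp$rcs[, groups[[g]], drop = FALSE])
    if (max(comp) == min(comp)) next  # degenerate: no defined peak
    fm <- peak_frequency(comp, decomp$fs)
    peak[g] <- fm
    hit <- which(bands$f_low <= fm & fm < bands$f_high)
    if (length(hit)) assign[g] <- bands$name[hit[1]]
  }
  structure(list(artifact_indices = art, pairs = pairs, groups = groups,
                 peak_freqs = peak, band_assignment = assign,
                 threshold_v0 = v0, tol = tol, bands = bands),
            class = "ssa_grouping")
}

#' @export
print.ssa_grouping <- function(x, ...) {
  cat(sprintf("<ssa_grouping> %d artifact RC(s): %s; %d pairs, %d groups\n",
              length(x$artifact_indices),
              paste(x$artifact_indices, collapse = ","),
              length(x$pairs), length(x$groups)))
  tab <- table(x$band_assignment, useNA = "ifany")
  cat("  groups per band:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Assemble rhythm series from grouped components
#'
#' Sums, for every rhythm band, the series of all groups assigned to it.
#' Bands with no group get an all-zero series, so the output always has one
#' column per band. Unassigned groups are summed into the `residue` series;
#' artifact RCs, band rhythms and residue partition the signal exactly.
#'
#' @param decomp an [ssa()] decomposition.
#' @param grouping an [group_rcs()] result for `decomp` (computed with
#'   defaults when missing).
#' @return list with `rhythms` (named list of numeric series, one per
#'   band), `residue` (series of unassigned groups), `dropped_groups`
#'   (their RC indices), and `grouping`.
#' @export
extract_rhythms <- function(decomp, grouping = group_rcs(decomp)) {
  stopifnot(inherits(decomp, "ssa_decomposition"),
            inherits(grouping, "ssa_grouping"))
  bands <- grouping$bands
  rhythms <- stats::setNames(
    rep(list(numeric(decomp$N)), nrow(bands)), bands$name)
  residue <- numeric(decomp$N)
  dropped <- list()
  for (g in seq_along(grouping$groups)) {
    comp <- rowSums(decomp$rcs[, grouping$groups[[g]], drop = FALSE])
    band <- grouping$band_assignment[g]
    if (is.na(band)) {
      residue <- residue + comp
      dropped[[length(dropped) + 1L]] <- grouping$groups[[g]]
    } else {
      rhythms[[band]] <- rhythms[[band]] + comp
    }
  }
  list(rhythms = rhythms, residue = residue, dropped_groups = dropped,
       grouping = grouping)
}

#' Adaptive SSA: denoise a signal and extract its rhythms
#'
#' The umbrella operation: SSA decomposition, adaptive artifact removal,
#' eigenvalue pairing, band assignment by Fourier peak, and rhythm
#' assembly. The returned pieces satisfy
#' `artifact + sum(rhythms) + residue == signal` exactly.
#'
#' @param x an [eeg_signal()] (or numeric vector plus `fs`).
#' @param L window length; default 40 (0.2 s at 200 Hz).
#' @param v0 artifact amplitude threshold, uV; default 200. Use `Inf` to
#'   disable artifact removal.
#' @param tol eigenvalue-pairing tolerance; default 0.05.
#' @param bands band table; default [rhythm_bands()] at the signal's rate.
#' @param fs sampling rate when `x` is a plain vector.
#' @param f_low optional lowest frequency of interest, Hz; when given, a
#'   window shorter than one period of it (`L < fs / f_low`) triggers a
#'   warning and the run proceeds.
#' @param verbose log every grouping decision with `message()`.
#' @return an object of class `adaptive_ssa`: list with `signal`,
#'   `decomposition`, `grouping`, `corrected`, `artifact` (both
#'   [eeg_signal()]s), `rhythms` (named list of series), `residue`.
#' @examples
#' sim <- simulate_contaminated_eeg(mpa_config(seed = 4),
#'                                  artifact_config(seed = 5))
#' res <- adaptive_ssa(sim$signal)
#' res$grouping$artifact_indices
#' cor(res$rhythms$alpha, sim$components[, "alpha"])
#' @export
adaptive_ssa <- function(x, L = 40, v0 = 200, tol = 0.05, bands = NULL,
                         fs = NULL, f_low = NULL, verbose = FALSE) {
  sig <- as_eeg_signal(x, fs)
  if (is.null(bands)) bands <- rhythm_bands(sig$fs)
  decomp <- ssa(sig, L = L, f_low = f_low)
  grouping <- group_rcs(decomp, v0 = v0, tol = tol, bands = bands)
  removal <- if (identical(v0, Inf)) {
    list(corrected = sig,
         artifact = eeg_signal(rep(0, n_samples(sig)), sig$fs),
         n_artifact = 0L)
  } else {
    remove_artifacts(decomp, sig, v0 = v0)
  }
  ext <- extract_rhythms(decomp, grouping)
  if (verbose) {
    message(sprintf("artifact RCs removed: %s (max |s| = %.1f uV, V0 = %g)",
                    paste(grouping$artifact_indices, collapse = ","),
                    max(abs(sig$samples)), v0))
    message(sprintf("eigenvalue pairs: %s",
                    paste(vapply(grouping$pairs, paste, "", collapse = "-"),
                          collapse = " ")))
    for (g in seq_along(grouping$groups))
      message(sprintf("group {%s}: f_max = %s Hz -> %s",
                      paste(grouping$groups[[g]], collapse = ","),
                      formatC(grouping$peak_freqs[g], digits = 3),
                      ifelse(is.na(grouping$band_assignment[g]), "dropped",
                             grouping$band_assignment[g])))
  }
  structure(list(signal = sig, decomposition = decomp, grouping = grouping,
                 corrected = removal$corrected, artifact = removal$artifact,
                 rhythms = ext$rhythms, residue = ext$residue,
                 dropped_groups = ext$dropped_groups),
            class = "adaptive_ssa")
}

#' @export
print.adaptive_ssa <- function(x, ...) {
  cat(sprintf("<adaptive_ssa> N = %d @ %g Hz, L = %d\n",
              x$decomposition$N, x$decomposition$fs, x$decomposition$L))
  cat(sprintf("  max |input| = %.1f uV -> %d artifact RC(s) removed, max |corrected| = %.1f uV\n",
              max(abs(x$signal$samples)),
              length(x$grouping$artifact_indices),
              max(abs(x$corrected$samples))))
  pw <- vapply(x$rhythms, function(r) mean(r^2), 0)
  cat("  band powers (uV^2):",
      paste(names(pw), sprintf("%.2f", pw), sep = "=", collapse = " "), "\n")
  invisible(x)
}
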