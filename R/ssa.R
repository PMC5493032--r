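#' Hankel trajectory matrix of a signal
#'
#' Embeds the series `s` into the `L x K` trajectory matrix with
#' `X[i, j] = s[i + j - 1]` and `K = N - L + 1` (each column a lagged window
#' of length `L`). Every anti-diagonal of the result is constant.
#'
#' @param x an [eeg_signal()] or numeric vector.
#' @param L window length (embedding dimension), `2 <= L <= N - 1`.
#' @return an `L x K` numeric matrix of class `trajectory_matrix` with
#'   attribute `L`.
#' @examples
#' trajectory_matrix(1:5, L = 3)
#' @export
trajectory_matrix <- function(x, L) {
  s <- signal_samples(x)
  N <- length(s)
  L <- as.integer(L)
  if (L < 2L || L > N - 1L)
    stop(sprintf("window length L must satisfy 2 <= L <= N-1 (N = %d)", N),
         call. = FALSE)
  K <- N - L + 1L
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- s[i:(i + K - 1L)]
  structure(X, L = L, class = c("trajectory_matrix", "matrix", "array"))
}

#' Singular value decomposition of a trajectory matrix
#'
#' Computes the eigentriples `(lambda_i, v_i, p_i)` of the SSA
#' decomposition `X = sum_i sqrt(lambda_i) v_i p_i^T`, where `lambda_i` are
#' the eigenvalues of the lag-covariance matrix `C = X X^T` in non-increasing
#' order, `v_i` its unit eigenvectors and `p_i = X^T v_i / sqrt(lambda_i)`.
#' Computed via the SVD of `X` directly (`lambda_i` = squared singular
#' value), which is numerically equivalent and better conditioned than
#' forming `C`.
#'
#' @param X a [trajectory_matrix()] (any finite numeric matrix is accepted).
#' @return an object of class `ssa_svd`: list with `lam` (length-L vector of
#'   eigenvalues, non-increasing), `v` (L x L matrix of left vectors) and
#'   `p` (K x L matrix of right factors; columns for zero eigenvalues are
#'   zero by convention, making the corresponding elementary matrices zero).
#' @export
ssa_decompose <- function(X) {
  if (!is.matrix(X) || !all(is.finite(X)))
    stop("'X' must be a finite numeric matrix", call. = FALSE)
  L <- nrow(X)
  r <- min(dim(X))
  sv <- svd(X, nu = L)
  # C = X X^T is L x L, so there are L eigenvalues; when L > K the trailing
  # L - K of them are exactly zero and their elementary matrices vanish
  lam <- numeric(L)
  lam[seq_len(r)] <- sv$d^2
  p <- matrix(0, ncol(X), L)
  p[, seq_len(r)] <- sv$v
  zero <- lam <= max(lam, 0) * .Machine$double.eps * max(dim(X))
  p[, zero] <- 0
  structure(list(lam = lam, v = sv$u, p = p), class = "ssa_svd")
}

#' Diagonal averaging (Hankelization) of a matrix
#'
#' Averages every anti-diagonal of an `L x K` matrix into one sample,
#' producing a series of length `N = L + K - 1`. This is the standard SSA
#' reconstruction step (the nearest-Hankel projection followed by reading
#' off the series); applied to a trajectory matrix it returns the original
#' signal exactly, and it is linear in its argument.
#'
#' @param M numeric matrix.
#' @return numeric vector of length `nrow(M) + ncol(M) - 1`.
#' @examples
#' diagonal_average(matrix(1:4, 2, byrow = TRUE)) # 1, 2.5, 4
#' @export
diagonal_average <- function(M) {
  if (!is.matrix(M) || !all(is.finite(M)))
    stop("'M' must be a finite numeric matrix", call. = FALSE)
  L <- nrow(M); K <- ncol(M); N <- L + K - 1L
  sums <- as.numeric(
    tapply(M, (row(M) + col(M))[seq_along(M)], sum))
  sums / pmin(seq_len(N), L, K, N - seq_len(N) + 1L)
}

# anti-diagonal element counts of an L x K matrix
antidiag_counts <- function(L, K) {
  N <- L + K - 1L
  pmin(seq_len(N), L, K, N - seq_len(N) + 1L)
}

# diagonal average of the rank-1 matrix u %*% t(w) via convolution:
# sum over i+j = t+1 of u[i] w[j] is the (open) convolution of u and w
rank1_diagonal_average <- function(u, w, counts) {
  convolve(u, rev(w), type = "open") / counts
}

#' Full singular spectrum analysis of a signal
#'
#' Embeds the signal (window length `L`, default 40), performs the SVD, and
#' diagonal-averages every elementary matrix `sqrt(lambda_i) v_i p_i^T`
#' into a reconstructed component (RC). The `L` RCs sum to the input signal
#' exactly (up to floating-point error); grouping utilities
#' ([adaptive_ssa()], [group_rcs()]) operate on the returned object.
#'
#' The window should span at least one period of the slowest component of
#' interest (`L >= fs / f_low`); a shorter window triggers a warning via
#' `f_low`.
#'
#' @param x an [eeg_signal()] (or numeric vector plus `fs`).
#' @param L window length; default 40.
#' @param fs sampling rate when `x` is a plain vector.
#' @param f_low optional lowest frequency of interest, Hz; when supplied and
#'   `L < fs / f_low` a warning is emitted (the run proceeds).
#' @return an object of class `ssa_decomposition`: list with `lam`
#'   (eigenvalues, non-increasing), `v`, `p` (singular vectors), `rcs`
#'   (N x L matrix, column i = RC i), `series` (the input samples), `L`,
#'   `N`, `fs`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 10 * (0:399) / 200), fs = 200)
#' d <- ssa(s, L = 40)
#' max(abs(rowSums(d$rcs) - s$samples)) # exact decomposition
#' @export
ssa <- function(x, L = 40, fs = NULL, f_low = NULL) {
  sig <- as_eeg_signal(x, fs)
  if (!is.null(f_low) && L < sig$fs / f_low)
    warning(sprintf(
      "window L = %d is shorter than one period of f_low = %g Hz (fs/f_low = %.1f samples)",
      L, f_low, sig$fs / f_low), call. = FALSE)
  X <- trajectory_matrix(sig, L)
  dec <- ssa_decompose(X)
  N <- n_samples(sig)
  counts <- antidiag_counts(nrow(X), ncol(X))
  rcs <- matrix(0, N, L)
  for (i in seq_len(L)) {
    if (dec$lam[i] > 0)
      rcs[, i] <- rank1_diagonal_average(sqrt(dec$lam[i]) * dec$v[, i],
                                         dec$p[, i], counts)
  }
  colnames(rcs) <- paste0("rc", seq_len(L))
  structure(list(lam = dec$lam, v = dec$v, p = dec$p, rcs = rcs,
                 series = sig$samples, L = as.integer(L), N = N,
                 fs = sig$fs),
            class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat(sprintf("<ssa_decomposition> N = %d, L = %d, fs = %g Hz\n",
              x$N, x$L, x$fs))
  share <- cumsum(x$lam) / sum(x$lam)
  cat(sprintf("  leading eigenvalue shares: %s\n",
              paste(sprintf("%.1f%%", 100 * head(x$lam / sum(x$lam), 5)),
                    collapse = " ")))
  cat(sprintf("  components for 99%% energy: %d\n", which(share >= 0.99)[1]))
  invisible(x)
}
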