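# Independent brute-force SSA oracle: explicit lag-covariance
# eigendecomposition and naive anti-diagonal averaging loops. Kept free of
# the production code paths (no trajectory_matrix / convolve shortcut).

brute_trajectory <- function(s, L) {
  K <- length(s) - L + 1
  outer(seq_len(L), seq_len(K), function(i, j) s[i + j - 1])
}

brute_diag_average <- function(M) {
  L <- nrow(M); K <- ncol(M); N <- L + K - 1
  out <- numeric(N)
  for (t in seq_len(N)) {
    vals <- c()
    for (i in seq_len(L)) {
      j <- t - i + 1
      if (j >= 1 && j <= K) vals <- c(vals, M[i, j])
    }
    out[t] <- mean(vals)
  }
  out
}

brute_ssa <- function(s, L) {
  X <- brute_trajectory(s, L)
  C <- X %*% t(X)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  rcs <- matrix(0, length(s), L)
  for (i in seq_len(L)) {
    if (lam[i] <= max(lam) * 1e-12) next
    v <- e$vectors[, i]
    p <- drop(t(X) %*% v) / sqrt(lam[i])
    rcs[, i] <- brute_diag_average(sqrt(lam[i]) * v %*% t(p))
  }
  list(lam = lam, rcs = rcs)
}

# pure tone helper on the package's sample grid
sinusoid <- function(freq, amp = 1, n = 1600, fs = 200, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}
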