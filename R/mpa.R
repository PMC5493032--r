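#' Parameters of one MPA rhythm
#'
#' In the Markov Process Amplitude (MPA) model each rhythm is a sinusoid at a
#' dominant frequency `m` whose instantaneous amplitude follows a first-order
#' Gauss-Markov (AR(1)) process: `a[k+1] = gamma * a[k] + xi[k]` with
#' `xi ~ N(0, sigma_xi^2)`. `sigma_xi` is interpreted as the standard
#' deviation of the Gaussian increment, in uV; this reading keeps the summed
#' spontaneous EEG in the physiological sub-100 uV amplitude regime.
#'
#' @param name rhythm label (`"delta"`, `"theta"`, `"alpha"`, `"beta"`).
#' @param m dominant frequency, Hz (> 0).
#' @param sigma_xi standard deviation of the amplitude increment, uV (>= 0).
#' @param gamma AR(1) coefficient, `0 <= gamma < 1` (stationarity).
#' @param theta initial phase in radians, in `[0, 2*pi)`, or `NA` to draw it
#'   uniformly from the seeded generator at simulation time.
#' @return a `rhythm_params` list.
#' @export
rhythm_params <- function(name, m, sigma_xi, gamma, theta = NA_real_) {
  name <- match.arg(name, c("delta", "theta", "alpha", "beta"))
  if (!is.finite(m) || m <= 0) stop("'m' must be > 0 (Hz)", call. = FALSE)
  if (!is.finite(sigma_xi) || sigma_xi < 0)
    stop("'sigma_xi' must be >= 0 (uV)", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0 || gamma >= 1)
    stop("'gamma' must satisfy 0 <= gamma < 1 (stable AR(1))", call. = FALSE)
  if (!is.na(theta) && (theta < 0 || theta >= 2 * pi))
    stop("'theta' must lie in [0, 2*pi)", call. = FALSE)
  structure(list(name = name, m = m, sigma_xi = sigma_xi, gamma = gamma,
                 theta = theta),
            class = "rhythm_params")
}

#' Default rhythm parameter set of the spontaneous-EEG simulator
#'
#' Four rhythms (delta 3.61 Hz, theta 5.76 Hz, alpha 10.45 Hz, beta
#' 16.02 Hz) with increment scales (3.86, 1.23, 1.57, 0.92) uV and AR(1)
#' coefficients (0.97, 0.99, 0.99, 0.98), the parameter set fitted to the
#' power spectrum of a resting real EEG that this simulator emulates.
#'
#' @return list of four `rhythm_params`.
#' @export
default_rhythms <- function() {
  list(rhythm_params("delta", 3.61, 3.86, 0.97),
       rhythm_params("theta", 5.76, 1.23, 0.99),
       rhythm_params("alpha", 10.45, 1.57, 0.99),
       rhythm_params("beta", 16.02, 0.92, 0.98))
}

#' Configuration of the spontaneous-EEG (MPA) simulator
#'
#' @param rhythms list of [rhythm_params()]; its length is the number of
#'   superposed oscillations.
#' @param duration segment length, seconds; default 8 s.
#' @param dt sample interval, seconds; default 0.005 s (200 Hz). `duration /
#'   dt` must be a whole number of samples.
#' @param seed integer seed for the amplitude processes and any drawn phases,
#'   or `NULL` to use the current RNG state.
#' @return an `mpa_config` list with an added `n` element (sample count).
#' @export
mpa_config <- function(rhythms = default_rhythms(), duration = 8,
                       dt = 0.005, seed = NULL) {
  if (!length(rhythms) || !all(vapply(rhythms, inherits, TRUE, "rhythm_params")))
    stop("'rhythms' must be a non-empty list of rhythm_params", call. = FALSE)
  if (duration <= 0 || dt <= 0)
    stop("'duration' and 'dt' must be positive", call. = FALSE)
  n <- duration / dt
  if (abs(n - round(n)) > 1e-8 || round(n) < 1)
    stop("duration/dt must be a positive integer sample count", call. = FALSE)
  structure(list(rhythms = rhythms, duration = duration, dt = dt,
                 seed = seed, n = as.integer(round(n))),
            class = "mpa_config")
}

#' Configuration of the simulated artifacts
#'
#' The artifact model is a periodic train of symmetric (isosceles) triangular
#' EOG pulses, a sinusoidal baseline drift, and white Gaussian measurement
#' noise.
#'
#' @param v_eog EOG pulse peak amplitude, uV (default 400).
#' @param t_eog pulse period, seconds (default 3).
#' @param pw_eog pulse base width, seconds (default 0.3); must be < `t_eog`.
#' @param v_bl baseline-drift amplitude, uV (default 20).
#' @param f_bl baseline-drift frequency, Hz (default 0.5).
#' @param noise_sd white-noise standard deviation, uV (default 2).
#' @param seed integer seed for the noise draw, or `NULL`.
#' @return an `artifact_config` list.
#' @export
artifact_config <- function(v_eog = 400, t_eog = 3, pw_eog = 0.3,
                            v_bl = 20, f_bl = 0.5, noise_sd = 2,
                            seed = NULL) {
  if (min(v_eog, v_bl, noise_sd) < 0 || f_bl < 0)
    stop("artifact amplitudes and frequencies must be >= 0", call. = FALSE)
  if (t_eog <= 0 || pw_eog < 0)
    stop("'t_eog' must be > 0 and 'pw_eog' >= 0", call. = FALSE)
  if (pw_eog >= t_eog)
    stop("EOG pulses overlap: 'pw_eog' must be smaller than 't_eog'",
         call. = FALSE)
  structure(list(v_eog = v_eog, t_eog = t_eog, pw_eog = pw_eog,
                 v_bl = v_bl, f_bl = f_bl, noise_sd = noise_sd, seed = seed),
            class = "artifact_config")
}

# run code under a temporary seed without disturbing the caller's RNG
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate a first-order Gauss-Markov amplitude process
#'
#' `a[k+1] = gamma * a[k] + xi[k]`, `xi ~ N(0, sigma_xi^2)`. The initial
#' value is drawn from the stationary distribution
#' `N(0, sigma_xi^2 / (1 - gamma^2))` so the series needs no burn-in; it can
#' be pinned with `a0` (useful for deterministic checks).
#'
#' @param gamma AR(1) coefficient, `0 <= gamma < 1`.
#' @param sigma_xi increment standard deviation, uV (>= 0).
#' @param n number of samples (>= 1).
#' @param seed integer seed or `NULL`.
#' @param a0 optional fixed initial amplitude; overrides the stationary draw.
#' @return numeric amplitude series of length `n`, uV.
#' @examples
#' # stationary variance of the alpha amplitude: 1.57^2 / (1 - 0.99^2)
#' a <- simulate_markov_amplitude(0.99, 1.57, 1e4, seed = 1)
#' var(a)
#' @export
simulate_markov_amplitude <- function(gamma, sigma_xi, n, seed = NULL,
                                      a0 = NULL) {
  if (!is.finite(gamma) || gamma < 0 || gamma >= 1)
    stop("'gamma' must satisfy 0 <= gamma < 1 (stable AR(1))", call. = FALSE)
  if (!is.finite(sigma_xi) || sigma_xi < 0)
    stop("'sigma_xi' must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  with_seed_(seed, {
    if (is.null(a0))
      a0 <- rnorm(1L, 0, sigma_xi / sqrt(1 - gamma^2))
    if (n == 1L) {
      a0
    } else {
      xi <- rnorm(n - 1L, 0, sigma_xi)
      rest <- stats::filter(xi, gamma, method = "recursive", init = a0)
      c(a0, as.numeric(rest))
    }
  })
}

#' Simulate spontaneous EEG from the MPA model
#'
#' The signal is the superposition `s(n dt) = sum_i a_i(n dt) *
#' sin(2*pi*m_i*n*dt + theta_i)` over the configured rhythms, each amplitude
#' `a_i` an independent Gauss-Markov process. Per-rhythm terms are returned
#' as ground truth for extraction experiments.
#'
#' Determinism: under a fixed `config$seed` the rhythms are simulated in
#' order, drawing for each first its phase (when `theta` is `NA`), then its
#' amplitude series; identical configs give bit-identical output.
#'
#' @param config an [mpa_config()].
#' @return an object of class `mpa_simulation`: list with `signal` (an
#'   [eeg_signal()] labelled `"synthetic"`), `components` (N x K matrix of
#'   the individual rhythm terms, columns named by rhythm), `phases`, and
#'   `config`.
#' @export
simulate_spontaneous_eeg <- function(config = mpa_config()) {
  stopifnot(inherits(config, "mpa_config"))
  n <- config$n
  t <- (seq_len(n) - 1) * config$dt
  sim <- with_seed_(config$seed, {
    comps <- matrix(0, n, length(config$rhythms))
    phases <- numeric(length(config$rhythms))
    for (i in seq_along(config$rhythms)) {
      r <- config$rhythms[[i]]
      th <- if (is.na(r$theta)) runif(1L, 0, 2 * pi) else r$theta
      a <- simulate_markov_amplitude(r$gamma, r$sigma_xi, n)
      comps[, i] <- a * sin(2 * pi * r$m * t + th)
      phases[i] <- th
    }
    list(comps = comps, phases = phases)
  })
  colnames(sim$comps) <- vapply(config$rhythms, `[[`, "", "name")
  names(sim$phases) <- colnames(sim$comps)
  structure(list(signal = eeg_signal(rowSums(sim$comps), fs = 1 / config$dt,
                                     label = "synthetic"),
                 components = sim$comps, phases = sim$phases,
                 config = config),
            class = "mpa_simulation")
}

#' Simulate the EOG artifact as a triangular pulse train
#'
#' Symmetric triangular pulses of peak value `v_eog` and base width
#' `pw_eog`, one pulse per period `t_eog`, the first pulse starting at
#' t = 0; zero between pulses. Emulates eye blinks (about one 0.3 s blink
#' every 3 s in a relaxed subject).
#'
#' @param cfg an [artifact_config()].
#' @param duration segment length, s.
#' @param dt sample interval, s.
#' @return numeric series, uV.
#' @export
simulate_eog <- function(cfg = artifact_config(), duration = 8, dt = 0.005) {
  stopifnot(inherits(cfg, "artifact_config"))
  t <- seq(0, duration - dt / 2, by = dt)
  ph <- t %% cfg$t_eog
  out <- numeric(length(t))
  if (cfg$pw_eog > 0) {
    in_pulse <- ph < cfg$pw_eog
    out[in_pulse] <- cfg$v_eog * (1 - abs(2 * ph[in_pulse] / cfg$pw_eog - 1))
  }
  out
}

#' Simulate sinusoidal baseline drift
#'
#' `v_bl * sin(2*pi*f_bl*t)` on the sample grid; a slow electro-potential
#' shift from head or body movement.
#'
#' @inheritParams simulate_eog
#' @return numeric series, uV.
#' @export
simulate_baseline <- function(cfg = artifact_config(), duration = 8,
                              dt = 0.005) {
  stopifnot(inherits(cfg, "artifact_config"))
  t <- seq(0, duration - dt / 2, by = dt)
  cfg$v_bl * sin(2 * pi * cfg$f_bl * t)
}

#' Simulate artifact-contaminated EEG
#'
#' Sum of the spontaneous MPA EEG, the EOG pulse train, the baseline drift
#' and white Gaussian noise, with every addend returned separately so
#' downstream removal and extraction can be scored against ground truth.
#' The contaminated samples are computed as the row sums of the returned
#' addends, so `signal - rowSums(cbind(components, artifacts))` is exactly
#' zero.
#'
#' @param mpa an [mpa_config()] (its `seed` drives the spontaneous part).
#' @param art an [artifact_config()] (its `seed` drives the noise draw).
#' @return an object of class `contaminated_simulation`: list with `signal`
#'   (an [eeg_signal()]), `spontaneous` (the clean [eeg_signal()]),
#'   `components` (rhythm terms), `artifacts` (N x 3 matrix with columns
#'   `eog`, `baseline`, `noise`), and both configs.
#' @examples
#' sim <- simulate_contaminated_eeg(mpa_config(seed = 1),
#'                                  artifact_config(seed = 2))
#' max(abs(sim$signal$samples))
#' @export
simulate_contaminated_eeg <- function(mpa = mpa_config(),
                                      art = artifact_config()) {
  stopifnot(inherits(mpa, "mpa_config"), inherits(art, "artifact_config"))
  spont <- simulate_spontaneous_eeg(mpa)
  eog <- simulate_eog(art, mpa$duration, mpa$dt)
  bl <- simulate_baseline(art, mpa$duration, mpa$dt)
  noise <- with_seed_(art$seed, rnorm(mpa$n, 0, art$noise_sd))
  artifacts <- cbind(eog = eog, baseline = bl, noise = noise)
  samples <- rowSums(cbind(spont$components, artifacts))
  structure(list(signal = eeg_signal(samples, fs = 1 / mpa$dt,
                                     label = "synthetic"),
                 spontaneous = spont$signal,
                 components = spont$components,
                 phases = spont$phases,
                 artifacts = artifacts,
                 mpa = mpa, art = art),
            class = "contaminated_simulation")
}

#' @export
print.mpa_simulation <- function(x, ...) {
  cat(sprintf("<mpa_simulation> %d rhythms, %d samples @ %g Hz\n",
              ncol(x$components), n_samples(x$signal), x$signal$fs))
  invisible(x)
}

#' @export
print.contaminated_simulation <- function(x, ...) {
  cat(sprintf(
    "<contaminated_simulation> %d samples @ %g Hz, max |s| = %.1f uV\n",
    n_samples(x$signal), x$signal$fs, max(abs(x$signal$samples))))
  invisible(x)
}
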