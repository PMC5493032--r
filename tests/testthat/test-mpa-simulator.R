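test_that("Gauss-Markov amplitude has the AR(1) stationary variance", {
  # white-noise limit: gamma = 0 reduces to iid N(0, 1)
  a0 <- simulate_markov_amplitude(0, 1, 1e5, seed = 11)
  expect_equal(var(a0), 1, tolerance = 0.05)
  # alpha-rhythm parameters: var = 1.57^2 / (1 - 0.99^2) = 123.86
  a <- simulate_markov_amplitude(0.99, 1.57, 1e6, seed = 12)
  expect_equal(var(a), 1.57^2 / (1 - 0.99^2), tolerance = 0.05)
})

test_that("amplitude recursion is exact when the increment is zero", {
  a <- simulate_markov_amplitude(0.5, 0, 10, a0 = 8)
  expect_equal(a, 8 * 0.5^(0:9))
  # zero increment without a pinned start decays from a zero stationary draw
  expect_equal(simulate_markov_amplitude(0.5, 0, 5, seed = 1), rep(0, 5))
})

test_that("amplitude parameters are validated", {
  expect_error(simulate_markov_amplitude(1, 1, 10), "gamma")
  expect_error(simulate_markov_amplitude(-0.1, 1, 10), "gamma")
  expect_error(simulate_markov_amplitude(0.5, -1, 10), "sigma_xi")
  expect_error(rhythm_params("alpha", -1, 1, 0.5), "'m'")
  expect_error(rhythm_params("alpha", 10, 1, 1.0), "gamma")
})

test_that("spontaneous EEG has the configured geometry and is seeded", {
  sim <- simulate_spontaneous_eeg(mpa_config(seed = 3))
  expect_s3_class(sim$signal, "eeg_signal")
  expect_identical(n_samples(sim$signal), 1600L)
  expect_equal(sim$signal$fs, 200)
  expect_identical(colnames(sim$components),
                   c("delta", "theta", "alpha", "beta"))
  # bit-identical under the same seed, different under another
  sim2 <- simulate_spontaneous_eeg(mpa_config(seed = 3))
  expect_identical(sim$signal$samples, sim2$signal$samples)
  sim3 <- simulate_spontaneous_eeg(mpa_config(seed = 4))
  expect_false(identical(sim$signal$samples, sim3$signal$samples))
  # the signal is exactly the superposition of the rhythm terms
  expect_identical(sim$signal$samples, rowSums(sim$components))
})

test_that("zero increment scales produce the zero signal", {
  quiet <- lapply(default_rhythms(), function(r)
    rhythm_params(r$name, r$m, 0, r$gamma, theta = 0))
  sim <- simulate_spontaneous_eeg(mpa_config(rhythms = quiet, seed = 1))
  expect_equal(sim$signal$samples, rep(0, 1600))
})

test_that("each simulated rhythm peaks at its dominant frequency", {
  m <- c(delta = 3.61, theta = 5.76, alpha = 10.45, beta = 16.02)
  pks <- t(sapply(1:20, function(s) {
    sp <- simulate_spontaneous_eeg(mpa_config(seed = s))
    vapply(colnames(sp$components),
           function(nm) peak_frequency(sp$components[, nm], 200), 0)
  }))
  # the Markov amplitude modulates the tone, so individual seeds wander;
  # the median over seeds must sit within one intrinsic FFT bin (fs/N)
  expect_lt(max(abs(apply(pks, 2, median) - m)), 200 / 1600)
})

test_that("EOG pulse train has the right peaks, onsets and zeros", {
  cfg <- artifact_config(v_eog = 400)
  e <- simulate_eog(cfg, duration = 8, dt = 0.005)
  expect_length(e, 1600)
  expect_equal(max(e), 400)        # peak equals the amplitude
  expect_gte(min(e), 0)
  # pulses occupy [k*3, k*3 + 0.3): onsets at 0, 3, 6 s -> 3 pulses
  t <- (0:1599) * 0.005
  expect_true(all(e[t %% 3 >= 0.3] == 0))
  on_peaks <- e[c(31, 631, 1231)]       # t = 0.15, 3.15, 6.15 s
  expect_equal(on_peaks, rep(400, 3))   # symmetric triangle apex mid-pulse
  expect_equal(sum(diff(e > 0) == 1) + (e[1] > 0), 3)
  expect_equal(simulate_eog(artifact_config(v_eog = 0)), rep(0, 1600))
  expect_error(artifact_config(pw_eog = 3, t_eog = 3), "overlap")
})

test_that("baseline drift is the configured sinusoid", {
  b <- simulate_baseline(artifact_config(), duration = 8, dt = 0.005)
  t <- (0:1599) * 0.005
  expect_equal(b, 20 * sin(2 * pi * 0.5 * t))
  expect_equal(max(b), 20)              # grid hits the crest exactly
  expect_equal(peak_frequency(b, 200), 0.5)
  zero <- simulate_baseline(artifact_config(f_bl = 0))
  expect_equal(zero, rep(0, 1600))
})

test_that("contaminated EEG is the exact sum of its returned parts", {
  sim <- simulate_contaminated_eeg(mpa_config(seed = 5),
                                   artifact_config(seed = 6))
  expect_identical(sim$signal$samples,
                   rowSums(cbind(sim$components, sim$artifacts)))
  # with artifacts and noise switched off it equals the spontaneous EEG
  clean <- simulate_contaminated_eeg(
    mpa_config(seed = 5),
    artifact_config(v_eog = 0, v_bl = 0, noise_sd = 0, seed = 6))
  spont <- simulate_spontaneous_eeg(mpa_config(seed = 5))
  expect_identical(clean$signal$samples, spont$signal$samples)
})

test_that("EOG amplitude controls which artifact branch is triggered", {
  big <- simulate_contaminated_eeg(mpa_config(seed = 8),
                                   artifact_config(v_eog = 400, seed = 9))
  small <- simulate_contaminated_eeg(mpa_config(seed = 8),
                                     artifact_config(v_eog = 100, seed = 9))
  expect_gt(max(abs(big$signal$samples)), 200)
  expect_lt(max(abs(small$signal$samples)), 200)
})
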