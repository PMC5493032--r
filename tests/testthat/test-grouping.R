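test_that("artifact RC count follows the amplitude threshold", {
  expect_identical(artifact_rc_count(c(0, 250, -10), v0 = 200), 2L)
  expect_identical(artifact_rc_count(c(0, 150, -10), v0 = 200), 1L)
  # amplitude exactly at the threshold takes the conservative 2-RC branch
  expect_identical(artifact_rc_count(c(0, 200), v0 = 200), 2L)
  # bipolar signals: negative excursions count
  expect_identical(artifact_rc_count(c(0, -300), v0 = 200), 2L)
  expect_error(artifact_rc_count(numeric(0)), "empty")
  expect_error(artifact_rc_count(c(1, 2), v0 = -5), "v0")
})

test_that("simulated EOG amplitude drives the adaptive branch", {
  big <- simulate_contaminated_eeg(mpa_config(seed = 21),
                                   artifact_config(v_eog = 400, seed = 22))
  small <- simulate_contaminated_eeg(mpa_config(seed = 21),
                                     artifact_config(v_eog = 100, seed = 22))
  expect_identical(artifact_rc_count(big$signal), 2L)
  expect_identical(artifact_rc_count(small$signal), 1L)
})

test_that("artifact removal is an exact additive split", {
  sim <- simulate_contaminated_eeg(mpa_config(seed = 23),
                                   artifact_config(seed = 24))
  d <- ssa(sim$signal)
  rem <- remove_artifacts(d, sim$signal)
  expect_identical(rem$n_artifact, 2L)
  expect_equal(rem$corrected$samples + rem$artifact$samples,
               sim$signal$samples, tolerance = 1e-10)
  expect_equal(rem$artifact$samples, rowSums(d$rcs[, 1:2]))
  # low-amplitude signal: only RC1 removed, identity still exact
  s <- eeg_signal(sinusoid(10, amp = 20), fs = 200)
  d1 <- ssa(s)
  rem1 <- remove_artifacts(d1, s)
  expect_identical(rem1$n_artifact, 1L)
  expect_equal(rem1$corrected$samples + rem1$artifact$samples, s$samples,
               tolerance = 1e-10)
})

test_that("eigenvalue pairing applies the 5% adjacency criterion", {
  expect_equal(pair_eigenvalues(c(10, 9.8, 5)), list(c(1L, 2L)))
  expect_equal(pair_eigenvalues(c(10, 9)), list())       # 0.10 >= 0.05
  expect_equal(pair_eigenvalues(c(10, 9.9, 9.85, 5)), list(c(1L, 2L)))
  # excluded prefix shifts the scan start
  expect_equal(pair_eigenvalues(c(100, 10, 9.8), exclude = 1L),
               list(c(2L, 3L)))
  # non-adjacent candidates (gap from exclusion) never pair
  expect_equal(pair_eigenvalues(c(10, 9.9, 9.8), exclude = 2L), list())
  expect_error(pair_eigenvalues(c(1, 2, 3)), "non-increasing")
})

test_that("a pure tone's two leading eigenvalues form a pair", {
  d <- ssa(sinusoid(10, amp = 25), L = 40, fs = 200)
  pairs <- pair_eigenvalues(d$lam)
  expect_gt(length(pairs), 0)
  expect_equal(pairs[[1]], c(1L, 2L))
  expect_lt(abs(1 - d$lam[2] / d$lam[1]), 0.05)
})

test_that("peak frequency finds the dominant tone", {
  expect_equal(peak_frequency(sinusoid(10), fs = 200), 10, tolerance = 1e-6)
  expect_equal(peak_frequency(sinusoid(0.5), fs = 200), 0.5,
               tolerance = 1e-6)
  # the larger-amplitude tone wins the magnitude argmax
  two <- sinusoid(3, amp = 2) + sinusoid(20, amp = 1)
  expect_equal(peak_frequency(two, fs = 200), 3, tolerance = 0.05)
  expect_error(peak_frequency(rep(1, 100), fs = 200), "constant")
})

test_that("a lone tone lands entirely in its band when removal is off", {
  s <- eeg_signal(sinusoid(10, amp = 25), fs = 200)
  res <- adaptive_ssa(s, v0 = Inf)
  expect_length(res$grouping$artifact_indices, 0)
  expect_equal(res$rhythms$alpha, s$samples, tolerance = 1e-6)
  for (b in setdiff(names(res$rhythms), "alpha"))
    expect_lt(max(abs(res$rhythms[[b]])), 1e-4 * 25)
})

test_that("artifacts, rhythms and residue partition the signal exactly", {
  for (seed in 1:10) {
    sim <- simulate_contaminated_eeg(mpa_config(seed = seed),
                                     artifact_config(seed = seed + 100))
    res <- adaptive_ssa(sim$signal)
    total <- res$artifact$samples + Reduce(`+`, res$rhythms) + res$residue
    expect_equal(total, sim$signal$samples, tolerance = 1e-9)
    # every non-artifact RC is used exactly once
    used <- sort(c(res$grouping$artifact_indices,
                   unlist(res$grouping$groups)))
    expect_identical(used, 1:40)
  }
})

test_that("each extracted rhythm's own spectral peak stays in its band", {
  bands <- rhythm_bands(200)
  for (seed in c(31, 32, 33)) {
    sp <- simulate_spontaneous_eeg(mpa_config(seed = seed))
    res <- adaptive_ssa(sp$signal)
    for (b in names(res$rhythms)) {
      r <- res$rhythms[[b]]
      if (all(r == 0)) next
      fm <- peak_frequency(r, 200)
      row <- bands[bands$name == b, ]
      expect_gte(fm, row$f_low)
      expect_lt(fm, row$f_high)
    }
  }
})

test_that("scaling the EOG across the threshold flips the branch once", {
  counts <- vapply(c(50, 100, 150, 250, 400, 600), function(v) {
    sim <- simulate_contaminated_eeg(mpa_config(seed = 41),
                                     artifact_config(v_eog = v, seed = 42))
    artifact_rc_count(sim$signal)
  }, 1L)
  expect_false(is.unsorted(counts))     # monotone 1 -> 2
  expect_setequal(unique(counts), c(1L, 2L))
})

test_that("the zero signal yields empty rhythms in every band", {
  res <- adaptive_ssa(rep(0, 400), fs = 200)
  for (b in names(res$rhythms)) expect_equal(res$rhythms[[b]], rep(0, 400))
  expect_true(all(is.na(res$grouping$band_assignment)))
})
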