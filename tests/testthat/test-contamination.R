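test_that("rms matches hand-computed values", {
  expect_equal(rms(rep(2.5, 8)), 2.5)
  expect_equal(rms(rep(-2.5, 8)), 2.5)
  expect_equal(rms(c(3, -3, 3, -3)), 3)
  expect_equal(rms(c(1, 2, 3, 4)), sqrt(7.5))  # (1+4+9+16)/4
  expect_error(rms(numeric()), "empty")
})

test_that("lambda solves the RMS-ratio SNR equation", {
  a <- signal_segment(c(1, -1, 1, -1), 256, "eeg")
  b <- signal_segment(c(1, 1, -1, -1), 256, "emg")
  expect_equal(lambda_for_snr(a, b, 0), 1)
  clean2 <- signal_segment(c(2, -2, 2, -2), 256, "eeg")
  expect_equal(lambda_for_snr(clean2, b, -10), 20)
  # recomputing the SNR of (clean, lambda*artifact) recovers -10 dB
  expect_equal(measure_snr(clean2$samples, 20 * b$samples), -10)
  expect_error(lambda_for_snr(a, rep(0, 4), 0), "zero power")
})

test_that("measured SNR follows 10*log10 of the RMS ratio", {
  x <- c(1, -1, 1, -1)
  expect_equal(measure_snr(x, x), 0)
  expect_equal(measure_snr(x, 10 * x), -10)
  expect_equal(measure_snr(2 * x, x), 10 * log10(2))
  expect_error(measure_snr(x, rep(0, 4)), "zero power")
})

test_that("SNR round-trips through lambda across the default grid", {
  set.seed(11)
  for (rep in 1:5) {
    clean <- signal_segment(dpae:::unit_rms(rnorm(128)), 256, "eeg")
    art <- signal_segment(dpae:::unit_rms(rnorm(128)), 256, "emg")
    lams <- vapply(-7:2, function(s) {
      lam <- lambda_for_snr(clean, art, s)
      expect_equal(measure_snr(clean$samples, lam * art$samples), s,
                   tolerance = 1e-9)
      lam
    }, numeric(1))
    expect_true(all(diff(lams) < 0))  # smaller lambda <-> larger SNR
  }
})

test_that("mixing is linear and exact at closed-form cases", {
  clean <- signal_segment(c(1, 1, 1, 1), 256, "eeg")
  art <- signal_segment(c(2, 2, 2, 2), 256, "emg")
  p <- mix_segments(clean, art, 0)
  expect_equal(p$spec$lambda, 0.5)
  expect_equal(p$mixed$samples, c(2, 2, 2, 2))

  set.seed(12)
  c2 <- signal_segment(dpae:::unit_rms(rnorm(256)), 256, "eeg")
  a2 <- signal_segment(dpae:::unit_rms(rnorm(256)), 256, "emg")
  hi <- mix_segments(c2, a2, 60)
  expect_lt(rms(hi$mixed$samples - c2$samples) / rms(c2$samples), 0.002)
  # subtracting the scaled artifact recovers the clean segment
  p2 <- mix_segments(c2, a2, -3)
  expect_equal(p2$mixed$samples - p2$spec$lambda * a2$samples, c2$samples,
               tolerance = 1e-12)
  expect_equal(measure_snr(c2, p2$spec$lambda * a2$samples), -3,
               tolerance = 1e-9)

  short <- signal_segment(rnorm(128), 256, "emg")
  expect_error(mix_segments(c2, short, 0), "equal length")
  other_fs <- signal_segment(a2$samples, 512, "emg")
  expect_error(mix_segments(c2, other_fs, 0), "sampling rate")
})

test_that("pair datasets are count-exact, without replacement, reproducible", {
  sets <- tiny_sets(n = 60, length = 64, seed = 21)
  ds <- build_pair_dataset(sets$clean, sets$emg, snr_levels = -7:2,
                           count_per_level = 10, seed = 5)
  expect_length(ds$pairs, 100)
  snrs <- vapply(ds$pairs, function(p) p$spec$snr_db, numeric(1))
  expect_equal(as.vector(table(snrs)), rep(10, 10))
  # artifact draws within a level are distinct
  for (s in -7:2) {
    arts <- do.call(rbind, lapply(ds$pairs[snrs == s],
                                  function(p) p$artifact$samples))
    expect_false(any(duplicated(arts)))
  }
  ds2 <- build_pair_dataset(sets$clean, sets$emg, snr_levels = -7:2,
                            count_per_level = 10, seed = 5)
  expect_identical(pair_matrices(ds), pair_matrices(ds2))

  small <- segment_set(sets$emg$segments[1:40])
  expect_error(build_pair_dataset(sets$clean, small, -7:2, 50),
               "insufficient artifact")
})

test_that("display normalization pins the maximum absolute value at 1", {
  set.seed(13)
  x <- rnorm(100)
  for (method in c("paper", "zscore_max")) {
    out <- normalize_segment(x, method)
    expect_equal(max(abs(out)), 1)
  }
  z <- normalize_segment(x, "zscore_max")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(normalize_segment(c(0, 2), "zscore_max"), c(-1, 1))
  expect_error(normalize_segment(rep(3, 10)), "degenerate")
})
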