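test_that("temporal RRMSE satisfies its closed-form identities", {
  set.seed(31)
  x <- rnorm(512)
  expect_equal(rrmse_temporal(x, x), 0)
  expect_equal(rrmse_temporal(2 * x, x), 1)
  expect_equal(rrmse_temporal(rep(0, 512), x), 1)
  expect_error(rrmse_temporal(x, rep(0, 512)), "zero power")
  expect_error(rrmse_temporal(x[1:10], x), "equal length")
})

test_that("Welch PSD matches an independent reference implementation", {
  # expected values frozen from scipy.signal.welch (fs=256, nperseg=256,
  # hann taper, 50% overlap, constant detrend) on the same inputs
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.5), 512))
  t <- (0:511) / 256
  y <- sin(2 * pi * 10 * t) + 0.1 * sin(2 * pi * 40 * t)
  p1 <- welch_psd(x, 256)
  p2 <- welch_psd(y, 256)
  expect_equal(p1$power[5], 0.0616818380, tolerance = 1e-8)
  expect_equal(p1$power[50], 0.0145159052, tolerance = 1e-8)
  expect_equal(sum(p1$power), 1.4320941358, tolerance = 1e-8)
  expect_equal(p2$power[11], 0.3333333333, tolerance = 1e-8)
  expect_equal(p1$freq[c(1, 129)], c(0, 128))
  expect_error(welch_psd(rnorm(100), 256), "shorter")
})

test_that("a 10 Hz sinusoid peaks in the alpha band", {
  t <- (0:511) / 256
  p <- welch_psd(sin(2 * pi * 10 * t), 256)
  fpk <- p$freq[which.max(p$power)]
  expect_gte(fpk, 8); expect_lte(fpk, 13)
})

test_that("the averaged white-noise PSD is flat and integrates to the variance", {
  set.seed(32)
  nseg <- 200
  acc <- 0
  vars <- numeric(nseg)
  for (i in seq_len(nseg)) {
    x <- rnorm(512)
    vars[i] <- var(x)
    acc <- acc + welch_psd(x, 256)$power
  }
  p <- acc / nseg
  f <- welch_psd(rnorm(512), 256)$freq
  sel <- f >= 4 & f <= 100
  expect_lt(sd(p[sel]) / mean(p[sel]), 0.2)
  # Parseval: integrated density ~ mean variance
  total <- dpae:::trapz(f, p)
  expect_equal(total, mean(vars), tolerance = 0.05)
})

test_that("spectral RRMSE identities and shift invariance hold", {
  set.seed(33)
  t <- (0:511) / 256
  x <- sin(2 * pi * 9 * t) + 0.5 * rnorm(512)
  expect_equal(rrmse_spectral(x, x, 256), 0)
  # PSD scales with amplitude^2, so doubling gives (4-1)/1 = 3 per bin
  expect_equal(rrmse_spectral(2 * x, x, 256), 3, tolerance = 1e-12)
  d <- x + 0.3 * rnorm(512)
  base <- rrmse_spectral(d, x, 256)
  sh <- function(v, k) c(v[(k + 1):length(v)], v[1:k])
  expect_lt(abs(rrmse_spectral(sh(d, 37), sh(x, 37), 256) - base), 1e-2)
})

test_that("Pearson correlation identities and affine invariance hold", {
  set.seed(34)
  x <- rnorm(256)
  expect_equal(cc(x, x), 1)
  expect_equal(cc(-x, x), -1)
  d <- x + rnorm(256)
  expect_equal(cc(3.2 * d + 5, x), cc(d, x))
  expect_error(cc(rep(1, 256), x), "zero-variance")
})

test_that("band powers integrate the density over the canonical bands", {
  t <- (0:511) / 256
  p <- welch_psd(sin(2 * pi * 10 * t), 256)
  bands <- eeg_bands()
  pw <- vapply(bands$name, function(b) band_power(p$freq, p$power, b),
               numeric(1))
  expect_equal(names(which.max(pw)), "alpha")
  expect_lte(sum(pw), band_power(p$freq, p$power, c(0, 128)) + 1e-12)
  p2 <- welch_psd(2 * sin(2 * pi * 10 * t), 256)
  pw2 <- vapply(bands$name, function(b) band_power(p2$freq, p2$power, b),
                numeric(1))
  expect_equal(unname(pw2), unname(4 * pw), tolerance = 1e-9)
  expect_error(band_power(p$freq, p$power, c(100, 200)), "outside")
})

test_that("no-denoising reference curves follow the SNR closed form", {
  sets <- tiny_sets(n = 40, length = 512, seed = 35)
  ds <- build_pair_dataset(sets$clean, sets$emg, -7:2, 20, seed = 36)
  curves <- evaluate_per_snr(NULL, ds)
  rt <- curves[curves$metric == "rrmse_temporal" & curves$input == "mixed", ]
  expect_equal(nrow(rt), 10)   # one value per configured level
  expect_equal(rt$mean[order(rt$snr_db)], 10^(-(-7:2) / 10),
               tolerance = 1e-6)
  # monotone: mixture error decreases as SNR increases
  expect_true(all(diff(rt$mean[order(rt$snr_db)]) < 0))
  expect_true(all(curves$n == 20))
  ccr <- curves[curves$metric == "cc", ]
  expect_true(all(ccr$mean >= -1 & ccr$mean <= 1))
})
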