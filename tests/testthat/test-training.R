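# Small-geometry specs keep the optimization tests fast; the canonical
# 512-input model is exercised in the acceptance suite.

make_pairs <- function(n, length = 64, seed = 1, snr = 0) {
  sets <- tiny_sets(n = n, length = length, seed = seed)
  mixed <- segment_matrix(sets$clean)
  clean <- mixed
  lam <- 10^(-snr / 10)
  art <- segment_matrix(sets$emg)
  list(mixed = clean + lam * art, clean = clean)
}

test_that("training drives the loss toward zero on an identity task", {
  # the bottleneck-free baseline can represent the identity map, so the
  # optimizer should push the reconstruction loss far below its start
  sets <- tiny_sets(n = 200, length = 64, seed = 41)
  X <- segment_matrix(sets$clean)
  m <- build_model(fcnn_spec(64), seed = 41)
  fit <- train_dpae(m, list(mixed = X, clean = X),
                    training_config(batch_size = 16, epochs = 50, seed = 41))
  expect_lt(tail(fit$history$loss, 1), 0.05)
  expect_lt(tail(fit$history$loss, 1), 0.05 * fit$history$loss[1])
})

test_that("a single batch can be overfit", {
  d <- make_pairs(128, seed = 42)
  m <- build_model(dpae_spec(64, "mlp"), seed = 42)
  fit <- train_dpae(m, d, training_config(epochs = 300, seed = 42))
  expect_lt(tail(fit$history$loss, 1), 0.1 * fit$history$loss[1])
  # loss trend is non-increasing: medians of successive 10-epoch means
  em <- colMeans(matrix(fit$history$loss, nrow = 10))
  expect_true(all(diff(em) < 0) || median(diff(em)) < 0)
})

test_that("training is reproducible given the seeds", {
  d <- make_pairs(60, seed = 43)
  cfg <- training_config(epochs = 5, seed = 7)
  f1 <- train_dpae(build_model(dpae_spec(64, "mlp"), seed = 3), d, cfg)
  f2 <- train_dpae(build_model(dpae_spec(64, "mlp"), seed = 3), d, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("validation loss is recorded but does not steer training", {
  d <- make_pairs(60, seed = 44)
  v <- make_pairs(20, seed = 45)
  cfg <- training_config(epochs = 4, seed = 8)
  fit <- train_dpae(build_model(dpae_spec(64, "mlp"), seed = 4), d, cfg, v)
  expect_equal(nrow(fit$history), 4)
  expect_true(all(is.finite(fit$history$val_loss)))
  bare <- train_dpae(build_model(dpae_spec(64, "mlp"), seed = 4), d, cfg)
  expect_identical(fit$history$loss, bare$history$loss)
})

test_that("segment-length mismatches are rejected", {
  d <- make_pairs(20, length = 64, seed = 46)
  m <- build_model(dpae_spec(128, "cnn", channels = c(4L, 8L, 16L)), seed = 1)
  expect_error(train_dpae(m, d, training_config(epochs = 1)), "input length")
  expect_error(denoise(m, matrix(rnorm(64), 1)), "input length")
})

test_that("denoising a trained model improves on the raw mixture", {
  sets <- tiny_sets(n = 150, length = 64, seed = 47)
  split_c <- split_train_test(sets$clean, 0.8, seed = 1)
  split_a <- split_train_test(sets$emg, 0.8, seed = 2)
  train <- build_pair_dataset(split_c$train, split_a$train, -7:2, 40,
                              seed = 3)
  test <- build_pair_dataset(split_c$test, split_a$test, -7:2, 10, seed = 4)
  m <- build_model(dpae_spec(64, "mlp"), seed = 5)
  fit <- train_dpae(m, train, training_config(epochs = 20, seed = 5))
  tm <- pair_matrices(test)
  den <- denoise(fit$model, tm$mixed)
  r_den <- mean(vapply(seq_len(nrow(den)), function(i)
    rrmse_temporal(den[i, ], tm$clean[i, ]), numeric(1)))
  r_mix <- mean(vapply(seq_len(nrow(tm$mixed)), function(i)
    rrmse_temporal(tm$mixed[i, ], tm$clean[i, ]), numeric(1)))
  expect_lt(r_den, r_mix)
})

test_that("denoise preserves counts, labels and inputs", {
  sets <- tiny_sets(n = 5, length = 64, seed = 48)
  m <- build_model(dpae_spec(64, "mlp"), seed = 6)
  before <- segment_matrix(sets$clean)
  out <- denoise(m, sets$clean)
  expect_s3_class(out, "segment_set")
  expect_length(out$segments, 5)
  expect_equal(out$source, "denoised")
  expect_equal(out$segments[[1]]$length, 64)
  expect_identical(segment_matrix(sets$clean), before)
  expect_identical(segment_matrix(denoise(m, sets$clean)),
                   segment_matrix(out))
})

test_that("RMS-scaled training round-trips amplitudes at inference", {
  d <- make_pairs(60, seed = 49)
  cfg <- training_config(epochs = 5, seed = 9, rms_scale = TRUE)
  fit <- train_dpae(build_model(dpae_spec(64, "mlp"), seed = 7), d, cfg)
  out1 <- predict_segments(fit$model, d$mixed[1:3, ])
  # scaling the input scales the output identically
  out2 <- predict_segments(fit$model, 5 * d$mixed[1:3, ])
  expect_equal(out2, 5 * out1, tolerance = 1e-10)
})

test_that("multichannel denoising is channel-independent", {
  m <- build_model(dpae_spec(64, "mlp"), seed = 8)
  set.seed(50)
  trial <- matrix(rnorm(22 * 64), 22, 64)
  out <- denoise_multichannel(m, trial)
  expect_equal(dim(out), c(22, 64))
  expect_equal(denoise_multichannel(m, trial[3, , drop = FALSE]),
               out[3, , drop = FALSE])
  perm <- sample(22)
  expect_equal(denoise_multichannel(m, trial[perm, ]), out[perm, ])
  expect_error(denoise_multichannel(m, trial[, 1:32]), "samples per channel")
})
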