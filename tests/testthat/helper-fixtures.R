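# Shared small fixtures, built in code.

tiny_sets <- function(n = 10, length = 64, seed = 1) {
  list(clean = gen_clean_eeg(n, length = length, seed = seed),
       emg = gen_emg(n, length = length, seed = seed + 100))
}

# finite-difference gradient check on a handful of sampled parameters
expect_gradients_match <- function(model, n_check = 3, tol = 1e-4,
                                   batch = 3, fd_seed = 99) {
  L <- model$spec$input_len
  set.seed(fd_seed)
  X <- matrix(stats::rnorm(batch * L), batch, L)
  Y <- matrix(stats::rnorm(batch * L), batch, L)
  fwd <- dpae:::nn_forward(model, X, training = TRUE)
  grads <- dpae:::nn_backward(model, fwd, 2 * (fwd$output - Y) / length(Y))
  loss_at <- function(m) mean((dpae:::nn_forward(m, X, TRUE)$output - Y)^2)
  for (nm in names(grads)) {
    p <- model$params[[nm]]
    for (i in sample.int(length(p), min(n_check, length(p)))) {
      h <- 1e-6
      m2 <- model
      m2$params[[nm]][i] <- p[i] + h
      l2 <- loss_at(m2)
      m2$params[[nm]][i] <- p[i] - h
      l1 <- loss_at(m2)
      fd <- (l2 - l1) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = tol,
                   label = sprintf("analytic gradient of %s[%d]", nm, i))
    }
  }
}
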