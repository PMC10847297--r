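#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam, mean squared
#' error, batch size 128, learning rate 0.001, 200 epochs.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training set (no early
#'   stopping; validation loss is recorded but never used for control).
#' @param seed integer seed controlling the per-epoch shuffling.
#' @param rms_scale if `TRUE`, scale each input/target pair by the RMS of
#'   the mixed segment before training (experimental switch; the default
#'   feeds raw mixed/clean units).
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 128L, learning_rate = 0.001,
                            epochs = 200L, seed = 1L, rms_scale = FALSE) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = "adam", loss = "mse", seed = as.integer(seed),
                 rms_scale = isTRUE(rms_scale)),
            class = "training_config")
}

as_xy <- function(dataset) {
  if (inherits(dataset, "pair_dataset")) {
    m <- pair_matrices(dataset)
    list(x = m$mixed, y = m$clean)
  } else if (is.list(dataset) && !is.null(dataset$mixed) &&
             !is.null(dataset$clean)) {
    list(x = as.matrix(dataset$mixed), y = as.matrix(dataset$clean))
  } else stop("'dataset' must be a pair_dataset or a list(mixed, clean)")
}

#' Train a denoising model on contaminated/clean pairs
#'
#' Minimizes the mean squared error between the model output on the
#' mixed segments and the paired clean segments, with Adam. Data order
#' is reshuffled every epoch; the whole run is deterministic given the
#' configuration seed and the model's initialization seed.
#'
#' @param model a `dpae_model` from [build_model].
#' @param dataset a `pair_dataset` (or `list(mixed, clean)` of matrices)
#'   whose segment length equals the model input length.
#' @param config a [training_config].
#' @param validation optional dataset of the same form; its loss is
#'   recorded per epoch (inference mode) but does not influence training.
#' @return List with `model` (trained) and `history` (data frame with
#'   one row per epoch: `epoch`, `loss`, and `val_loss` when a
#'   validation set is given).
#' @export
train_dpae <- function(model, dataset, config = training_config(),
                       validation = NULL) {
  stopifnot(inherits(model, "dpae_model"), inherits(config, "training_config"))
  xy <- as_xy(dataset)
  L <- model$spec$input_len
  if (ncol(xy$x) != L || ncol(xy$y) != L)
    stop("segment length ", ncol(xy$x), " != model input length ", L)
  if (config$rms_scale) {
    sc <- sqrt(rowMeans(xy$x^2))
    xy$x <- xy$x / sc
    xy$y <- xy$y / sc
  }
  vxy <- if (!is.null(validation)) as_xy(validation)
  if (!is.null(vxy) && config$rms_scale) {
    vsc <- sqrt(rowMeans(vxy$x^2))
    vxy$x <- vxy$x / vsc
    vxy$y <- vxy$y / vsc
  }
  n <- nrow(xy$x)
  bs <- min(config$batch_size, n)
  losses <- numeric(config$epochs)
  val_losses <- rep(NA_real_, config$epochs)
  params <- model$params
  state <- model$state
  opt <- adam_init(params)
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        xb <- xy$x[idx, , drop = FALSE]
        yb <- xy$y[idx, , drop = FALSE]
        model$params <- params; model$state <- state
        fwd <- nn_forward(model, xb, training = TRUE)
        state <- fwd$state
        err <- fwd$output - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        ep_loss <- ep_loss + loss * length(idx)
        dout <- 2 * err / length(err)
        grads <- nn_backward(model, fwd, dout)
        upd <- adam_step(params, grads, opt, lr = config$learning_rate)
        params <- upd$params; opt <- upd$opt
      }
      losses[ep] <- ep_loss / n
      if (!is.null(validation)) {
        model$params <- params; model$state <- state
        pv <- nn_forward(model, vxy$x, training = FALSE)$output
        val_losses[ep] <- mean((pv - vxy$y)^2)
      }
    }
  })
  model$params <- params
  model$state <- state
  model$rms_scale <- config$rms_scale
  history <- data.frame(epoch = seq_len(config$epochs), loss = losses)
  if (!is.null(validation)) history$val_loss <- val_losses
  list(model = model, history = history)
}

#' Denoise a set of segments
#'
#' Inference wrapper: one output segment per input, labelled
#' `"denoised"`; inputs are not modified. Deterministic (batch
#' normalization uses running statistics).
#'
#' @param model a trained `dpae_model`.
#' @param segments a [segment_set] (or matrix, rows = segments) with
#'   segment length equal to the model input length.
#' @return A [segment_set] of denoised segments (or a matrix when a
#'   matrix was supplied).
#' @export
denoise <- function(model, segments) {
  if (inherits(segments, "segment_set")) {
    out <- predict_segments(model, segment_matrix(segments))
    segment_set(lapply(seq_len(nrow(out)), function(i)
      signal_segment(out[i, ], fs = segments$fs, source = "denoised")),
      seed = segments$seed)
  } else {
    predict_segments(model, as.matrix(segments))
  }
}

#' Channel-by-channel denoising of a multichannel trial
#'
#' Applies the single-channel model independently to every channel of a
#' channels x samples matrix; shape and channel order are preserved.
#'
#' @param model a trained `dpae_model`.
#' @param trial numeric matrix, channels x samples, with the sample
#'   dimension equal to the model input length.
#' @return Matrix of the same shape with denoised channels.
#' @export
denoise_multichannel <- function(model, trial) {
  trial <- as.matrix(trial)
  if (ncol(trial) != model$spec$input_len)
    stop("trial has ", ncol(trial), " samples per channel; model expects ",
         model$spec$input_len)
  out <- predict_segments(model, trial)
  dimnames(out) <- dimnames(trial)
  out
}
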