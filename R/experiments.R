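#' Experiment configuration
#'
#' Desk-scale defaults: 10 SNR levels x 200 training pairs (2,000 pairs)
#' and 50 epochs; the reference-scale protocol (4,478 training / 560
#' test pairs per level for EMG, 200 epochs) remains reachable by
#' setting the corresponding fields.
#'
#' @param artifact `"emg"` or `"eog"`.
#' @param backbones character vector of backbones to train
#'   (`"mlp"`, `"cnn"`, `"rnn"`).
#' @param snr_levels SNR grid in dB.
#' @param train_per_level,test_per_level pairs per SNR level.
#' @param n_clean,n_artifact sizes of the generated source pools (each is
#'   split 80/20 into train/test sub-pools so test sources are unseen).
#' @param input_len,fs segment geometry.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param include_fcnn also train the plain fully connected baseline.
#' @param seed master seed.
#' @param out_dir optional directory for CSV/YAML outputs.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(artifact = c("emg", "eog"),
                              backbones = "mlp", snr_levels = -7:2,
                              train_per_level = 200L, test_per_level = 50L,
                              n_clean = 500L, n_artifact = 320L,
                              input_len = 512L, fs = 256,
                              epochs = 50L, batch_size = 128L,
                              learning_rate = 0.001,
                              include_fcnn = FALSE, seed = 42L,
                              out_dir = NULL) {
  artifact <- match.arg(artifact)
  backbones <- match.arg(backbones, c("mlp", "cnn", "rnn"),
                         several.ok = TRUE)
  if (round(0.8 * n_artifact) < train_per_level ||
      (n_artifact - round(0.8 * n_artifact)) < test_per_level)
    stop("artifact pool too small for the requested per-level counts")
  structure(list(artifact = artifact, backbones = backbones,
                 snr_levels = snr_levels,
                 train_per_level = as.integer(train_per_level),
                 test_per_level = as.integer(test_per_level),
                 n_clean = as.integer(n_clean),
                 n_artifact = as.integer(n_artifact),
                 input_len = as.integer(input_len), fs = fs,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 include_fcnn = isTRUE(include_fcnn),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# Generate source pools and SNR-stratified train/test pair datasets.
# Test pairs use held-out clean and artifact sub-pools (unseen sources).
experiment_data <- function(config) {
  gen_art <- if (config$artifact == "emg") gen_emg else gen_eog
  cleans <- gen_clean_eeg(config$n_clean, config$input_len, config$fs,
                          seed = config$seed)
  arts <- gen_art(config$n_artifact, config$input_len, config$fs,
                  seed = config$seed + 1L)
  csplit <- split_train_test(cleans, 0.8, seed = config$seed + 2L)
  asplit <- split_train_test(arts, 0.8, seed = config$seed + 3L)
  list(train = build_pair_dataset(csplit$train, asplit$train,
                                  config$snr_levels, config$train_per_level,
                                  seed = config$seed + 4L),
       test = build_pair_dataset(csplit$test, asplit$test,
                                 config$snr_levels, config$test_per_level,
                                 seed = config$seed + 5L))
}

final_loss <- function(history) history$loss[nrow(history)]

epochs_to_threshold <- function(history, threshold) {
  hit <- which(history$loss <= threshold)
  if (length(hit)) hit[1] else NA_integer_
}

write_outputs <- function(config, tables) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package_version = as.character(utils::packageVersion("dpae")),
               psd_estimator = list(window = 256L, overlap = 0.5,
                                    taper = "hann"),
               config = unclass(config))
  yaml::write_yaml(meta, file.path(config$out_dir, "config.yaml"))
  for (nm in names(tables))
    utils::write.csv(tables[[nm]],
                     file.path(config$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(config$out_dir)
}

#' Ablation study: fusion block and residual connections
#'
#' Trains the full dual-pathway MLP and its two ablation variants
#' (fusion block removed; residual connections removed) with the same
#' seed, the same training pairs and the same hyperparameters, and
#' reports per-epoch losses, final losses and epochs-to-threshold.
#'
#' @param config an [experiment_config] (MLP is the ablation base).
#' @return List with `histories` (named list of per-epoch loss data
#'   frames for `full`, `no_residual`, `no_fusion`) and `table`
#'   (data frame: model, final_loss, epochs_to_threshold).
#' @export
run_ablation <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  data <- experiment_data(config)
  tc <- training_config(batch_size = config$batch_size,
                        learning_rate = config$learning_rate,
                        epochs = config$epochs, seed = config$seed)
  variants <- list(
    full = dpae_mlp_canonical(),
    no_residual = dpae_mlp_canonical(use_residual = FALSE),
    no_fusion = dpae_mlp_canonical(use_fusion = FALSE))
  if (config$input_len != 512L)
    variants <- list(
      full = dpae_spec(config$input_len, "mlp"),
      no_residual = dpae_spec(config$input_len, "mlp", use_residual = FALSE),
      no_fusion = dpae_spec(config$input_len, "mlp", use_fusion = FALSE))
  histories <- lapply(variants, function(spec) {
    fit <- train_dpae(build_model(spec, seed = config$seed), data$train, tc)
    fit$history
  })
  thr <- 0.5 * max(vapply(histories, function(h) h$loss[1], numeric(1)))
  table <- data.frame(
    model = names(histories),
    final_loss = vapply(histories, final_loss, numeric(1)),
    epochs_to_threshold = vapply(histories, epochs_to_threshold,
                                 integer(1), threshold = thr),
    row.names = NULL)
  attr(table, "threshold") <- thr
  write_outputs(config, list(ablation = table))
  list(histories = histories, table = table)
}

#' Benchmark configured models on a shared dataset
#'
#' Trains every configured dual-pathway backbone (and optionally the
#' plain fully connected baseline) on the same pair dataset, evaluates
#' per-SNR metric curves on held-out pairs, and tabulates parameter and
#' FLOP counts alongside final training losses.
#'
#' @param config an [experiment_config].
#' @return List with `curves` (per-SNR metrics, one `model` column; the
#'   `"mixed"` rows are the no-denoising reference), `scale` (model,
#'   params, flops, final_loss) and `histories`.
#' @export
run_benchmark <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$backbones) < 1L)
    stop("at least one dual-pathway backbone must be configured")
  data <- experiment_data(config)
  tc <- training_config(batch_size = config$batch_size,
                        learning_rate = config$learning_rate,
                        epochs = config$epochs, seed = config$seed)
  specs <- stats::setNames(
    lapply(config$backbones, function(b)
      if (b == "mlp" && config$input_len == 512L) dpae_mlp_canonical()
      else dpae_spec(config$input_len, b)),
    paste0("dpae_", config$backbones))
  if (config$include_fcnn) specs$fcnn <- fcnn_spec(config$input_len)
  histories <- list(); curves <- list(); scale <- list()
  for (nm in names(specs)) {
    fit <- train_dpae(build_model(specs[[nm]], seed = config$seed),
                      data$train, tc)
    histories[[nm]] <- fit$history
    cv <- evaluate_per_snr(fit$model, data$test, fs = config$fs)
    cv$model <- ifelse(cv$input == "mixed", "mixed", nm)
    curves[[nm]] <- cv
    scale[[nm]] <- data.frame(model = nm,
                              params = count_params(specs[[nm]]),
                              flops = count_flops(specs[[nm]]),
                              final_loss = final_loss(fit$history))
  }
  curves <- unique(do.call(rbind, curves))
  scale <- do.call(rbind, c(scale, list(make.row.names = FALSE)))
  write_outputs(config, list(benchmark_curves = curves,
                             benchmark_scale = scale))
  list(curves = curves, scale = scale, histories = histories)
}

#' Multichannel denoising evaluation
#'
#' Contaminates every channel of each trial with generated EMG at each
#' SNR level, denoises channel by channel with the given single-channel
#' model, and pools per-channel metrics per level.
#'
#' @param model a trained `dpae_model`.
#' @param trials list of channels x samples matrices (samples must equal
#'   the model input length).
#' @param snr_levels SNR grid in dB.
#' @param fs sampling rate in Hz.
#' @param seed seed for the artifact draws.
#' @return Data frame as in [evaluate_per_snr] with metrics pooled over
#'   channels and trials.
#' @export
run_multichannel_eval <- function(model, trials, snr_levels = -7:2,
                                  fs = 256, seed = 1L) {
  stopifnot(inherits(model, "dpae_model"))
  if (is.matrix(trials)) trials <- list(trials)
  L <- model$spec$input_len
  for (tr in trials)
    if (ncol(tr) != L)
      stop("trial has ", ncol(tr), " samples per channel; model expects ", L)
  n_ch <- sum(vapply(trials, nrow, numeric(1)))
  arts <- gen_emg(n_ch * length(snr_levels), L, fs, seed = seed)
  out <- list()
  k <- 0L
  for (s in snr_levels) {
    clean <- do.call(rbind, trials)
    mixed <- clean
    for (i in seq_len(nrow(clean))) {
      k <- k + 1L
      lam <- lambda_for_snr(clean[i, ], arts$segments[[k]]$samples, s)
      mixed[i, ] <- clean[i, ] + lam * arts$segments[[k]]$samples
    }
    den <- denoise_multichannel(model, mixed)
    for (which in c("mixed", "denoised")) {
      mat <- if (which == "mixed") mixed else den
      rt <- vapply(seq_len(nrow(mat)), function(i)
        rrmse_temporal(mat[i, ], clean[i, ]), numeric(1))
      rs <- vapply(seq_len(nrow(mat)), function(i)
        rrmse_spectral(mat[i, ], clean[i, ], fs, window = min(256L, L)),
        numeric(1))
      pc <- vapply(seq_len(nrow(mat)), function(i)
        cc(mat[i, ], clean[i, ]), numeric(1))
      vals <- list(rrmse_temporal = rt, rrmse_spectral = rs, cc = pc)
      for (metric in names(vals))
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, snr_db = s, input = which,
          mean = mean(vals[[metric]]), sd = stats::sd(vals[[metric]]),
          n = length(vals[[metric]]))
    }
  }
  do.call(rbind, out)
}
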