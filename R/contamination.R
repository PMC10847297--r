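#' Root mean square of a segment
#'
#' `sqrt(mean(x^2))`, the amplitude scale used by the SNR definition and
#' by the relative error metrics.
#'
#' @param x a [signal_segment] or numeric vector.
#' @return Non-negative scalar.
#' @export
rms <- function(x) {
  s <- as_samples(x)
  if (length(s) == 0L) stop("cannot take the RMS of an empty segment")
  sqrt(mean(s^2))
}

#' Artifact scaling coefficient for a target SNR
#'
#' The SNR of a contaminated segment is defined on the RMS-amplitude
#' ratio: `SNR = 10 * log10(rms(clean) / rms(lambda * artifact))` dB.
#' Inverting for the artifact coefficient gives
#' `lambda = rms(clean) / rms(artifact) * 10^(-snr_db / 10)`, so smaller
#' lambda corresponds to larger SNR.
#'
#' @param clean clean segment (or numeric vector).
#' @param artifact artifact segment (or numeric vector).
#' @param snr_db target signal-to-noise ratio in dB.
#' @return Positive scalar lambda.
#' @export
lambda_for_snr <- function(clean, artifact, snr_db) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db))
    stop("'snr_db' must be a single finite number")
  ra <- rms(artifact)
  if (ra == 0) stop("artifact has zero power; lambda is undefined")
  rms(clean) / ra * 10^(-snr_db / 10)
}

#' Measured SNR of a clean/scaled-artifact pair
#'
#' @param clean clean segment.
#' @param scaled_artifact the artifact already multiplied by its
#'   coefficient lambda.
#' @return SNR in dB: `10 * log10(rms(clean) / rms(scaled_artifact))`.
#' @export
measure_snr <- function(clean, scaled_artifact) {
  ra <- rms(scaled_artifact)
  if (ra == 0) stop("scaled artifact has zero power; SNR is undefined")
  10 * log10(rms(clean) / ra)
}

#' Contaminate a clean segment with an artifact at a target SNR
#'
#' Linear mixing: `mixed = clean + lambda * artifact`, with lambda solved
#' by [lambda_for_snr] so the measured SNR of the pair equals `snr_db`.
#'
#' @param clean clean EEG [signal_segment].
#' @param artifact EOG or EMG [signal_segment] of equal length and
#'   sampling rate.
#' @param snr_db target SNR in dB.
#' @return A `contaminated_pair`: list with `clean`, `artifact`, `spec`
#'   (fields `snr_db`, `lambda`) and `mixed` (a `"mixed"` segment).
#' @export
mix_segments <- function(clean, artifact, snr_db) {
  stopifnot(inherits(clean, "signal_segment"),
            inherits(artifact, "signal_segment"))
  if (clean$length != artifact$length)
    stop("clean and artifact segments must have equal length")
  if (clean$fs != artifact$fs)
    stop("clean and artifact segments must share the sampling rate")
  lam <- lambda_for_snr(clean, artifact, snr_db)
  mixed <- signal_segment(clean$samples + lam * artifact$samples,
                          fs = clean$fs, source = "mixed")
  structure(list(clean = clean, artifact = artifact,
                 spec = list(snr_db = snr_db, lambda = lam),
                 mixed = mixed),
            class = "contaminated_pair")
}

#' @export
print.contaminated_pair <- function(x, ...) {
  cat(sprintf("<contaminated_pair> SNR %g dB (lambda %.4g), %d samples @ %g Hz\n",
              x$spec$snr_db, x$spec$lambda, x$clean$length, x$clean$fs))
  invisible(x)
}

#' Build an SNR-stratified dataset of contaminated pairs
#'
#' For each SNR level, draws `count_per_level` artifact segments without
#' replacement (clean segments are drawn without replacement when the
#' pool allows, with replacement otherwise, and may be reused across
#' levels) and mixes each pair at that level. Deterministic given the
#' seed.
#'
#' @param cleans [segment_set] of clean EEG segments.
#' @param artifacts [segment_set] of artifact segments (EOG or EMG).
#' @param snr_levels SNR levels in dB (default the integer grid -7..2).
#' @param count_per_level pairs per level.
#' @param seed integer seed.
#' @return A `pair_dataset`: list with `pairs` (list of
#'   `contaminated_pair`), `snr_levels`, `count_per_level`, `seed`.
#' @export
build_pair_dataset <- function(cleans, artifacts, snr_levels = -7:2,
                               count_per_level, seed = 1) {
  stopifnot(inherits(cleans, "segment_set"),
            inherits(artifacts, "segment_set"))
  if (!is.numeric(count_per_level) || count_per_level < 1)
    stop("'count_per_level' must be a positive integer")
  count_per_level <- as.integer(count_per_level)
  n_art <- length(artifacts)
  if (count_per_level > n_art)
    stop(sprintf(paste0("insufficient artifact segments to draw %d without ",
                        "replacement at SNR level %g dB (pool has %d)"),
                 count_per_level, snr_levels[1], n_art))
  n_clean <- length(cleans)
  pairs <- withr::with_seed(seed, {
    out <- vector("list", length(snr_levels) * count_per_level)
    k <- 0L
    for (s in snr_levels) {
      art_idx <- sample.int(n_art, count_per_level)  # without replacement
      clean_idx <- sample.int(n_clean, count_per_level,
                              replace = count_per_level > n_clean)
      for (i in seq_len(count_per_level)) {
        k <- k + 1L
        out[[k]] <- mix_segments(cleans$segments[[clean_idx[i]]],
                                 artifacts$segments[[art_idx[i]]], s)
      }
    }
    out
  })
  structure(list(pairs = pairs, snr_levels = snr_levels,
                 count_per_level = count_per_level, seed = seed),
            class = "pair_dataset")
}

#' @export
length.pair_dataset <- function(x) length(x$pairs)

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d pairs: %d SNR levels [%g..%g dB] x %d per level (seed %s)\n",
              length(x), length(x$snr_levels), min(x$snr_levels),
              max(x$snr_levels), x$count_per_level, format(x$seed)))
  invisible(x)
}

#' Stack a pair dataset into numeric matrices
#'
#' @param ds a `pair_dataset`.
#' @return List with `mixed` and `clean` (matrices, one row per pair) and
#'   `snr_db` (vector of per-row SNR levels).
#' @export
pair_matrices <- function(ds) {
  stopifnot(inherits(ds, "pair_dataset"))
  list(mixed = do.call(rbind, lapply(ds$pairs, function(p) p$mixed$samples)),
       clean = do.call(rbind, lapply(ds$pairs, function(p) p$clean$samples)),
       snr_db = vapply(ds$pairs, function(p) p$spec$snr_db, numeric(1)))
}

#' Normalize a segment for display
#'
#' Two variants of the two-step display normalization. `"paper"` follows
#' the literal rule of subtracting the standard deviation before dividing
#' by the maximum absolute value; `"zscore_max"` subtracts the mean
#' instead (the conventional reading). Both end with maximum absolute
#' value 1. Intended for reporting/plotting, not for training targets.
#'
#' @param x a [signal_segment] or numeric vector with non-constant
#'   samples.
#' @param method `"paper"` or `"zscore_max"`.
#' @return Object of the same kind as the input, normalized.
#' @export
normalize_segment <- function(x, method = c("paper", "zscore_max")) {
  method <- match.arg(method)
  s <- as_samples(x)
  if (length(unique(s)) == 1L)
    stop("degenerate input: all samples are equal, normalization undefined")
  centred <- if (method == "paper") s - stats::sd(s) else s - mean(s)
  out <- centred / max(abs(centred))
  if (inherits(x, "signal_segment"))
    signal_segment(out, fs = x$fs, source = x$source)
  else out
}
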