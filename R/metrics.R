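#' Temporal relative root-mean-square error
#'
#' `rms(denoised - clean) / rms(clean)`: 0 for a perfect reconstruction,
#' 1 for an all-zero output.
#'
#' @param denoised,clean segments or numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rrmse_temporal <- function(denoised, clean) {
  d <- as_samples(denoised); x <- as_samples(clean)
  if (length(d) != length(x)) stop("segments must have equal length")
  rx <- rms(x)
  if (rx == 0) stop("clean segment has zero power; RRMSE is undefined")
  rms(d - x) / rx
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a periodic Hann taper, per-window
#' mean removal and one-sided density scaling (power / Hz): the
#' integrated density approximates the signal variance.
#'
#' @param x segment or numeric vector (length at least `window`).
#' @param fs sampling rate in Hz.
#' @param window taper length in samples (default 256).
#' @param overlap fractional window overlap (default 0.5).
#' @return List with `freq` (Hz, 0 to fs/2) and `power`
#'   (amplitude^2 / Hz).
#' @export
welch_psd <- function(x, fs = 256, window = 256L, overlap = 0.5) {
  s <- as_samples(x)
  n <- length(s)
  if (n < window)
    stop("segment (", n, " samples) is shorter than the estimator window (",
         window, ")")
  step <- max(1L, floor(window * (1 - overlap)))
  starts <- seq(1L, n - window + 1L, by = step)
  k <- 0:(window - 1L)
  w <- 0.5 * (1 - cos(2 * pi * k / window))
  u <- sum(w^2)
  nf <- window %/% 2L + 1L
  acc <- numeric(nf)
  for (st in starts) {
    seg <- s[st:(st + window - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nf)]
    p <- Mod(sp)^2 / (fs * u)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / window, power = acc / length(starts))
}

#' Spectral relative root-mean-square error
#'
#' RMS of the difference between the Welch PSDs of the denoised and
#' clean segments, normalized by the RMS of the clean PSD; both PSDs use
#' identical estimator parameters.
#'
#' @inheritParams rrmse_temporal
#' @param fs sampling rate in Hz.
#' @param window,overlap estimator parameters passed to [welch_psd].
#' @return Non-negative scalar.
#' @export
rrmse_spectral <- function(denoised, clean, fs = 256, window = 256L,
                           overlap = 0.5) {
  pd <- welch_psd(denoised, fs, window, overlap)$power
  px <- welch_psd(clean, fs, window, overlap)$power
  rx <- rms(px)
  if (rx == 0) stop("clean segment has zero spectral power")
  rms(pd - px) / rx
}

#' Pearson correlation between denoised and clean segments
#'
#' @inheritParams rrmse_temporal
#' @return Correlation in \[-1, 1\].
#' @export
cc <- function(denoised, clean) {
  d <- as_samples(denoised); x <- as_samples(clean)
  if (length(d) != length(x)) stop("segments must have equal length")
  if (stats::var(d) == 0 || stats::var(x) == 0)
    stop("zero-variance segment; the correlation is undefined")
  stats::cor(d, x)
}

#' Canonical EEG frequency bands
#'
#' @return Data frame with columns `name`, `lo`, `hi` (Hz): delta 1-4,
#'   theta 4-8, alpha 8-13, beta 13-30, gamma 30-80.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 13, 30),
             hi = c(4, 8, 13, 30, 80))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Band power from a PSD
#'
#' Trapezoidal integral of the power density over a frequency band, with
#' linear interpolation at the band edges.
#'
#' @param freq frequency vector (Hz) from [welch_psd].
#' @param power matching power density vector.
#' @param band a band name from [eeg_bands] or a numeric `c(lo, hi)`.
#' @return Non-negative scalar (amplitude^2).
#' @export
band_power <- function(freq, power, band) {
  if (is.character(band)) {
    bands <- eeg_bands()
    row <- bands[bands$name == band, ]
    if (nrow(row) == 0) stop("unknown band '", band, "'")
    band <- c(row$lo, row$hi)
  }
  lo <- band[1]; hi <- band[2]
  if (lo < min(freq) || hi > max(freq))
    stop("band [", lo, ", ", hi, "] Hz lies outside the frequency support [",
         min(freq), ", ", max(freq), "] Hz")
  inside <- freq > lo & freq < hi
  fx <- c(lo, freq[inside], hi)
  fy <- stats::approx(freq, power, xout = fx)$y
  trapz(fx, fy)
}

#' Per-SNR-level evaluation curves
#'
#' Computes temporal RRMSE, spectral RRMSE and Pearson correlation for
#' every pair of a labelled test set, then aggregates mean and standard
#' deviation at each SNR level. The same curves are always also computed
#' on the raw mixed inputs (the no-denoising reference).
#'
#' @param model a trained `dpae_model`, or `NULL` for the reference
#'   curves only.
#' @param test a `pair_dataset` with per-pair SNR labels.
#' @param fs sampling rate in Hz.
#' @param window,overlap Welch estimator parameters.
#' @return Data frame with columns `metric` (`rrmse_temporal`,
#'   `rrmse_spectral`, `cc`), `snr_db`, `input` (`"denoised"` or
#'   `"mixed"`), `mean`, `sd`, `n`.
#' @export
evaluate_per_snr <- function(model, test, fs = 256, window = 256L,
                             overlap = 0.5) {
  stopifnot(inherits(test, "pair_dataset"))
  m <- pair_matrices(test)
  window <- min(window, ncol(m$clean))
  inputs <- list(mixed = m$mixed)
  if (!is.null(model)) inputs$denoised <- predict_segments(model, m$mixed)
  per_pair <- function(mat) {
    data.frame(
      rrmse_temporal = vapply(seq_len(nrow(mat)), function(i)
        rrmse_temporal(mat[i, ], m$clean[i, ]), numeric(1)),
      rrmse_spectral = vapply(seq_len(nrow(mat)), function(i)
        rrmse_spectral(mat[i, ], m$clean[i, ], fs, window, overlap),
        numeric(1)),
      cc = vapply(seq_len(nrow(mat)), function(i)
        cc(mat[i, ], m$clean[i, ]), numeric(1)))
  }
  out <- list()
  for (which in names(inputs)) {
    vals <- per_pair(inputs[[which]])
    for (metric in names(vals)) {
      for (s in test$snr_levels) {
        sel <- m$snr_db == s
        if (!any(sel)) {
          warning("no test pairs at SNR level ", s, " dB; level omitted")
          next
        }
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, snr_db = s, input = which,
          mean = mean(vals[[metric]][sel]),
          sd = stats::sd(vals[[metric]][sel]),
          n = sum(sel))
      }
    }
  }
  do.call(rbind, out)
}
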