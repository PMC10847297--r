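#' Single EEG/artifact segment
#'
#' A `signal_segment` is a fixed-length window of a single-channel signal:
#' a numeric sample vector together with its sampling rate and a source
#' label. The default geometry is a 2 s window at 256 Hz (512 samples),
#' the segment shape used throughout the package.
#'
#' @param samples numeric vector of finite sample values (arbitrary
#'   amplitude units).
#' @param fs sampling rate in Hz.
#' @param source one of `"eeg"`, `"eog"`, `"emg"`, `"mixed"`, `"denoised"`.
#' @return An object of class `signal_segment` with fields `samples`,
#'   `fs`, `source` and `length`.
#' @export
signal_segment <- function(samples, fs = 256,
                           source = c("eeg", "eog", "emg", "mixed",
                                      "denoised")) {
  source <- match.arg(source)
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stop("'samples' must be finite real numbers")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(list(samples = samples, fs = fs, source = source,
                 length = length(samples)),
            class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment> source=%s, %d samples @ %g Hz (%.3g s), RMS=%.4g\n",
              x$source, x$length, x$fs, x$length / x$fs, rms(x$samples)))
  invisible(x)
}

# Coerce a segment or bare numeric vector to its sample vector.
as_samples <- function(x) {
  if (inherits(x, "signal_segment")) return(x$samples)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a 'signal_segment' or a numeric vector")
}

#' Homogeneous collection of segments
#'
#' All segments in a `segment_set` share sampling rate, length and source
#' label; the set records the seed that generated (or split) it.
#'
#' @param segments list of [signal_segment] objects of one source.
#' @param seed integer seed associated with the set (or `NA`).
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, seed = NA_integer_) {
  if (!is.list(segments) || length(segments) < 1L)
    stop("'segments' must be a non-empty list of signal_segment objects")
  if (!all(vapply(segments, inherits, logical(1), "signal_segment")))
    stop("all elements must be signal_segment objects")
  fs <- vapply(segments, function(s) s$fs, numeric(1))
  len <- vapply(segments, function(s) s$length, numeric(1))
  src <- vapply(segments, function(s) s$source, character(1))
  if (length(unique(fs)) != 1L || length(unique(len)) != 1L ||
      length(unique(src)) != 1L)
    stop("all segments in a set must share fs, length and source")
  structure(list(segments = segments, fs = fs[1], length = len[1],
                 source = src[1], seed = seed),
            class = "segment_set")
}

#' @export
length.segment_set <- function(x) length(x$segments)

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d x %s segments of %d samples @ %g Hz (seed %s)\n",
              length(x), x$source, x$length, x$fs, format(x$seed)))
  invisible(x)
}

#' Stack a segment set into a numeric matrix
#'
#' @param set a [segment_set].
#' @return matrix with one row per segment.
#' @export
segment_matrix <- function(set) {
  stopifnot(inherits(set, "segment_set"))
  do.call(rbind, lapply(set$segments, function(s) s$samples))
}

# Zero-phase Butterworth band-pass. Low normalized corner frequencies
# (EOG at 0.3 Hz) need a low order for numerical stability with filtfilt.
bandpass <- function(x, fs, lo, hi, order = 4L) {
  ny <- fs / 2
  if (hi >= ny) stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

unit_rms <- function(x) {
  r <- rms(x)
  if (r == 0) stop("cannot normalize a zero-power segment")
  x / r
}

# Random phase spectral synthesis: coloured noise with amplitude spectrum
# |X(f)| ~ f^(-slope/2) (power ~ f^-slope), f in Hz, zero DC.
coloured_noise <- function(length, fs, slope) {
  nf <- length %/% 2
  f <- seq_len(nf) * fs / length
  amp <- pmax(f, 1)^(-slope / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(length)
  full[2:(nf + 1)] <- spec
  if (length %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))
    full[seq(length, nf + 2)] <- Conj(full[2:nf])
  } else {
    full[seq(length, nf + 1)] <- Conj(full[2:(nf + 1)])
  }
  Re(stats::fft(full, inverse = TRUE)) / length
}

check_gen_args <- function(n, length, fs, min_fs) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (!is.numeric(length) || length(length) != 1L || length < 64 ||
      length != round(length))
    stop("'length' must be an integer >= 64")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= min_fs)
    stop(sprintf("'fs' must exceed %g Hz so the band edge is below Nyquist",
                 min_fs))
  invisible(TRUE)
}

#' Generate surrogate clean-EEG segments
#'
#' Produces band-limited surrogates with the spectral structure of
#' resting scalp EEG: 1/f-weighted background noise plus an
#' amplitude-modulated alpha-band (8-13 Hz) oscillation, band-pass
#' filtered to 1-80 Hz and normalized to unit RMS. These emulate the
#' band structure of curated clean-EEG benchmark segments (2 s windows
#' at 256 Hz), not physiological detail.
#'
#' @param n number of segments.
#' @param length samples per segment (default 512).
#' @param fs sampling rate in Hz; must exceed 160 so the 80 Hz band edge
#'   is below Nyquist.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A [segment_set] of `n` unit-RMS `"eeg"` segments.
#' @examples
#' eeg <- gen_clean_eeg(3, seed = 7)
#' rms(eeg$segments[[1]]$samples)
#' @export
gen_clean_eeg <- function(n, length = 512, fs = 256, seed = 1) {
  check_gen_args(n, length, fs, 160)
  withr::with_seed(seed, {
    segs <- lapply(seq_len(n), function(i) {
      x <- coloured_noise(length, fs, slope = 1)
      t <- seq(0, by = 1 / fs, length.out = length)
      f_alpha <- stats::runif(1, 8, 13)
      # slow (< 2 Hz) positive envelope emulating waxing/waning alpha
      env <- 1 + 0.5 * sin(2 * pi * stats::runif(1, 0.2, 2) * t +
                             stats::runif(1, 0, 2 * pi))
      amp <- stats::runif(1, 0.5, 1.5) * stats::sd(x)
      x <- x + amp * env * sin(2 * pi * f_alpha * t + stats::runif(1, 0, 2 * pi))
      x <- bandpass(x, fs, 1, 80)
      signal_segment(unit_rms(x), fs = fs, source = "eeg")
    })
    segment_set(segs, seed = seed)
  })
}

#' Generate surrogate EOG (ocular artifact) segments
#'
#' Low-frequency smoothed noise plus randomly placed blink-like
#' transients, band-limited to 0.3-10 Hz, unit RMS.
#'
#' @inheritParams gen_clean_eeg
#' @return A [segment_set] of `"eog"` segments.
#' @export
gen_eog <- function(n, length = 512, fs = 256, seed = 1) {
  check_gen_args(n, length, fs, 20)
  withr::with_seed(seed, {
    segs <- lapply(seq_len(n), function(i) {
      x <- coloured_noise(length, fs, slope = 2)
      t <- seq(0, by = 1 / fs, length.out = length)
      n_blinks <- stats::rpois(1, 1.5)
      if (n_blinks > 0) {
        for (b in seq_len(n_blinks)) {
          centre <- stats::runif(1, 0.1, length / fs - 0.1)
          width <- stats::runif(1, 0.08, 0.2)          # blink half-width, s
          amp <- stats::runif(1, 2, 6) * stats::sd(x)  # blinks dominate
          x <- x + amp * exp(-((t - centre)^2) / (2 * width^2))
        }
      }
      x <- bandpass(x, fs, 0.3, 10, order = 2L)
      signal_segment(unit_rms(x), fs = fs, source = "eog")
    })
    segment_set(segs, seed = seed)
  })
}

#' Generate surrogate EMG (myogenic artifact) segments
#'
#' Broadband noise with random burst-envelope amplitude modulation,
#' band-limited to 1-120 Hz, unit RMS.
#'
#' @inheritParams gen_clean_eeg
#' @param fs sampling rate in Hz; must exceed 240 so the 120 Hz band edge
#'   is below Nyquist.
#' @return A [segment_set] of `"emg"` segments.
#' @export
gen_emg <- function(n, length = 512, fs = 256, seed = 1) {
  check_gen_args(n, length, fs, 240)
  withr::with_seed(seed, {
    segs <- lapply(seq_len(n), function(i) {
      x <- stats::rnorm(length)
      env <- rep(0.3, length)
      n_bursts <- 1 + stats::rpois(1, 1)
      for (b in seq_len(n_bursts)) {
        start <- sample.int(length, 1)
        dur <- round(stats::runif(1, 0.1, 0.6) * fs)
        idx <- start:min(length, start + dur)
        env[idx] <- env[idx] + stats::runif(1, 1, 3)
      }
      x <- bandpass(x * env, fs, 1, 120)
      signal_segment(unit_rms(x), fs = fs, source = "emg")
    })
    segment_set(segs, seed = seed)
  })
}

#' Load a segment matrix from a delimited text file
#'
#' Adapter for benchmark-style segment matrices (rows = segments,
#' columns = samples) stored as plain-text numeric arrays (CSV,
#' tab- or whitespace-separated).
#'
#' @param path file path.
#' @param fs sampling rate to attach, Hz.
#' @param source source label for the segments.
#' @return A [segment_set] with one segment per row.
#' @export
load_segment_matrix <- function(path, fs = 256,
                                source = c("eeg", "eog", "emg")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  dat <- tryCatch(utils::read.table(path, sep = sep, header = FALSE),
                  error = function(e)
                    stop("cannot parse '", path, "' as a numeric matrix: ",
                         conditionMessage(e)))
  m <- as.matrix(dat)
  if (!is.numeric(m))
    stop("file does not contain a numeric matrix: ", path)
  if (ncol(m) < 2L)
    stop("expected a 2-D segment matrix (rows = segments, columns = samples); ",
         "got ", ncol(m), " column(s)")
  segs <- lapply(seq_len(nrow(m)), function(i)
    signal_segment(m[i, ], fs = fs, source = source))
  segment_set(segs, seed = NA_integer_)
}

#' Random train/test split of a segment set
#'
#' Disjoint partition with `round(n * train_fraction)` training segments,
#' permuted deterministically by the seed.
#'
#' @param set a [segment_set].
#' @param train_fraction proportion assigned to training, in (0, 1).
#' @param seed integer seed for the permutation.
#' @return A list with components `train` and `test`, both [segment_set]s.
#' @export
split_train_test <- function(set, train_fraction = 0.8, seed = 1) {
  stopifnot(inherits(set, "segment_set"))
  n <- length(set)
  if (n < 1L) stop("cannot split an empty segment set")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("'train_fraction' must be strictly between 0 and 1")
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    stop("split leaves an empty partition; adjust 'train_fraction'")
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = segment_set(set$segments[perm[seq_len(n_train)]], seed = seed),
       test = segment_set(set$segments[perm[(n_train + 1L):n]], seed = seed))
}
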