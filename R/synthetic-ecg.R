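#' Configuration for the synthetic ECG-like signal generator
#'
#' The generator produces labeled, amplitude-bounded, fixed-length signals
#' whose class structure mirrors what the training and robustness methods in
#' this package assume about real single-lead ECG: rhythm regularity
#' differences between classes, morphology differences (P/QRS/T bumps), and
#' class-discriminative narrowband content placed on opposite sides of a
#' configurable split frequency so that frequency-partitioned ensembles have
#' something band-specific to learn. It is *not* a physiological simulator.
#'
#' The four default classes are:
#' \describe{
#'   \item{normal}{regular pulse trains with P, QRS and T bumps;}
#'   \item{afib_like}{irregular inter-beat intervals, no P bump, plus a
#'     4--9 Hz baseline oscillation emulating fibrillatory waves;}
#'   \item{other}{regular rhythm but widened QRS morphology;}
#'   \item{noise}{band-limited noise with no pulse structure.}
#' }
#' In addition every class carries a weak narrowband tone at a
#' class-specific frequency; classes 0 and 2 sit below `band_split`, classes
#' 1 and 3 above it.
#'
#' @param sampling_rate Sampling rate in Hz (default 100; real challenge data
#'   are 300/500 Hz, heavier than needed to exercise the methods).
#' @param duration Record duration in seconds (default 10).
#' @param n_channels Number of channels (default 1).
#' @param class_names Ordered class names; the generator knows how to build
#'   `"normal"`, `"afib_like"`, `"other"` and `"noise"`.
#' @param rr_mean Named numeric vector of mean inter-beat intervals in
#'   seconds per class (ignored for `"noise"`).
#' @param rr_jitter Named numeric vector of the half-width of the uniform
#'   inter-beat jitter, in seconds.
#' @param band_split Frequency (Hz) separating low-band from high-band
#'   class-discriminative tones; defaults to `sampling_rate / 8`, matching
#'   the default partition edge of [design_ring_filters()].
#' @param tone_amp Amplitude of the class-discriminative tone before
#'   normalization.
#' @param noise_sd Standard deviation of the additive white measurement
#'   noise before normalization.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   datasets.
#'
#' @return An object of class `ecg_generator_config`.
#' @export
ecg_generator_config <- function(sampling_rate = 100, duration = 10,
                                 n_channels = 1L,
                                 class_names = c("normal", "afib_like",
                                                 "other", "noise"),
                                 rr_mean = c(normal = 0.8, afib_like = 0.75,
                                             other = 1.0, noise = 0.8),
                                 rr_jitter = c(normal = 0.02, afib_like = 0.22,
                                               other = 0.04, noise = 0),
                                 band_split = sampling_rate / 8,
                                 tone_amp = 0.15,
                                 noise_sd = 0.03,
                                 seed = 1L) {
  check_domain(is_scalar_num(sampling_rate) && sampling_rate > 0,
               "`sampling_rate` must be > 0")
  check_domain(is_scalar_num(duration) && duration > 0, "`duration` must be > 0")
  check_domain(is_count(n_channels), "`n_channels` must be a positive count")
  check_domain(length(class_names) >= 2, "need at least two classes")
  check_domain(band_split > 0 && band_split < sampling_rate / 2,
               "`band_split` must lie strictly inside (0, Nyquist)")
  rr_mean <- rr_mean[class_names]
  rr_jitter <- rr_jitter[class_names]
  names(rr_mean) <- names(rr_jitter) <- class_names
  rr_mean[is.na(rr_mean)] <- 0.8
  rr_jitter[is.na(rr_jitter)] <- 0.05
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         n_channels = as.integer(n_channels), class_names = class_names,
         rr_mean = rr_mean, rr_jitter = rr_jitter,
         band_split = band_split, tone_amp = tone_amp, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "ecg_generator_config")
}

# Class-discriminative tone frequencies: alternate classes sit below/above
# the split so partitioned members see different discriminative content.
# Even class indices (0, 2, ...) get low-band tones, odd indices high-band.
class_tone_freq <- function(class_index, config) {
  fs <- config$sampling_rate
  split <- config$band_split
  low <- split * c(0.45, 0.65, 0.30, 0.80, 0.55)       # below the split
  high <- split + (fs / 2 - split) * c(0.35, 0.55, 0.20, 0.70, 0.45)
  side <- class_index %% 2L
  pick <- (class_index %/% 2L) %% 5L + 1L
  if (side == 0L) low[pick] else high[pick]
}

# Gaussian bump evaluated on sample time grid (seconds).
gauss_bump <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

# One heartbeat waveform centered at 0: P + QRS (difference of Gaussians) + T.
# Constants are generator inventions tuned for visual ECG likeness only.
beat_waveform <- function(t, widen_qrs = 1, with_p = TRUE) {
  w <- widen_qrs
  qrs <- gauss_bump(t, 0, 0.018 * w, 1.0) - gauss_bump(t, 0.035 * w, 0.028 * w, 0.35)
  tw <- gauss_bump(t, 0.26, 0.06, 0.28)
  p <- if (with_p) gauss_bump(t, -0.17, 0.03, 0.18) else 0
  qrs + tw + p
}

#' Generate one synthetic record of a given class
#'
#' Draws from the *current* R random stream; callers that need
#' reproducibility seed the stream first (as [generate_dataset()] does).
#'
#' @param class_index Zero-based class index, `0 <= class_index < C`.
#' @param config An [ecg_generator_config()].
#' @return A `channels x T` numeric matrix with values in `[-1, 1]`.
#' @export
generate_record <- function(class_index, config) {
  cls <- config$class_names
  check_domain(is_count(class_index, positive = FALSE) && class_index >= 0 &&
                 class_index < length(cls),
               sprintf("`class_index` must be in [0, %d)", length(cls)))
  fs <- config$sampling_rate
  t_len <- round(fs * config$duration)
  tt <- (seq_len(t_len) - 1) / fs
  name <- cls[class_index + 1L]

  base <- numeric(t_len)
  if (name != "noise") {
    rr_mean <- config$rr_mean[[name]]
    rr_jit <- config$rr_jitter[[name]]
    # Beat onsets: intervals are rounded to whole samples individually so the
    # zero-jitter case yields exactly equal spacing.
    first <- round(runif(1, 0.25, 0.55) * fs)
    pos <- first
    positions <- integer(0)
    repeat {
      if (pos > t_len) break
      positions <- c(positions, pos)
      step <- round((rr_mean + runif(1, -rr_jit, rr_jit)) * fs)
      pos <- pos + max(step, round(0.25 * fs))
    }
    for (p in positions) {
      tc <- tt - (p - 1) / fs
      base <- base + beat_waveform(tc,
                                   widen_qrs = if (name == "other") 2.2 else 1,
                                   with_p = name != "afib_like")
    }
    if (name == "afib_like") {
      f_fib <- runif(1, 4, 9)               # fibrillatory baseline oscillation
      base <- base + 0.12 * sin(2 * pi * f_fib * tt + runif(1, 0, 2 * pi))
    }
  } else {
    # Band-limited noise: white noise low-passed below ~0.7 * Nyquist.
    w <- rnorm(t_len)
    base <- bandlimit(w, fs, 0.35 * fs) * 0.4
  }

  tone_f <- class_tone_freq(class_index, config)
  base <- base + config$tone_amp * sin(2 * pi * tone_f * tt + runif(1, 0, 2 * pi))

  out <- matrix(0, config$n_channels, t_len)
  gains <- seq(1, 0.6, length.out = config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    out[ch, ] <- gains[ch] * base + rnorm(t_len, sd = config$noise_sd)
  }
  m <- max(abs(out))
  if (m > 0) out <- out / m                 # per-record max-abs normalization
  out
}

# Zero-phase FFT low-pass used by the noise class.
bandlimit <- function(x, fs, cutoff) {
  t_len <- length(x)
  f <- (seq_len(t_len) - 1) * fs / t_len
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  mask <- as.numeric(f <= cutoff)
  Re(fft(fft(x) * mask, inverse = TRUE) / t_len)
}

#' Generate a balanced, shuffled synthetic dataset
#'
#' Produces `n_per_class * C` records, shuffled with the config seed. Record
#' ids are assigned before shuffling and are therefore stable across runs
#' with the same configuration.
#'
#' @param n_per_class Records per class (>= 1).
#' @param config An [ecg_generator_config()].
#' @return A [signal_batch()].
#' @export
generate_dataset <- function(n_per_class, config) {
  check_domain(is_count(n_per_class), "`n_per_class` must be >= 1")
  cls <- config$class_names
  n_cls <- length(cls)
  n <- n_per_class * n_cls
  t_len <- round(config$sampling_rate * config$duration)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  signals <- array(0, c(n, config$n_channels, t_len))
  labels <- integer(n)
  ids <- character(n)
  i <- 0L
  for (c_idx in seq_len(n_cls) - 1L) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      signals[i, , ] <- generate_record(c_idx, config)
      labels[i] <- c_idx
      ids[i] <- sprintf("rec_%s_%04d", cls[c_idx + 1L], j)
    }
  }
  ord <- sample.int(n)
  signal_batch(signals[ord, , , drop = FALSE], labels[ord], ids[ord],
               config$sampling_rate, n_classes = n_cls, class_names = cls)
}
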