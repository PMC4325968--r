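#' Default 23-channel bipolar montage
#'
#' Channel labels for the synthetic recordings, modelled on the standard
#' 10-20 bipolar longitudinal montage used by public paediatric scalp-EEG
#' archives. One archive channel appears twice under the same name there;
#' because channel labels must be unique, the second occurrence is
#' disambiguated as `"T8-P8-2"`.
#'
#' @return Character vector of 23 unique channel labels.
#' @export
default_montage <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FZ-CZ", "CZ-PZ",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "P7-T7", "T7-FT9", "FT9-FT10", "FT10-T8", "T8-P8-2")
}

#' Synthetic EEG generation parameters
#'
#' Free parameters of the synthetic generator. Background activity is
#' 1/f^alpha Gaussian noise plus a weak 10 Hz alpha rhythm; ictal activity
#' superimposes an amplitude-modulated low-frequency oscillation (default
#' 3 Hz, with a second harmonic) on a contiguous scalp region, emulating
#' the three signatures a seizure shows on scalp EEG: a dominant cyclic
#' spectral peak, an elevated delta+theta share of signal energy, and a drop
#' in signal entropy. Occasional runs of exact-zero samples emulate the
#' missing data the preprocessing stage must repair.
#'
#' @param n_channels number of channels (default 23; at 23 the default
#'   montage labels are used, otherwise `CH1..CHn`).
#' @param fs sampling rate in Hz (default 256).
#' @param block_duration block length in seconds (default 60).
#' @param seizure_peak_freq dominant ictal frequency in Hz (default 3,
#'   inside the delta range with its harmonic in theta); must be below fs/2.
#' @param seizure_amplitude_gain ictal oscillation amplitude as a multiple
#'   of `noise_sd` (default 3).
#' @param background_spectral_exponent alpha of the 1/f^alpha background
#'   (default 1).
#' @param missing_run_rate expected number of zero-runs per record
#'   (Poisson; default 1).
#' @param noise_sd background standard deviation in microvolts (default 20).
#' @param seed integer seed; fixes all randomness of a call.
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(n_channels = 23L, fs = 256, block_duration = 60,
                       seizure_peak_freq = 3, seizure_amplitude_gain = 3,
                       background_spectral_exponent = 1,
                       missing_run_rate = 1, noise_sd = 20, seed = NULL) {
  stopifnot_scalar(fs, "fs")
  stopifnot_scalar(block_duration, "block_duration")
  stopifnot_scalar(seizure_peak_freq, "seizure_peak_freq")
  stopifnot_scalar(noise_sd, "noise_sd")
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  if (seizure_peak_freq >= fs / 2) {
    stop("seizure_peak_freq must be below the Nyquist frequency",
         call. = FALSE)
  }
  if (missing_run_rate < 0) stop("missing_run_rate must be >= 0",
                                 call. = FALSE)
  labels <- if (n_channels == 23L) default_montage() else
    sprintf("CH%d", seq_len(n_channels))
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 block_duration = block_duration,
                 seizure_peak_freq = seizure_peak_freq,
                 seizure_amplitude_gain = seizure_amplitude_gain,
                 background_spectral_exponent = background_spectral_exponent,
                 missing_run_rate = missing_run_rate, noise_sd = noise_sd,
                 seed = seed, channel_labels = labels),
            class = "gen_params")
}

# one channel of 1/f^alpha Gaussian background, sd = noise_sd
pink_noise <- function(n, fs, alpha, sd_target) {
  w <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  shape <- 1 / pmax(f, 0.5)^(alpha / 2)
  shape[1L] <- 0                       # remove DC
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

#' Generate one synthetic EEG record
#'
#' Produces an `n_channels x (fs * block_duration)` record. Nonseizure
#' records are pure 1/f^alpha background with a weak alpha rhythm. Seizure
#' records additionally carry an amplitude-modulated oscillation at
#' `seizure_peak_freq` (plus a weaker second harmonic) on one randomly
#' chosen contiguous channel region, emulating a focal seizure; the whole
#' block is annotated as ictal. Zero-runs are injected at `missing_run_rate`
#' runs per record.
#'
#' @param params a [gen_params()].
#' @param is_seizure logical: superimpose ictal activity?
#' @return An [eeg_record] with a `seizure` or `nonseizure` annotation
#'   covering the block.
#' @export
generate_record <- function(params, is_seizure = FALSE) {
  stopifnot(inherits(params, "gen_params"))
  with_local_seed(params$seed, {
    n <- as.integer(round(params$fs * params$block_duration))
    tm <- (seq_len(n) - 1) / params$fs
    data <- matrix(0, params$n_channels, n)
    for (i in seq_len(params$n_channels)) {
      bg <- pink_noise(n, params$fs, params$background_spectral_exponent,
                       params$noise_sd)
      alpha_amp <- 0.4 * params$noise_sd
      data[i, ] <- bg + alpha_amp * sin(2 * pi * 10 * tm +
                                          stats::runif(1, 0, 2 * pi))
    }
    if (is_seizure) {
      focus <- seizure_focus_channels(params)
      f0 <- params$seizure_peak_freq
      amp <- params$seizure_amplitude_gain * params$noise_sd
      # Hann-like envelope with a slower waxing-waning modulation: energy
      # concentrates mid-block, which is what depresses the signal entropy
      env <- (0.5 - 0.5 * cos(2 * pi * tm / params$block_duration)) *
        (1 + 0.3 * sin(2 * pi * 0.25 * tm + stats::runif(1, 0, 2 * pi)))
      for (i in focus) {
        ph <- stats::runif(2, 0, 2 * pi)
        data[i, ] <- data[i, ] + amp * env *
          (sin(2 * pi * f0 * tm + ph[1]) +
             0.4 * sin(2 * pi * 2 * f0 * tm + ph[2]))
      }
    }
    if (params$missing_run_rate > 0) {
      n_runs <- stats::rpois(1, params$missing_run_rate)
      for (r in seq_len(n_runs)) {
        ch <- sample_int(params$n_channels, 1L)
        run_len <- sample_int(16L, 1L)
        start <- sample_int(n - run_len + 1L, 1L)
        data[ch, start:(start + run_len - 1L)] <- 0
      }
    }
    eeg_record(data, params$fs, params$channel_labels,
               annotations = data.frame(
                 onset = 0, offset = params$block_duration,
                 label = if (is_seizure) "seizure" else "nonseizure"))
  })
}

# focal seizures are injected on one scalp region's channels (when the
# montage matches the default region map) or on a random contiguous run
seizure_focus_channels <- function(params) {
  rm_ <- region_map_default(quiet = TRUE)
  region_chs <- lapply(rm_$channels, intersect, x = params$channel_labels)
  region_chs <- Filter(length, region_chs)
  if (length(region_chs)) {
    chs <- region_chs[[sample_int(length(region_chs), 1L)]]
    match(chs, params$channel_labels)
  } else {
    width <- min(params$n_channels, 4L)
    start <- sample_int(params$n_channels - width + 1L, 1L)
    start:(start + width - 1L)
  }
}

#' Generate a labelled dataset of synthetic blocks
#'
#' Draws `n_seizure` seizure and `n_nonseizure` nonseizure records with
#' [generate_record()] and returns them as labelled [segment_block]s, each
#' `block_duration` seconds long. Each block gets its own sub-seed derived
#' from `params$seed`, so the whole dataset is reproducible.
#'
#' @param params a [gen_params()].
#' @param n_seizure,n_nonseizure per-class block counts (>= 0).
#' @return List of `n_seizure + n_nonseizure` [segment_block]s (seizure
#'   blocks first).
#' @export
generate_dataset <- function(params, n_seizure, n_nonseizure) {
  stopifnot(inherits(params, "gen_params"))
  if (n_seizure < 0 || n_nonseizure < 0) stop("counts must be >= 0",
                                              call. = FALSE)
  base <- if (is.null(params$seed)) NULL else as.integer(params$seed)
  one <- function(i, is_seizure) {
    p <- params
    if (!is.null(base)) {
      p$seed <- (base + i + if (is_seizure) 0L else 500000L) %% .Machine$integer.max
    }
    rec <- generate_record(p, is_seizure)
    segment_block(rec$data, rec$fs, rec$channel_labels,
                  label = if (is_seizure) "seizure" else "nonseizure",
                  source_id = sprintf("synthetic-%s-%d",
                                      if (is_seizure) "sz" else "ns", i))
  }
  c(lapply(seq_len(n_seizure), one, is_seizure = TRUE),
    lapply(seq_len(n_nonseizure), one, is_seizure = FALSE))
}

#' Delta+theta share of broadband signal energy
#'
#' Convenience summary used to validate the generator: the summed signal
#' energy of the delta and theta band signals across all channels, divided
#' by the summed broadband (0.5-30 Hz) energy. Seizure blocks concentrate
#' energy at low frequency, so this fraction is higher for them.
#'
#' @param block a [segment_block] or [eeg_record].
#' @param bands band specifications (default [band_specs()]).
#' @return A fraction in (0, 1) (can slightly exceed 1 at band overlaps).
#' @export
delta_theta_energy_fraction <- function(block, bands = band_specs()) {
  need <- bands[c("broadband", "delta", "theta")]
  num <- 0
  den <- 0
  for (i in seq_len(nrow(block$data))) {
    x <- block$data[i, ]
    den <- den + energy(bandpass(x, block$fs, need$broadband))
    num <- num + energy(bandpass(x, block$fs, need$delta)) +
      energy(bandpass(x, block$fs, need$theta))
  }
  num / den
}

#' Mean per-channel signal entropy of a block
#'
#' The [signal_entropy()] of each channel's raw signal, averaged over
#' channels; the generator's ictal blocks have lower values.
#'
#' @param block a [segment_block] or [eeg_record].
#' @return A single number.
#' @export
block_entropy <- function(block) {
  mean(apply(block$data, 1L, signal_entropy))
}
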