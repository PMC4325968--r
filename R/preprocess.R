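#' Frequency band specifications
#'
#' `band_spec()` describes one bandpass: name, lower and upper edge in Hz and
#' Butterworth filter order (default 2). `band_specs()` returns the five
#' default bands used throughout the pipeline: broadband 0.5-30 Hz plus the
#' classical delta (0.5-4), theta (4-8), alpha (8-12) and beta (12-25) EEG
#' bands. The beta upper edge is configurable because reported feature labels
#' in this literature sometimes print 12-30 Hz for the same band.
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @param order Butterworth order (applied forward and backward, so the
#'   effective magnitude response is the squared order-`order` response).
#' @return `band_spec()` a `band_spec` object; `band_specs()` a named list of
#'   five of them.
#' @export
band_spec <- function(name, low, high, order = 2L) {
  stopifnot_scalar(low, "low")
  stopifnot_scalar(high, "high")
  if (low >= high) stop("band edges must satisfy 0 < low < high",
                        call. = FALSE)
  structure(list(name = as.character(name), low = low, high = high,
                 order = as.integer(order)),
            class = "band_spec")
}

#' @param beta_high upper beta edge in Hz (default 25).
#' @param order Butterworth order for every band.
#' @rdname band_spec
#' @export
band_specs <- function(beta_high = 25, order = 2L) {
  list(broadband = band_spec("broadband", 0.5, 30, order),
       delta = band_spec("delta", 0.5, 4, order),
       theta = band_spec("theta", 4, 8, order),
       alpha = band_spec("alpha", 8, 12, order),
       beta = band_spec("beta", 12, beta_high, order))
}

#' Repair missing or zeroed samples
#'
#' Replaces every exact-zero or `NA` sample by the mean of the non-missing
#' samples inside a window of `window/2` samples on each side of it
#' (truncated at the record edges). Runs of missing samples are repaired
#' sample by sample using only originally non-missing neighbours, so the
#' result does not depend on repair order; a missing sample whose whole
#' window is missing (a run longer than the window) is a degenerate input
#' and raises an error, as is an entirely missing signal.
#'
#' @param x numeric signal; `NA` and exact zeros are treated as missing.
#' @param fs sampling rate (unused by the rule itself; kept for interface
#'   symmetry with the other per-signal operations).
#' @param window window width in samples (even, >= 2; default 256).
#' @return The repaired signal, same length as `x`.
#' @export
repair_missing <- function(x, fs = NULL, window = 256L) {
  window <- as.integer(window)
  if (window < 2L || window %% 2L != 0L) {
    stop("'window' must be an even integer >= 2", call. = FALSE)
  }
  miss <- is.na(x) | x == 0
  if (!any(miss)) return(x)
  if (all(miss)) stop("degenerate input: all samples missing", call. = FALSE)
  half <- window %/% 2L
  n <- length(x)
  out <- x
  for (i in which(miss)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    nb <- (lo:hi)[!miss[lo:hi]]
    if (!length(nb)) {
      stop("degenerate input: missing run longer than the repair window",
           call. = FALSE)
    }
    out[i] <- mean(x[nb])
  }
  out
}

# repair every channel of a block/record in place
repair_block <- function(block, window = 256L) {
  if (!anyNA(block$data) && all(block$data != 0)) return(block)
  for (i in seq_len(nrow(block$data))) {
    row <- block$data[i, ]
    if (anyNA(row) || any(row == 0)) {
      block$data[i, ] <- repair_missing(row, block$fs, window)
    }
  }
  block
}

#' Zero-phase Butterworth bandpass
#'
#' Applies an order-`band$order` Butterworth bandpass forward and backward
#' ([signal::filtfilt()]), so the output is not phase-shifted relative to
#' the input and seizure annotations; the effective magnitude response is
#' the squared one-pass response.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, band) {
  stopifnot(inherits(band, "band_spec"))
  nyq <- fs / 2
  if (band$high >= nyq || band$low <= 0) {
    stop("band edges must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  key <- sprintf("%d|%.9g|%.9g|%.9g", band$order, band$low, band$high, fs)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(band$order, c(band$low, band$high) / nyq,
                         type = "pass")
    .butter_cache[[key]] <- bf
  }
  as.numeric(signal::filtfilt(bf, x))
}

.butter_cache <- new.env(parent = emptyenv())

#' Decompose a block into per-band signals
#'
#' Filters every channel of a segment through each band of `bands`,
#' producing the broadband signal plus the four classical band signals per
#' channel: a 23-channel segment yields 115 signals. Order is deterministic:
#' channel-major, band-minor.
#'
#' @param block a [segment_block] (or [eeg_record]); missing samples should
#'   be repaired first.
#' @param bands list of [band_spec()]s, default [band_specs()].
#' @return A `band_signal_set`: list with `signals` (list of numeric
#'   vectors) and `descriptors` (data.frame of channel label and band name,
#'   one row per signal).
#' @export
decompose <- function(block, bands = band_specs()) {
  data <- block$data
  labels <- block$channel_labels
  fs <- block$fs
  band_names <- vapply(bands, `[[`, "", "name")
  signals <- vector("list", nrow(data) * length(bands))
  k <- 0L
  for (i in seq_len(nrow(data))) {
    for (b in bands) {
      k <- k + 1L
      signals[[k]] <- bandpass(data[i, ], fs, b)
    }
  }
  structure(list(
    signals = signals,
    descriptors = data.frame(
      channel = rep(labels, each = length(bands)),
      band = rep(band_names, times = nrow(data)),
      stringsAsFactors = FALSE),
    fs = fs), class = "band_signal_set")
}

#' @export
print.band_signal_set <- function(x, ...) {
  cat(sprintf("<band_signal_set> %d signals (%d channels x %d bands)\n",
              length(x$signals), length(unique(x$descriptors$channel)),
              length(unique(x$descriptors$band))))
  invisible(x)
}

#' Cut labelled fixed-duration blocks from an annotated record
#'
#' Emits one seizure block per annotated seizure, anchored at the annotated
#' onset (ictal periods often exceed the block length, so the window starts
#' at onset rather than being centred); an onset too close to the record end
#' is shifted left so the block fits, and skipped with a warning when the
#' record is shorter than one block. Optionally also cuts randomly
#' positioned nonseizure blocks that do not overlap any annotated seizure
#' interval.
#'
#' @param record an [eeg_record] with annotations (labels equal to
#'   `"seizure"` mark ictal intervals).
#' @param duration block length in seconds (default 60).
#' @param n_nonseizure number of nonseizure blocks to cut (default 0).
#' @param seed optional integer fixing the placement of nonseizure blocks.
#' @return List of [segment_block]s.
#' @export
extract_blocks <- function(record, duration = 60, n_nonseizure = 0L,
                           seed = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  n <- ncol(record$data)
  fs <- record$fs
  len <- as.integer(round(duration * fs))
  if (len > n) stop("duration exceeds record length", call. = FALSE)
  ann <- record$annotations
  sz <- if (is.null(ann)) NULL else ann[ann$label == "seizure", ,
                                        drop = FALSE]
  blocks <- list()
  take <- function(start_sample, label, id) {
    segment_block(record$data[, start_sample:(start_sample + len - 1L),
                              drop = FALSE],
                  fs, record$channel_labels, label = label, source_id = id)
  }
  if (!is.null(sz) && nrow(sz)) {
    for (i in seq_len(nrow(sz))) {
      start <- as.integer(round(sz$onset[i] * fs)) + 1L
      if (start + len - 1L > n) start <- n - len + 1L  # shift left to fit
      if (start < 1L) {
        warning("seizure block does not fit in record; skipped")
        next
      }
      blocks[[length(blocks) + 1L]] <-
        take(start, "seizure", sprintf("seizure-%d", i))
    }
  }
  if (n_nonseizure > 0L) {
    with_local_seed(seed, {
      candidates <- seq_len(n - len + 1L)
      if (!is.null(sz) && nrow(sz)) {
        ok <- rep(TRUE, length(candidates))
        for (i in seq_len(nrow(sz))) {
          a <- sz$onset[i] * fs + 1
          b <- sz$offset[i] * fs
          # block [s, s+len-1] intersects [a, b] iff s <= b and s+len-1 >= a
          ok <- ok & (candidates > b | candidates + len - 1L < a)
        }
        candidates <- candidates[ok]
      }
      if (!length(candidates)) {
        warning("no nonseizure placement avoids seizure intervals")
      } else {
        starts <- candidates[sample_int(length(candidates),
                                        size = n_nonseizure, replace = TRUE)]
        for (i in seq_along(starts)) {
          blocks[[length(blocks) + 1L]] <-
            take(starts[i], "nonseizure", sprintf("nonseizure-%d", i))
        }
      }
    })
  }
  blocks
}
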