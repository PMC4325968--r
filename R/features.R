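#' Welch-averaged power spectrum
#'
#' One-sided power spectrum of a signal, estimated by averaging modified
#' periodograms over Hann-windowed segments with 50% overlap (4-second
#' segments by default). Normalisation is Parseval-consistent: the sum of
#' the one-sided bin powers approximates the variance of the (mean-removed)
#' signal, so band powers read directly as signal power in uV^2.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param segment_sec segment length in seconds (truncated to the signal
#'   length when the signal is shorter).
#' @param overlap fractional overlap between consecutive segments.
#' @return An object of class `eeg_spectrum`: list with `frequencies` (Hz,
#'   0 .. fs/2), `power` (>= 0), `fs`, and `n` (number of time samples).
#' @export
estimate_psd <- function(x, fs, segment_sec = 4, overlap = 0.5) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  stopifnot_scalar(fs, "fs")
  nseg <- min(length(x), max(8L, as.integer(round(segment_sec * fs))))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  wss <- sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * w))^2
  }
  # Parseval: sum_k |FFT(y)_k|^2 = nseg * sum(y^2) and E sum(w x)^2 = var * wss,
  # so dividing by (nseg * wss) makes the bin powers sum to ~ var(x).
  p_full <- acc / (length(starts) * nseg * wss)
  half <- floor(nseg / 2)
  p <- p_full[1:(half + 1L)]
  # fold negative frequencies onto the positive half
  if (nseg %% 2 == 0) {
    p[2:half] <- 2 * p[2:half]
  } else {
    p[2:(half + 1L)] <- 2 * p[2:(half + 1L)]
  }
  structure(list(frequencies = (0:half) * fs / nseg, power = p,
                 fs = fs, n = length(x)),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d bins, 0-%g Hz (resolution %.3g Hz)\n",
              length(x$power), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Peak and median frequency of a power spectrum
#'
#' `peak_frequency` returns the frequency of the largest spectral bin (ties
#' broken toward the lowest frequency); on an all-zero spectrum it returns
#' 0 Hz with attribute `degenerate = TRUE`. `median_frequency` returns the
#' smallest grid frequency at which the cumulative power reaches half the
#' total, i.e. the midpoint splitting spectral power into equal halves.
#'
#' @param spec an `eeg_spectrum`.
#' @return Frequency in Hz.
#' @export
peak_frequency <- function(spec) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  if (!length(spec$power)) stop("empty spectrum", call. = FALSE)
  if (all(spec$power <= 0)) {
    return(structure(0, degenerate = TRUE))
  }
  spec$frequencies[which.max(spec$power)]
}

#' @rdname peak_frequency
#' @export
median_frequency <- function(spec) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  tot <- sum(spec$power)
  if (tot <= 0) stop("degenerate input: zero total spectral power",
                     call. = FALSE)
  spec$frequencies[which(cumsum(spec$power) >= tot / 2)[1L]]
}

#' Time-domain signal features
#'
#' The per-signal statistics extracted from every (channel, band) signal:
#' root mean square `sqrt(mean(x^2))`; total signal energy `sum(x^2)`;
#' unbiased sample variance; skewness and kurtosis as standardised third and
#' fourth population moments (kurtosis is non-excess: a normal signal gives
#' 3); and `signal_entropy`, the Shannon entropy of the normalised energy
#' distribution p_i = x_i^2 / sum(x^2), which drops when signal energy
#' concentrates in bursts, as during ictal activity.
#'
#' @param x numeric signal (no `NA`).
#' @return A single number.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  sqrt(mean(x^2))
}

#' @rdname rms
#' @export
energy <- function(x) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  sum(x^2)
}

#' @rdname rms
#' @export
signal_variance <- function(x) {
  if (length(x) < 2L) stop("variance needs at least 2 samples", call. = FALSE)
  stats::var(x)
}

#' @rdname rms
#' @export
skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) stop("degenerate input: zero standard deviation", call. = FALSE)
  mean((x - m)^3) / s2^1.5
}

#' @rdname rms
#' @export
kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) stop("degenerate input: zero standard deviation", call. = FALSE)
  mean((x - m)^4) / s2^2
}

#' @rdname rms
#' @export
signal_entropy <- function(x) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  e <- x^2
  tot <- sum(e)
  if (tot <= 0) stop("degenerate input: all-zero signal", call. = FALSE)
  p <- e[e > 0] / tot
  -sum(p * log(p))
}

#' Literal energy-log-energy sum
#'
#' The raw sum `sum(x_i * log(x_i^2))` over nonzero samples, kept alongside
#' [signal_entropy()] for auditability: it is the printed form of the
#' entropy-style feature, but it is neither sign- nor scale-normalised and
#' is not used in the default feature set.
#'
#' @param x numeric signal.
#' @return A single number.
#' @export
signal_entropy_literal <- function(x) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  nz <- x != 0
  sum(x[nz] * log(x[nz]^2))
}

#' Correlation dimension by correlation-integral scaling
#'
#' Grassberger-Procaccia estimate of the fractal (correlation) dimension of
#' a signal's reconstructed trajectory. The signal is delay-embedded into
#' `embed_dim`-dimensional vectors y_i; the correlation integral C(r) is the
#' fraction of pairs (i, j), i < j, whose distance is below r; and the
#' dimension is the slope of log C(r) against log r over the supplied radii.
#'
#' @param x numeric signal.
#' @param radii radii at which C(r) is evaluated; default log-spaced between
#'   the 5th and 50th percentile of the pairwise distances.
#' @param embed_dim embedding dimension (default 5).
#' @param delay embedding delay in samples (default 4).
#' @param max_points cap on the number of delay vectors (evenly subsampled)
#'   to keep pair counting tractable on long signals.
#' @return Estimated dimension (slope), a single number.
#' @export
correlation_dimension <- function(x, radii = NULL, embed_dim = 5L,
                                  delay = 4L, max_points = 400L) {
  m <- length(x) - (embed_dim - 1L) * delay
  if (m < 10L) stop("estimation error: too few points for embedding",
                    call. = FALSE)
  idx <- unique(as.integer(round(seq(1L, m, length.out = min(m, max_points)))))
  emb <- vapply(0:(embed_dim - 1L), function(k) x[idx + k * delay],
                numeric(length(idx)))
  d <- as.vector(stats::dist(emb))
  if (max(d) - min(d) < 1e-12) {
    stop("estimation error: all pairwise distances identical", call. = FALSE)
  }
  if (is.null(radii)) {
    q <- stats::quantile(d[d > 0], c(0.05, 0.5))
    radii <- exp(seq(log(q[[1L]]), log(q[[2L]]), length.out = 8L))
  }
  cr <- vapply(radii, function(r) mean(d < r), 0)
  keep <- cr > 0 & cr < 1
  if (sum(keep) < 2L) stop("estimation error: degenerate correlation integral",
                           call. = FALSE)
  unname(stats::coef(stats::lm(log(cr[keep]) ~ log(radii[keep])))[2L])
}

# the seven default features (whole-brain set: 23 channels x 5 bands x 7 = 805)
default_feature_set <- function() {
  c("rms", "variance", "skewness", "kurtosis", "peak_freq", "median_freq",
    "entropy")
}

feature_fun <- function(kind) {
  switch(kind,
    rms = function(x, fs) rms(x),
    variance = function(x, fs) signal_variance(x),
    skewness = function(x, fs) skewness(x),
    kurtosis = function(x, fs) kurtosis(x),
    entropy = function(x, fs) signal_entropy(x),
    energy = function(x, fs) energy(x),
    peak_freq = function(x, fs) as.numeric(peak_frequency(estimate_psd(x, fs))),
    median_freq = function(x, fs) median_frequency(estimate_psd(x, fs)),
    corr_dim = function(x, fs) correlation_dimension(x),
    stop("unknown feature kind: ", kind, call. = FALSE))
}

feature_display_name <- function(kind) {
  switch(kind,
    rms = "RMS", variance = "Variance", skewness = "Skewness",
    kurtosis = "Kurtosis", entropy = "Sample entropy", energy = "Energy",
    peak_freq = "Peak Freq", median_freq = "Med Freq",
    corr_dim = "Corr Dim", kind)
}

#' Feature matrix container
#'
#' Observations x features values with one descriptor per column (feature
#' kind, channel label, band name) and one class label per row. Column names
#' follow the field's reporting style, e.g. `"RMS CH2 0.5-30 Hz"`.
#'
#' @param values numeric matrix, observations x features.
#' @param descriptors data.frame with columns `feature`, `channel`, `band`
#'   (and optionally `channel_index`, `band_range`), one row per column.
#' @param labels factor or character of `"seizure"` / `"nonseizure"`, one
#'   per observation.
#' @param synthetic optional logical flag per row (set by SMOTE).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, labels, synthetic = NULL) {
  values <- as.matrix(values)
  descriptors <- as.data.frame(descriptors)
  if (nrow(descriptors) != ncol(values)) {
    stop("one descriptor per column is required", call. = FALSE)
  }
  if (anyDuplicated(descriptors[, c("feature", "channel", "band")])) {
    stop("(feature, channel, band) descriptors must be unique", call. = FALSE)
  }
  labels <- factor(as.character(labels), levels = c("nonseizure", "seizure"))
  if (length(labels) != nrow(values) || anyNA(labels)) {
    stop("one label ('seizure'/'nonseizure') per row is required",
         call. = FALSE)
  }
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(values))
  if (is.null(colnames(values)) && nrow(descriptors)) {
    colnames(values) <- descriptor_names(descriptors)
  }
  structure(list(values = values, descriptors = descriptors, labels = labels,
                 synthetic = synthetic),
            class = "feature_matrix")
}

descriptor_names <- function(d) {
  ch <- if ("channel_index" %in% names(d)) {
    sprintf("CH%d", d$channel_index)
  } else d$channel
  rng <- if ("band_range" %in% names(d)) d$band_range else d$band
  paste(vapply(as.character(d$feature), feature_display_name, ""), ch, rng)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d observations x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix
#'
#' Keeps the selected rows (observations) and/or columns (features),
#' carrying descriptors, labels and synthetic flags along.
#'
#' @param fm a [feature_matrix].
#' @param rows,cols index vectors; `NULL` keeps everything.
#' @return A [feature_matrix].
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$values))
  if (is.null(cols)) cols <- seq_len(ncol(fm$values))
  feature_matrix(fm$values[rows, cols, drop = FALSE],
                 fm$descriptors[cols, , drop = FALSE],
                 fm$labels[rows], fm$synthetic[rows])
}

#' Build the whole-brain feature matrix from labelled blocks
#'
#' For each block: repairs missing samples, decomposes every channel into
#' the broadband plus delta/theta/alpha/beta signals, and evaluates each
#' requested feature on each of the resulting (channel, band) signals. With
#' the default seven features, five bands and 23 channels this yields the
#' full 805-column feature space. Column order is deterministic:
#' channel-major, band-minor, feature-innermost.
#'
#' Features that are degenerate on a given block (e.g. entropy of an
#' all-zero band signal) are returned as `NA` and then imputed by the
#' column's finite mean, with a message; the assembled matrix contains no
#' non-finite values.
#'
#' @param blocks list of [segment_block]s sharing channel labels and fs.
#' @param feature_set character vector of feature kinds; default the seven
#'   canonical features (`rms`, `variance`, `skewness`, `kurtosis`,
#'   `peak_freq`, `median_freq`, `entropy`). `energy` and `corr_dim` are
#'   also available.
#' @param bands list of band specifications from [band_specs()].
#' @param repair repair missing/zero samples first (default `TRUE`).
#' @return A [feature_matrix] with one row per block.
#' @export
build_feature_matrix <- function(blocks, feature_set = default_feature_set(),
                                 bands = band_specs(), repair = TRUE) {
  stopifnot(length(blocks) >= 1L)
  labels0 <- blocks[[1L]]$channel_labels
  fs <- blocks[[1L]]$fs
  for (b in blocks) {
    if (!identical(b$channel_labels, labels0) || b$fs != fs) {
      stop("all blocks must share channel labels and sampling rate",
           call. = FALSE)
    }
  }
  spectral <- c("peak_freq", "median_freq")
  funs <- lapply(feature_set, feature_fun)
  n_ch <- length(labels0)
  n_bd <- length(bands)
  n_ft <- length(feature_set)
  desc <- data.frame(
    feature = rep(feature_set, times = n_ch * n_bd),
    channel = rep(labels0, each = n_bd * n_ft),
    channel_index = rep(seq_len(n_ch), each = n_bd * n_ft),
    band = rep(rep(vapply(bands, `[[`, "", "name"), each = n_ft),
               times = n_ch),
    band_range = rep(rep(vapply(bands, function(b)
      sprintf("%g-%g Hz", b$low, b$high), ""), each = n_ft), times = n_ch),
    stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow = length(blocks), ncol = nrow(desc))
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    if (repair) blk <- repair_block(blk)
    sigs <- decompose(blk, bands)
    col <- 0L
    for (s in sigs$signals) {
      # spectral features share one PSD estimate per signal
      spec <- if (any(feature_set %in% spectral)) {
        tryCatch(estimate_psd(s, fs), error = function(e) NULL)
      }
      for (fi in seq_along(funs)) {
        col <- col + 1L
        vals[i, col] <- tryCatch({
          if (feature_set[fi] == "peak_freq" && !is.null(spec)) {
            as.numeric(peak_frequency(spec))
          } else if (feature_set[fi] == "median_freq" && !is.null(spec)) {
            median_frequency(spec)
          } else {
            funs[[fi]](s, fs)
          }
        }, error = function(e) NA_real_)
      }
    }
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    for (j in unique(which(bad, arr.ind = TRUE)[, 2L])) {
      fin <- is.finite(vals[, j])
      vals[!fin, j] <- if (any(fin)) mean(vals[fin, j]) else 0
    }
    message(sum(bad), " degenerate feature value(s) imputed by column means")
  }
  colnames(vals) <- descriptor_names(desc)
  feature_matrix(vals, desc,
                 vapply(blocks, `[[`, "", "label"))
}
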