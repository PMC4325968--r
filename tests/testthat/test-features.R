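test_that("PSD estimate is Parseval-consistent with a correct peak", {
  fs <- 256
  tm <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * tm)
  sp <- estimate_psd(x, fs)
  res <- sp$frequencies[2L] - sp$frequencies[1L]
  expect_lte(abs(as.numeric(peak_frequency(sp)) - 10), res)
  expect_equal(sum(sp$power), var(x), tolerance = 0.05)
  set.seed(5)
  w <- rnorm(15360)
  spw <- estimate_psd(w, fs)
  expect_lt(max(spw$power) / median(spw$power), 10)
  expect_equal(sum(spw$power), var(w), tolerance = 0.05)
})

test_that("peak frequency picks the strongest tone, low tie, degenerate 0", {
  fs <- 128
  tm <- (0:(40 * fs - 1)) / fs
  two <- 2 * sin(2 * pi * 5 * tm) + sin(2 * pi * 20 * tm)
  sp <- estimate_psd(two, fs)
  res <- sp$frequencies[2L] - sp$frequencies[1L]
  expect_lte(abs(as.numeric(peak_frequency(sp)) - 5), res)
  flat <- structure(list(frequencies = 0:10, power = rep(1, 11),
                         fs = 20, n = 100), class = "eeg_spectrum")
  expect_equal(as.numeric(peak_frequency(flat)), 0)  # tie -> lowest frequency
  zero <- structure(list(frequencies = 0:10, power = rep(0, 11),
                         fs = 20, n = 100), class = "eeg_spectrum")
  pf <- peak_frequency(zero)
  expect_equal(as.numeric(pf), 0)
  expect_true(attr(pf, "degenerate"))
})

test_that("median frequency follows the cumulative-half rule", {
  fs <- 128
  tm <- (0:(40 * fs - 1)) / fs
  sp1 <- estimate_psd(sin(2 * pi * 12 * tm), fs)
  res <- sp1$frequencies[2L] - sp1$frequencies[1L]
  expect_lte(abs(median_frequency(sp1) - 12), res)
  two <- sin(2 * pi * 5 * tm) + sin(2 * pi * 15 * tm)
  mf <- median_frequency(estimate_psd(two, fs))
  expect_gte(mf, 5); expect_lte(mf, 15)
  # flat synthetic spectrum over (0, 128]: cumulative half sits near 64
  flat <- structure(list(frequencies = seq(0.5, 128, by = 0.5),
                         power = rep(1, 256), fs = 256, n = 512),
                    class = "eeg_spectrum")
  expect_equal(median_frequency(flat), 64, tolerance = 0.01)
  zero <- structure(list(frequencies = 0:3, power = rep(0, 4), fs = 8,
                         n = 8), class = "eeg_spectrum")
  expect_error(median_frequency(zero), "degenerate")
})

test_that("time-domain features match closed forms and brute force", {
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2.5, 7)), 2.5)
  tm <- (0:999) / 100
  expect_equal(rms(3 * sin(2 * pi * 5 * tm)), 3 / sqrt(2), tolerance = 1e-3)
  expect_equal(energy(c(1, 2, 2)), 9)
  expect_equal(energy(rep(0, 5)), 0)
  x <- rnorm(50)
  expect_equal(energy(3 * x), 9 * energy(x))
  expect_equal(signal_variance(1:5), 2.5)
  expect_equal(signal_variance(rep(4, 9)), 0)
  expect_error(signal_variance(1), "2 samples")
  set.seed(10)
  for (i in 1:5) {
    y <- rnorm(200, sd = runif(1, 0.5, 3))
    expect_equal(rms(y), bf_rms(y), tolerance = 1e-9)
    expect_equal(energy(y), bf_energy(y), tolerance = 1e-9)
    expect_equal(signal_variance(y), bf_variance(y), tolerance = 1e-9)
    expect_equal(skewness(y), bf_skewness(y), tolerance = 1e-9)
    expect_equal(kurtosis(y), bf_kurtosis(y), tolerance = 1e-9)
    expect_equal(signal_entropy(y), bf_entropy(y), tolerance = 1e-9)
    # rms^2 * N = energy, always
    expect_equal(rms(y)^2 * length(y), energy(y), tolerance = 1e-9)
  }
})

test_that("skewness and kurtosis match known distributions and symmetries", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  set.seed(2)
  e <- rexp(1e5)
  expect_equal(skewness(e), 2, tolerance = 0.1)
  expect_equal(skewness(-e), -skewness(e))
  g <- rnorm(1e5)
  expect_equal(kurtosis(g), 3, tolerance = 0.1)
  expect_equal(kurtosis(5 * g - 2), kurtosis(g), tolerance = 1e-9)
  expect_equal(kurtosis(c(-1, 1, -1, 1)), 1)
  expect_error(skewness(rep(1, 10)), "degenerate")
  expect_error(kurtosis(rep(1, 10)), "degenerate")
})

test_that("signal entropy spans [0, log N] with the right extremes", {
  expect_equal(signal_entropy(c(0, 0, 5, 0)), 0)
  expect_equal(signal_entropy(rep(2, 64)), log(64))
  set.seed(3)
  for (i in 1:10) {
    y <- rnorm(100)
    h <- signal_entropy(y)
    expect_gte(h, 0)
    expect_lte(h, log(100) + 1e-12)
  }
  expect_error(signal_entropy(rep(0, 4)), "degenerate")
  # literal printed sum, for audit: direct loop
  y <- c(0.5, -1.2, 0, 2)
  expect_equal(signal_entropy_literal(y),
               0.5 * log(0.25) - 1.2 * log(1.44) + 2 * log(4))
})

test_that("correlation dimension recovers line and plane dimensionality", {
  set.seed(8)
  # points on a line: embed a linear ramp; slope ~ 1
  x <- seq(0, 1, length.out = 400)
  radii <- exp(seq(log(0.05), log(0.4), length.out = 6))
  slope <- correlation_dimension(x, radii = radii, embed_dim = 1L,
                                 delay = 1L, max_points = 150L)
  expect_equal(slope, 1, tolerance = 0.2)
  # brute-force pair counting on the same subsampled points agrees
  idx <- unique(round(seq(1, length(x), length.out = 150)))
  expect_equal(slope, bf_corr_dim_slope(x[idx], radii), tolerance = 1e-9)
  # uniform square in a 2-D embedding: interleave coordinates so that the
  # delay-1 pairs (x_i, x_{i+1}) fill the unit square
  pts <- matrix(runif(2 * 300), ncol = 2)
  sq <- as.vector(t(pts))
  radii2 <- exp(seq(log(0.1), log(0.5), length.out = 6))
  slope2 <- correlation_dimension(sq, radii = radii2, embed_dim = 2L,
                                  delay = 1L, max_points = 250L)
  expect_equal(slope2, 2, tolerance = 0.3)
  expect_error(correlation_dimension(rnorm(10), embed_dim = 5L, delay = 4L),
               "too few")
  expect_error(correlation_dimension(rep(1, 100)), "identical")
})

test_that("feature matrix has the full 805-column deterministic layout", {
  blk <- small_block(seed = 12L, n_channels = 23L)
  fm <- build_feature_matrix(list(blk))
  expect_equal(ncol(fm$values), 805L)
  expect_equal(nrow(fm$values), 1L)
  expect_false(any(!is.finite(fm$values)))
  expect_equal(colnames(fm$values)[1L], "RMS CH1 0.5-30 Hz")
  # channel-major, band-minor, feature-innermost
  expect_equal(fm$descriptors$channel[1:35],
               rep(blk$channel_labels[1L], 35L))
  expect_equal(unique(fm$descriptors$band[1:35]),
               c("broadband", "delta", "theta", "alpha", "beta"))
  fm2 <- build_feature_matrix(list(blk))
  expect_identical(colnames(fm$values), colnames(fm2$values))
  expect_identical(fm$values, fm2$values)
  # single channel, single band, single feature -> one column
  one <- build_feature_matrix(list(small_block(seed = 12L, n_channels = 1L)),
                              feature_set = "rms",
                              bands = band_specs()["broadband"])
  expect_equal(dim(one$values), c(1L, 1L))
})

test_that("degenerate feature values are imputed by column means", {
  b1 <- small_block(seed = 13L)
  b2 <- small_block(seed = 14L)
  b3 <- b1
  b3$data[1L, ] <- 0   # all-zero channel: entropy/skewness degenerate
  expect_message(
    fm <- build_feature_matrix(list(b1, b2, b3), repair = FALSE),
    "imputed")
  expect_false(any(!is.finite(fm$values)))
  j <- which(fm$descriptors$feature == "skewness" &
               fm$descriptors$channel == b1$channel_labels[1L] &
               fm$descriptors$band == "broadband")
  expect_equal(unname(fm$values[3L, j]), mean(fm$values[1:2, j]))
})
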