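# Small fixtures built in code. Module tests mostly use short blocks with few
# channels to stay fast; full-size 23-channel/60-s objects appear only where
# the property under test concerns the full dimensionality.

small_params <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_channels = 4L, fs = 64, block_duration = 4,
                   missing_run_rate = 0, seed = seed)
  defaults[names(args)] <- args
  do.call(gen_params, defaults)
}

small_block <- function(seed = 1L, label = "nonseizure", ...) {
  p <- small_params(seed, ...)
  rec <- generate_record(p, is_seizure = label == "seizure")
  segment_block(rec$data, rec$fs, rec$channel_labels, label = label)
}

# a feature matrix of plain Gaussian features (no EEG pipeline involved)
gaussian_fm <- function(n_per_class, p, effect = 0, informative = integer(0),
                        seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("nonseizure", "seizure"), each = n_per_class)
  for (j in informative) X[y == "seizure", j] <- X[y == "seizure", j] + effect
  desc <- data.frame(feature = sprintf("f%d", seq_len(p)),
                     channel = sprintf("CH%d", seq_len(p)),
                     band = "broadband")
  colnames(X) <- sprintf("f%d CH%d broadband", seq_len(p), seq_len(p))
  feature_matrix(X, desc, y)
}

# two well-separated spherical Gaussian clouds in d dimensions
separated_fm <- function(n_per_class = 200L, d = 2L, dist = 10, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = dist / sqrt(d)), ncol = d))
  desc <- data.frame(feature = sprintf("f%d", seq_len(d)),
                     channel = sprintf("CH%d", seq_len(d)),
                     band = "broadband")
  feature_matrix(X, desc,
                 rep(c("nonseizure", "seizure"), each = n_per_class))
}
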