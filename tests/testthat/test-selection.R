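test_that("the default region map mirrors the five-region channel grouping", {
  expect_message(rm_ <- region_map_default(), "substitutions")
  expect_equal(rm_$region_ids, 1:5)
  expect_equal(lengths(rm_$channels), c(`1` = 5L, `2` = 5L, `3` = 4L,
                                        `4` = 4L, `5` = 3L))
  # FZ-CZ belongs to region 5 and no other
  hits <- vapply(rm_$channels, function(ch) "FZ-CZ" %in% ch, TRUE)
  expect_identical(which(hits), c(`5` = 5L))
  expect_setequal(rm_$channels[["5"]], c("FZ-CZ", "CZ-PZ", "FT9-FT10"))
  # 21 of the 23 montage channels are mapped
  expect_length(intersect(unlist(rm_$channels), default_montage()), 21L)
  expect_setequal(setdiff(default_montage(), unlist(rm_$channels)),
                  c("P7-T7", "T8-P8-2"))
  # the shipped text table parses to the same map
  path <- system.file("extdata", "region_map.tsv", package = "seizepipe")
  expect_equal(read_region_map(path)$channels, rm_$channels)
  expect_error(region_map(data.frame(region = c(1, 2),
                                     channel = c("A", "A"))),
               "two regions")
})

test_that("every ranking is a valid deterministic permutation", {
  fm <- gaussian_fm(15L, 12L, effect = 1.5, informative = c(3L, 7L),
                    seed = 21L)
  for (m in ranking_methods()) {
    rk <- rank_features(fm, m)
    expect_identical(sort(rk$order), seq_len(12L))
    expect_true(all(is.finite(rk$score)))
    rk2 <- rank_features(fm, m)
    expect_identical(rk$order, rk2$order)
  }
  expect_error(rank_features(fm_subset(fm, rows = 1:15), "p_value"),
               "both classes")
})

test_that("a planted near-label column is ranked first by every method", {
  # col 1 = class effect + small noise; others pure noise at matched scale
  set.seed(31)
  n <- 100L
  y <- rep(c("nonseizure", "seizure"), each = n / 2)
  X <- matrix(rnorm(n * 10, sd = 0.25), n, 10L)
  X[, 1L] <- ifelse(y == "seizure", 1, 0) + rnorm(n, sd = 0.05)
  fm <- feature_matrix(X, data.frame(feature = sprintf("f%d", 1:10),
                                     channel = sprintf("CH%d", 1:10),
                                     band = "broadband"), y)
  for (m in setdiff(ranking_methods(), "pca_pc2")) {
    expect_equal(rank_features(fm, m)$order[1L], 1L,
                 label = sprintf("method %s top pick", m))
  }
})

test_that("p-value ranking equals per-column two-sample test order", {
  fm <- gaussian_fm(20L, 8L, effect = 1, informative = c(2L, 5L), seed = 41L)
  p_oracle <- vapply(seq_len(8L), function(j) {
    stats::t.test(fm$values[fm$labels == "seizure", j],
                  fm$values[fm$labels == "nonseizure", j])$p.value
  }, 0)
  rk <- rank_features(fm, "p_value")
  expect_equal(rk$score, p_oracle, tolerance = 1e-12)
  expect_identical(rk$order, order(p_oracle))
  # q-values are the BH adjustment of the same p-values
  rkq <- rank_features(fm, "q_value")
  expect_equal(rkq$score, p.adjust(p_oracle, "BH"), tolerance = 1e-12)
})

test_that("backward search drops one of two identical informative columns", {
  set.seed(51)
  n <- 80L
  y <- rep(c("nonseizure", "seizure"), each = n / 2)
  info <- ifelse(y == "seizure", 2, 0) + rnorm(n, sd = 0.3)
  X <- cbind(info, info, matrix(rnorm(n * 6), n, 6L))
  fm <- feature_matrix(X, data.frame(feature = sprintf("f%d", 1:8),
                                     channel = sprintf("CH%d", 1:8),
                                     band = "broadband"), y)
  pv <- rank_features(fm, "p_value")
  expect_setequal(pv$order[1:2], c(1L, 2L))   # marginal test keeps both
  bk <- rank_features(fm, "lda_backward")
  expect_false(all(c(1L, 2L) %in% bk$order[1:2]))  # redundancy removed
  expect_true(any(c(1L, 2L) == bk$order[1L]))
})

test_that("constant columns are pushed to the worst ranks with a warning", {
  fm <- gaussian_fm(10L, 5L, effect = 2, informative = 1L, seed = 61L)
  fm$values[, 4L] <- 3.14
  for (m in c("p_value", "pca_pc1", "lda_independent", "lda_backward")) {
    expect_warning(rk <- rank_features(fm, m), "constant")
    expect_equal(rk$order[5L], 4L)
  }
})

test_that("select_top_uncorrelated enforces the pairwise correlation cap", {
  set.seed(71)
  n <- 60L
  y <- rep(c("nonseizure", "seizure"), each = n / 2)
  x1 <- rnorm(n) + (y == "seizure")
  X <- cbind(x1, x1, rnorm(n))
  fm <- feature_matrix(X, data.frame(feature = sprintf("f%d", 1:3),
                                     channel = sprintf("CH%d", 1:3),
                                     band = "broadband"), y)
  rk <- rank_features(fm, "p_value")
  expect_setequal(select_top_uncorrelated(rk, fm, k = 2L, max_abs_corr = 0.9),
                  c(1L, 3L))
  # threshold 1 disables the filter
  expect_identical(select_top_uncorrelated(rk, fm, k = 2L, max_abs_corr = 1),
                   rk$order[1:2])
  # impossible request warns and returns the survivors
  expect_warning(kept <- select_top_uncorrelated(rk, fm, k = 3L,
                                                 max_abs_corr = 0.9),
                 "survive")
  expect_length(kept, 2L)
  # selected sets always satisfy the cap
  fm2 <- gaussian_fm(40L, 30L, effect = 1, informative = 1:5, seed = 72L)
  kept2 <- select_top_uncorrelated(rank_features(fm2, "p_value"), fm2,
                                   k = 10L, max_abs_corr = 0.6)
  cm <- abs(cor(fm2$values[, kept2]))
  expect_lte(max(cm[upper.tri(cm)]), 0.6)
})

test_that("region-wise selection takes five per region from its channels", {
  blocks <- c(lapply(1:6, function(i)
                small_block(seed = 100L + i, n_channels = 23L,
                            label = "seizure")),
              lapply(1:6, function(i)
                small_block(seed = 200L + i, n_channels = 23L)))
  fm <- build_feature_matrix(blocks)
  sel <- suppressWarnings(select_region_top(fm))
  expect_length(sel, 25L)
  rm_ <- region_map_default(quiet = TRUE)
  by_region <- attr(sel, "regions")
  for (id in names(by_region)) {
    expect_length(by_region[[id]], 5L)
    expect_true(all(fm$descriptors$channel[by_region[[id]]] %in%
                      rm_$channels[[id]]))
  }
})

test_that("per-region planted features are recovered at quota one", {
  rm_ <- region_map_default(quiet = TRUE)
  set.seed(91)
  n <- 60L
  y <- rep(c("nonseizure", "seizure"), each = n / 2)
  channels <- unlist(rm_$channels)
  planted_ch <- vapply(rm_$channels, `[`, "", 1L)  # one channel per region
  X <- matrix(rnorm(n * length(channels)), n, length(channels))
  for (ch in planted_ch) {
    j <- match(ch, channels)
    X[, j] <- X[, j] + 3 * (y == "seizure")
  }
  fm <- feature_matrix(X, data.frame(feature = "rms", channel = channels,
                                     band = "broadband"), y)
  sel <- select_region_top(fm, rm_, per_region = 1L)
  expect_setequal(fm$descriptors$channel[sel], unname(planted_ch))
})
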