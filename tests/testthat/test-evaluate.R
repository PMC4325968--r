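test_that("confusion metrics match arithmetic and pair counting", {
  truth <- c(rep("seizure", 100L), rep("nonseizure", 100L))
  pred <- c(rep("seizure", 84L), rep("nonseizure", 16L),
            rep("nonseizure", 85L), rep("seizure", 15L))
  cm <- confusion_metrics(truth, pred)
  expect_equal(cm[["sensitivity"]], 0.84)
  expect_equal(cm[["specificity"]], 0.85)
  expect_equal(cm[["error"]], 31 / 200)
  expect_equal(confusion_metrics(truth, truth),
               c(sensitivity = 1, specificity = 1, error = 0))
  set.seed(1)
  for (i in 1:10) {
    t_ <- sample(c("seizure", "nonseizure"), 50L, replace = TRUE)
    # ensure both classes occur
    t_[1:2] <- c("seizure", "nonseizure")
    p_ <- sample(c("seizure", "nonseizure"), 50L, replace = TRUE)
    expect_equal(confusion_metrics(t_, p_), bf_confusion(t_, p_))
    # exact consistency: error = 1 - (TP + TN) / total
    cm_ <- confusion_metrics(t_, p_)
    n1 <- sum(t_ == "seizure"); n0 <- 50L - n1
    expect_equal(cm_[["error"]],
                 1 - (cm_[["sensitivity"]] * n1 + cm_[["specificity"]] * n0) /
                   50)
  }
  expect_error(confusion_metrics(character(0), character(0)), "contract")
})

test_that("majority-class baseline error is exactly 50% when balanced", {
  expect_equal(base_rate_error(rep(c("seizure", "nonseizure"), 171L)), 0.5)
  expect_equal(base_rate_error(c(rep("a", 3L), "b")), 0.25)
})

test_that("AUC matches the rank-sum oracle and handles extremes and ties", {
  truth <- rep(c("seizure", "nonseizure"), each = 5L)
  expect_equal(roc_auc(truth, c(6:10, 1:5)), 1)
  expect_equal(roc_auc(truth, c(1:5, 6:10)), 0)
  set.seed(2)
  for (i in 1:10) {
    t_ <- sample(rep(c("seizure", "nonseizure"), times = c(12L, 18L)))
    s_ <- sample(1:8, 30L, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(t_, s_), bf_auc(t_, s_), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep("seizure", 5L), 1:5), "contract")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  t_ <- sample(rep(c("seizure", "nonseizure"), 20L))
  s_ <- rnorm(40L)
  a0 <- roc_auc(t_, s_)
  expect_equal(roc_auc(t_, exp(s_)), a0)
  expect_equal(roc_auc(t_, 100 * s_ - 3), a0)
  expect_equal(roc_auc(t_, plogis(s_)), a0)
})

test_that("ROC points trace a valid curve from (0,0) to (1,1)", {
  set.seed(4)
  t_ <- sample(rep(c("seizure", "nonseizure"), 15L))
  s_ <- rnorm(30L)
  rp <- roc_points(t_, s_)
  expect_equal(rp$fpr[1L], 0); expect_equal(rp$tpr[1L], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0))
  expect_true(all(diff(rp$tpr) >= 0))
  # trapezoidal area under the points equals the rank-sum AUC
  area <- sum(diff(rp$fpr) * (head(rp$tpr, -1L) + tail(rp$tpr, -1L)) / 2)
  expect_equal(area, roc_auc(t_, s_), tolerance = 1e-12)
})

test_that("holdout evaluation splits 342 as 274/68 and is seed-stable", {
  fm <- gaussian_fm(171L, 4L, effect = 1.2, informative = 1:2, seed = 5L)
  # the split sizes: ceil(0.8 * 171) = 137 per class
  seen <- local({
    y <- fm$labels
    set.seed(6)
    idx <- seizepipe:::stratified_split(y, 0.8)
    c(train = length(idx), test = nrow(fm$values) - length(idx))
  })
  expect_equal(unname(seen), c(274L, 68L))
  r1 <- holdout_evaluate(fm, classifier_spec("LDC"), reps = 5L, seed = 7L)
  r2 <- holdout_evaluate(fm, classifier_spec("LDC"), reps = 5L, seed = 7L)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_s3_class(r1, "evaluation_report")
  expect_true(all(unlist(r1[, c("sensitivity", "specificity", "auc",
                                "mean_error")]) >= 0))
  expect_true(all(unlist(r1[, c("sensitivity", "specificity", "auc",
                                "mean_error")]) <= 1))
  expect_error(holdout_evaluate(fm_subset(fm, rows = c(1, 172)),
                                classifier_spec("LDC"), reps = 2L),
               "contract")
})

test_that("k-fold testing partitions every observation exactly once", {
  fm <- gaussian_fm(171L, 3L, effect = 1, informative = 1L, seed = 8L)
  y <- fm$labels
  set.seed(9)
  fid <- seizepipe:::stratified_fold_ids(y, 5L)
  expect_setequal(unique(fid), 1:5)
  expect_true(all(table(fid) %in% c(68L, 69L)))   # 5-fold on 342
  for (f in 1:5) {
    expect_true(all(table(y[fid == f]) >= 34L))   # stratified
  }
  rep_ <- kfold_evaluate(fm, classifier_spec("LDC"), folds = 5L, reps = 2L,
                         seed = 10L)
  expect_equal(rep_$scheme, "cv5_2")
  expect_lte(rep_$mean_error, 0.5)
  expect_error(kfold_evaluate(fm_subset(fm, rows = c(1:3, 172:174)),
                              classifier_spec("LDC"), folds = 5L),
               "contract")
})

test_that("repetition averaging shrinks the error SD", {
  fm <- gaussian_fm(40L, 3L, effect = 1, informative = 1L, seed = 11L)
  one <- kfold_evaluate(fm, classifier_spec("LDC"), folds = 5L, reps = 1L,
                        seed = 12L)
  many <- kfold_evaluate(fm, classifier_spec("LDC"), folds = 5L, reps = 20L,
                         seed = 12L)
  # SD over repetition means < SD of single-repetition fold errors
  expect_lt(many$sd_error, one$sd_error)
})

test_that("train-only SMOTE inside splits keeps the test set untouched", {
  fm <- gaussian_fm(30L, 3L, effect = 2, informative = 1L, seed = 13L)
  rep_ <- holdout_evaluate(fm, classifier_spec("LDC"), reps = 3L, seed = 14L,
                           smote = smote_params(seed = 15L))
  # reported observation count is the input matrix's, not the oversampled one
  expect_equal(rep_$n_observations, 60L)
  expect_s3_class(rep_, "evaluation_report")
})

test_that("run_experiment emits the full 2x2x9 grid of report rows", {
  # small synthetic problem end to end; reduced repetitions for speed
  cfg <- pipeline_config(n_seizure = 12L, n_nonseizure = 12L,
                         generator = list(n_channels = 23L,
                                          block_duration = 4L, fs = 64),
                         evaluation = list(holdout_reps = 2L))
  res <- suppressWarnings(run_experiment(cfg, seed = 16L))
  expect_setequal(names(res$reports),
                  c("top20", "region", "top20_smote", "region_smote"))
  all_rows <- do.call(rbind, lapply(res$reports, as.data.frame))
  expect_equal(nrow(all_rows), 36L)
  expect_setequal(unique(all_rows$classifier), classifier_kinds())
  # SMOTE arms report doubled observation counts
  expect_equal(unique(all_rows$n_observations[grepl("smote", all_rows$arm)]),
               48L)
  expect_equal(unique(all_rows$n_observations[!grepl("smote", all_rows$arm)]),
               24L)
  # region arm uses exactly 25 feature columns
  expect_length(res$selected$region, 25L)
  expect_length(res$selected$top20, 20L)
  # ROC data covers every arm and classifier
  expect_setequal(unique(res$roc$arm), names(res$reports))
  expect_setequal(unique(res$roc$classifier), classifier_kinds())
})

test_that("stronger class separation never lowers the median AUC", {
  # protocol monotonicity on synthetic data: three ictal gain levels x
  # 20 seeds, reduced block size, delta-band RMS features, LDC holdout AUC
  gains <- c(0.8, 1.6, 3.2)
  med_auc <- vapply(gains, function(g) {
    aucs <- vapply(1:20, function(s) {
      p <- small_params(seed = 5000L + s, n_channels = 8L,
                        seizure_amplitude_gain = g)
      blocks <- generate_dataset(p, 8L, 8L)
      fm <- build_feature_matrix(blocks, feature_set = "rms",
                                 bands = band_specs()["delta"])
      rep_ <- holdout_evaluate(fm, classifier_spec("LDC"), reps = 4L,
                               seed = 6000L + s)
      rep_$auc
    }, 0)
    median(aucs)
  }, 0)
  expect_true(all(diff(med_auc) >= 0))
})

test_that("YAML configuration merges onto the defaults", {
  path <- system.file("extdata", "example_config.yaml",
                      package = "seizepipe")
  cfg <- read_pipeline_config(path)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$n_seizure, 171L)
  expect_equal(cfg$smote$mode, "pre_split")
  expect_equal(cfg$evaluation$holdout_reps, 100L)
  # unspecified keys keep their defaults
  expect_equal(cfg$feature_set, seizepipe:::default_feature_set())
  expect_equal(cfg$classifiers, classifier_kinds())
  # programmatic overrides nest the same way
  cfg2 <- pipeline_config(evaluation = list(holdout_reps = 7L))
  expect_equal(cfg2$evaluation$holdout_reps, 7L)
  expect_equal(cfg2$evaluation$train_frac, 0.8)
})

test_that("reports and ROC points are written to disk on request", {
  cfg <- pipeline_config(n_seizure = 8L, n_nonseizure = 8L,
                         generator = list(n_channels = 23L,
                                          block_duration = 4L, fs = 64),
                         classifiers = c("LDC", "KNNC"),
                         evaluation = list(holdout_reps = 2L))
  out <- withr::local_tempdir()
  res <- suppressWarnings(run_experiment(cfg, seed = 17L, out_dir = out))
  expect_true(file.exists(file.path(out, "reports.csv")))
  expect_true(file.exists(file.path(out, "reports.json")))
  expect_true(file.exists(file.path(out, "roc_points.csv")))
  back <- read.csv(file.path(out, "reports.csv"))
  expect_equal(nrow(back), 8L)
})
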