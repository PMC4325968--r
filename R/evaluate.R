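#' Confusion metrics
#'
#' Sensitivity (true-positive rate on the seizure class), specificity
#' (true-negative rate on the nonseizure class) and global error
#' `(FP + FN) / total` from two label vectors.
#'
#' @param truth,predicted factors/characters of `"seizure"`/`"nonseizure"`,
#'   same length, non-empty.
#' @return Named numeric vector `sensitivity`, `specificity`, `error`.
#' @export
confusion_metrics <- function(truth, predicted) {
  if (!length(truth) || length(truth) != length(predicted)) {
    stop("contract error: label vectors must be non-empty and equal length",
         call. = FALSE)
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  tp <- sum(truth == "seizure" & predicted == "seizure")
  fn <- sum(truth == "seizure" & predicted != "seizure")
  tn <- sum(truth != "seizure" & predicted != "seizure")
  fp <- sum(truth != "seizure" & predicted == "seizure")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    error = (fp + fn) / length(truth))
}

#' Base-rate (majority-class) error
#'
#' The error of always predicting the most frequent class: `1 - max class
#' frequency`. On a balanced dataset this is exactly 50%, the bound every
#' useful classifier must beat.
#'
#' @param labels class labels.
#' @return A fraction in `[0, 0.5]`.
#' @export
base_rate_error <- function(labels) {
  if (!length(labels)) stop("contract error: empty labels", call. = FALSE)
  1 - max(table(labels)) / length(labels)
}

#' Area under the ROC curve
#'
#' AUC over all score thresholds, computed as the normalised Mann-Whitney
#' statistic with the midrank convention, which equals trapezoidal
#' integration of the ROC curve in the presence of ties. Invariant under
#' strictly monotone transforms of the scores.
#'
#' @param truth labels containing both classes.
#' @param scores numeric scores, higher = more seizure-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, scores) {
  pos <- as.character(truth) == "seizure"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L || length(truth) != length(scores)) {
    stop("contract error: both classes and matching scores are required",
         call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs over all distinct score thresholds, suitable for
#' plotting; thresholds sweep from +Inf (0, 0) to -Inf (1, 1).
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(truth, scores) {
  pos <- as.character(truth) == "seizure"
  o <- order(scores, decreasing = TRUE)
  thr <- c(Inf, unique(scores[o]))
  tpr <- c(0, cumsum(pos[o])[!duplicated(scores[o], fromLast = TRUE)] /
             sum(pos))
  fpr <- c(0, cumsum(!pos[o])[!duplicated(scores[o], fromLast = TRUE)] /
             sum(!pos))
  data.frame(fpr = fpr, tpr = tpr, threshold = thr)
}

new_report <- function(rows, scheme, n_repetitions) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$scheme <- scheme
  df$n_repetitions <- n_repetitions
  structure(df, class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> scheme %s (%d repetitions)\n",
              x$scheme[1L], x$n_repetitions[1L]))
  print.data.frame(cbind(x[, c("classifier", "n_observations")],
                         round(x[, c("sensitivity", "specificity", "auc",
                                     "mean_error", "sd_error")], 4L)),
                   row.names = FALSE)
  invisible(x)
}

stratified_split <- function(y, train_frac) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- ceiling(train_frac * length(idx))
    if (n_tr >= length(idx) || n_tr < 1L) {
      stop("contract error: class too small to stratify", call. = FALSE)
    }
    train <- c(train, idx[sample_int(length(idx), n_tr)])
  }
  sort(train)
}

stratified_fold_ids <- function(y, folds) {
  if (min(table(y)) < folds) {
    stop("contract error: folds exceed class size", call. = FALSE)
  }
  f <- integer(length(y))
  load <- integer(folds)   # spread per-class remainders across folds
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_cl <- length(idx)
    base <- rep(seq_len(folds), n_cl %/% folds)
    rem <- n_cl %% folds
    if (rem > 0L) base <- c(base, order(load)[seq_len(rem)])
    f[idx] <- sample(base)
    load <- load + tabulate(base, folds)
  }
  f
}

eval_one_split <- function(matrix, spec, train_idx, smote = NULL) {
  train <- fm_subset(matrix, rows = train_idx)
  test <- fm_subset(matrix, rows = setdiff(seq_len(nrow(matrix$values)),
                                           train_idx))
  if (!is.null(smote)) train <- smote_oversample(train, smote)
  model <- fit_classifier(spec, train)
  sc <- score(model, test)
  cm <- confusion_metrics(test$labels, sc$label)
  list(metrics = cm, auc = roc_auc(test$labels, sc$score),
       truth = test$labels, scores = sc$score)
}

#' Repeated stratified holdout evaluation
#'
#' Repeats `reps` stratified random train/test splits (training fraction
#' `train_frac`, sizes rounded up per class), fits the classifier on each
#' training portion and scores the held-out remainder; reports the mean
#' sensitivity, specificity and AUC at the default label threshold, the mean
#' global error and its standard deviation over repetitions. When `smote` is
#' supplied, oversampling is applied to the training portion of each split
#' only (no leakage into the test set); to emulate oversampling of the whole
#' dataset before splitting, apply [smote_oversample()] first.
#'
#' @param matrix a [feature_matrix] with at least ~10 observations per
#'   class.
#' @param spec a [classifier_spec()].
#' @param train_frac training fraction (default 0.8).
#' @param reps number of random splits (default 100).
#' @param seed integer seed fixing the splits (and fit-internal folds).
#' @param smote optional [smote_params()] applied to training portions.
#' @return An `evaluation_report` (one row).
#' @export
holdout_evaluate <- function(matrix, spec, train_frac = 0.8, reps = 100L,
                             seed = NULL, smote = NULL) {
  y <- matrix$labels
  with_local_seed(seed, {
    res <- lapply(seq_len(reps), function(r) {
      idx <- stratified_split(y, train_frac)
      sp <- spec
      if (!is.null(spec$seed)) sp$seed <- spec$seed + r
      eval_one_split(matrix, sp, idx, smote)
    })
    summarise_reps(res, spec$kind, nrow(matrix$values),
                   scheme = sprintf("holdout_%d", reps), reps)
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Stratified `folds`-fold cross-validation, repeated `reps` times with
#' re-randomised folds; within one repetition every observation is tested
#' exactly once. Mean error is averaged over all folds (and repetitions);
#' the standard deviation is over repetitions (over folds when `reps = 1`).
#'
#' @inheritParams holdout_evaluate
#' @param folds number of folds (default 5).
#' @param reps repetitions (1 or 100 in the reference protocol).
#' @return An `evaluation_report` (one row).
#' @export
kfold_evaluate <- function(matrix, spec, folds = 5L, reps = 1L, seed = NULL,
                           smote = NULL) {
  y <- matrix$labels
  n <- nrow(matrix$values)
  with_local_seed(seed, {
    rep_res <- lapply(seq_len(reps), function(r) {
      fid <- stratified_fold_ids(y, folds)
      fold_res <- lapply(seq_len(folds), function(f) {
        sp <- spec
        if (!is.null(spec$seed)) sp$seed <- spec$seed + r * folds + f
        eval_one_split(matrix, sp, which(fid != f), smote)
      })
      # aggregate the folds of one repetition
      list(metrics = rowMeans(vapply(fold_res, `[[`, numeric(3L), "metrics")),
           auc = mean(vapply(fold_res, `[[`, 0, "auc")),
           errors = vapply(fold_res, function(x) x$metrics[["error"]], 0))
    })
    err_per_rep <- vapply(rep_res, function(x) mean(x$errors), 0)
    sd_err <- if (reps > 1L) stats::sd(err_per_rep) else
      stats::sd(rep_res[[1L]]$errors)
    m <- rowMeans(vapply(rep_res, `[[`, numeric(3L), "metrics"))
    new_report(list(data.frame(
      classifier = spec$kind, n_observations = n,
      sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
      auc = mean(vapply(rep_res, `[[`, 0, "auc")),
      mean_error = mean(err_per_rep), sd_error = sd_err)),
      scheme = sprintf("cv%d_%d", folds, reps), reps)
  })
}

summarise_reps <- function(res, kind, n, scheme, reps) {
  M <- vapply(res, `[[`, numeric(3L), "metrics")
  aucs <- vapply(res, `[[`, 0, "auc")
  errs <- M["error", ]
  new_report(list(data.frame(
    classifier = kind, n_observations = n,
    sensitivity = mean(M["sensitivity", ]),
    specificity = mean(M["specificity", ]),
    auc = mean(aucs), mean_error = mean(errs),
    sd_error = stats::sd(errs))), scheme, reps)
}

#' Pipeline configuration
#'
#' Default configuration for [run_experiment()]: dataset size, generator
#' parameters, bands, feature set, selection (method, whole-brain `k`,
#' decorrelation threshold, per-region quota), SMOTE parameters and mode
#' (`"pre_split"` oversamples the whole dataset before evaluation, matching
#' the reference protocol's reported 342-to-684 doubling; `"train_only"`
#' confines oversampling to training portions), classifier list, and the
#' evaluation scheme (holdout fraction and repetitions, optional k-fold).
#' `read_pipeline_config()` reads the same structure from a YAML file and
#' fills unspecified entries with these defaults.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_seizure = 171L, n_nonseizure = 171L,
    generator = list(),             # gen_params() overrides
    beta_high = 25,
    feature_set = default_feature_set(),
    selection = list(method = "lda_backward", k = 20L, max_abs_corr = 0.9,
                     per_region = 5L),
    smote = list(k = 5L, amount = 100, mode = "pre_split"),
    classifiers = classifier_kinds(),
    evaluation = list(train_frac = 0.8, holdout_reps = 100L,
                      kfold = FALSE, folds = 5L, kfold_reps = 1L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @param path YAML file.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full 2x2 evaluation grid
#'
#' The end-to-end protocol on synthetic data: generate a labelled dataset,
#' build the whole-brain feature matrix, then evaluate every configured
#' classifier under the four arms {whole-brain top-k decorrelated features,
#' region-wise top-5-per-region features} x {original data, SMOTE
#' oversampled}, using repeated stratified holdout (and optionally k-fold).
#' Returns one report row per (arm, classifier) plus pooled ROC points per
#' arm, and optionally writes reports as CSV/JSON and ROC data as CSV.
#'
#' @param config a [pipeline_config()].
#' @param seed master integer seed for generation, selection and
#'   evaluation.
#' @param out_dir optional directory for `reports.csv`, `reports.json` and
#'   `roc_points.csv`.
#' @param blocks optional pre-generated list of [segment_block]s (bypasses
#'   the generator).
#' @param progress print progress messages.
#' @return List with `reports` (one `evaluation_report` per arm), `roc`
#'   (data.frame of pooled ROC points per arm and classifier), `selected`
#'   (column indices per arm) and `feature_matrix`.
#' @export
run_experiment <- function(config = pipeline_config(), seed = 1L,
                           out_dir = NULL, blocks = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  if (is.null(blocks)) {
    gp <- do.call(gen_params, c(config$generator,
                                list(seed = seed)))
    say("generating %d + %d blocks", config$n_seizure, config$n_nonseizure)
    blocks <- generate_dataset(gp, config$n_seizure, config$n_nonseizure)
  }
  say("building feature matrix")
  fm <- build_feature_matrix(blocks, config$feature_set,
                             band_specs(config$beta_high))
  sel_cfg <- config$selection
  rk <- rank_features(fm, sel_cfg$method)
  top_idx <- select_top_uncorrelated(rk, fm, sel_cfg$k, sel_cfg$max_abs_corr)
  region_idx <- select_region_top(fm, region_map_default(quiet = TRUE),
                                  sel_cfg$method, sel_cfg$per_region)
  arms <- list(
    top20 = fm_subset(fm, cols = top_idx),
    region = fm_subset(fm, cols = as.integer(region_idx)))
  smote_mode <- config$smote$mode
  sp_smote <- smote_params(config$smote$k, config$smote$amount,
                           seed = seed + 7L)
  reports <- list()
  roc <- list()
  ev <- config$evaluation
  arm_defs <- expand.grid(arm = names(arms), smote = c(FALSE, TRUE),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(arm_defs))) {
    arm_name <- arm_defs$arm[i]
    use_smote <- arm_defs$smote[i]
    key <- paste0(arm_name, if (use_smote) "_smote" else "")
    sub <- arms[[arm_name]]
    smote_arg <- NULL
    if (use_smote) {
      if (smote_mode == "pre_split") {
        sub <- smote_oversample(sub, sp_smote)
      } else {
        smote_arg <- sp_smote
      }
    }
    say("evaluating arm %s (%d observations)", key, nrow(sub$values))
    rows <- list()
    roc_rows <- list()
    for (kind in config$classifiers) {
      spec <- classifier_spec(kind, seed = seed + 11L)
      rep_ <- holdout_evaluate(sub, spec, ev$train_frac, ev$holdout_reps,
                               seed = seed + 13L, smote = smote_arg)
      rows[[kind]] <- rep_
      if (isTRUE(ev$kfold)) {
        rows[[paste0(kind, "_cv")]] <-
          kfold_evaluate(sub, spec, ev$folds, ev$kfold_reps,
                         seed = seed + 17L, smote = smote_arg)
      }
      # pooled ROC points from one representative split
      with_local_seed(seed + 19L, {
        idx <- stratified_split(sub$labels, ev$train_frac)
        one <- eval_one_split(sub, spec, idx, smote_arg)
        rp <- roc_points(one$truth, one$scores)
        rp$classifier <- kind
        rp$arm <- key
        roc_rows[[kind]] <- rp
      })
    }
    rep_all <- do.call(rbind, rows)
    rep_all$arm <- key
    reports[[key]] <- rep_all
    roc[[key]] <- do.call(rbind, roc_rows)
  }
  out <- list(reports = reports, roc = do.call(rbind, roc),
              selected = list(top20 = top_idx, region = region_idx),
              feature_matrix = fm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- do.call(rbind, lapply(reports, as.data.frame))
    utils::write.csv(flat, file.path(out_dir, "reports.csv"),
                     row.names = FALSE)
    jsonlite::write_json(flat, file.path(out_dir, "reports.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$roc, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
  }
  out
}
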