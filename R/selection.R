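#' Scalp region map
#'
#' Groups bipolar montage channels into the five scalp regions used for
#' region-wise feature selection (left fronto-temporal, right
#' fronto-temporal, left posterior, right posterior, central/midline). A
#' channel may belong to at most one region; region-map channels missing
#' from a montage are reported at use time rather than failing.
#'
#' `region_map_default()` returns the built-in five-region map. Two label
#' substitutions are applied relative to the published grouping and flagged
#' via the `"substitutions"` attribute: `P7-O7` (not a montage channel,
#' evidently `P7-O1`) and `T8-FT10` (the montage spells the same derivation
#' `FT10-T8`). The map covers 21 of the default montage's 23 channels;
#' `P7-T7` and the disambiguated duplicate `T8-P8-2` are unmapped.
#'
#' @param table data.frame with columns `region` (integer id) and `channel`.
#' @return An object of class `region_map`: named list, one character vector
#'   of channel labels per region id.
#' @export
region_map <- function(table) {
  table <- as.data.frame(table)
  if (!all(c("region", "channel") %in% names(table))) {
    stop("region map table needs columns 'region' and 'channel'",
         call. = FALSE)
  }
  if (anyDuplicated(table$channel)) {
    stop("a channel may not belong to two regions", call. = FALSE)
  }
  ids <- sort(unique(table$region))
  out <- lapply(ids, function(r) table$channel[table$region == r])
  names(out) <- as.character(ids)
  structure(list(region_ids = ids, channels = out), class = "region_map")
}

#' @param quiet suppress the substitution message.
#' @rdname region_map
#' @export
region_map_default <- function(quiet = FALSE) {
  tab <- data.frame(
    region = rep(1:5, c(5L, 5L, 4L, 4L, 3L)),
    channel = c(
      "FP1-F7", "F7-T7", "FP1-F3", "F3-C3", "T7-FT9",
      "FP2-F4", "F4-C4", "FP2-F8", "F8-T8", "FT10-T8",
      "T7-P7", "P7-O1", "C3-P3", "P3-O1",
      "C4-P4", "P4-O2", "T8-P8", "P8-O2",
      "FZ-CZ", "CZ-PZ", "FT9-FT10"),
    stringsAsFactors = FALSE)
  rm_ <- region_map(tab)
  attr(rm_, "substitutions") <- c("P7-O7 -> P7-O1", "T8-FT10 -> FT10-T8")
  if (!quiet) {
    message("region map uses label substitutions: ",
            paste(attr(rm_, "substitutions"), collapse = "; "))
  }
  rm_
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  for (id in names(x$channels)) {
    cat(sprintf("  region %s: %s\n", id,
                paste(x$channels[[id]], collapse = ", ")))
  }
  invisible(x)
}

#' Read a region map from a text table
#'
#' Reads a tab- or comma-separated table with columns `region` and
#' `channel`; the packaged default map is in
#' `system.file("extdata", "region_map.tsv", package = "seizepipe")`.
#'
#' @param path file path.
#' @return A [region_map].
#' @export
read_region_map <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  region_map(utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE))
}

#' The nine supported ranking criteria
#'
#' @return Character vector of method names accepted by [rank_features()].
#' @export
ranking_methods <- function() {
  c("p_value", "q_value", "pca_pc1", "pca_pc2", "pca_pc12",
    "lda_independent", "lda_forward", "lda_backward", "gram_schmidt")
}

# vectorised two-sample Welch t-test p-values per column
welch_p_values <- function(X, y) {
  g1 <- y == levels(y)[2L]   # seizure
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[!g1, , drop = FALSE], 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(p)] <- 1       # constant columns: worst possible evidence
  p
}

# per-column Fisher discriminant ratio (between-class over pooled within)
fisher_ratio <- function(X, y) {
  g1 <- y == levels(y)[2L]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[!g1, , drop = FALSE], 2L, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  r <- (m1 - m2)^2 / pooled
  r[!is.finite(r)] <- 0
  r
}

# pooled within-class covariance and mean-difference vector
pooled_within <- function(X, y) {
  g1 <- y == levels(y)[2L]
  X1 <- X[g1, , drop = FALSE]
  X2 <- X[!g1, , drop = FALSE]
  S1 <- stats::cov(X1)
  S2 <- stats::cov(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  W <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  list(W = W, d = colMeans(X1) - colMeans(X2))
}

ridge_eps <- function(W) 1e-6 * sum(diag(W)) / max(1L, ncol(W))

# backward greedy elimination of the Fisher criterion J(S) = d' W^-1 d,
# using the rank-one deletion identity J(S \ j) = J(S) - (A d)_j^2 / A_jj
# with A = W^-1; rank 1 = last survivor.
lda_backward_order <- function(X, y) {
  p <- ncol(X)
  pw <- pooled_within(X, y)
  W <- pw$W + diag(ridge_eps(pw$W), p)
  A <- solve(W)
  d <- pw$d
  alive <- seq_len(p)
  removal <- integer(0)
  while (length(alive) > 1L) {
    Ad <- A %*% d
    loss <- as.vector(Ad)^2 / diag(A)
    j <- which.min(loss)   # ties: lowest index wins (which.min takes first)
    removal <- c(removal, alive[j])
    A <- A[-j, -j, drop = FALSE] -
      tcrossprod(A[-j, j, drop = FALSE]) / A[j, j]
    d <- d[-j]
    alive <- alive[-j]
  }
  rev(c(removal, alive))
}

# forward greedy selection by Fisher criterion gain, using the bordered
# inverse: adding j to S gives J(S + j) = J(S) + (d_j - w_j' A d_S)^2 / s_j
# with s_j = W_jj - w_j' A w_j. Ranks beyond max_steps fall back to the
# marginal per-feature ratio.
lda_forward_order <- function(X, y, max_steps = NULL) {
  p <- ncol(X)
  if (is.null(max_steps)) max_steps <- min(p, 60L)
  pw <- pooled_within(X, y)
  W <- pw$W + diag(ridge_eps(pw$W), p)
  d <- pw$d
  marginal <- fisher_ratio(X, y)
  sel <- integer(0)
  A <- matrix(0, 0, 0)
  rest <- seq_len(p)
  while (length(sel) < max_steps && length(rest)) {
    if (!length(sel)) {
      gain <- d[rest]^2 / diag(W)[rest]
    } else {
      B <- W[sel, rest, drop = FALSE]
      U <- A %*% B
      s <- diag(W)[rest] - colSums(B * U)
      num <- d[rest] - as.vector(crossprod(B, A %*% d[sel]))
      gain <- num^2 / pmax(s, 1e-12)
    }
    j <- rest[which.max(gain)]
    sel <- c(sel, j)
    # grow A = W_S^-1 by bordering
    if (length(sel) == 1L) {
      A <- matrix(1 / W[j, j], 1L, 1L)
    } else {
      old <- sel[-length(sel)]
      b <- W[old, j]
      u <- A %*% b
      s <- as.numeric(W[j, j] - crossprod(b, u))
      s <- max(s, 1e-12)
      A <- rbind(cbind(A + tcrossprod(u) / s, -u / s),
                 c(-u / s, 1 / s))
    }
    rest <- setdiff(rest, j)
  }
  c(sel, rest[order(-marginal[rest], rest)])
}

# Gram-Schmidt / orthogonal forward regression on the class indicator
gram_schmidt_order <- function(X, y) {
  p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  r <- as.numeric(y == levels(y)[2L])
  r <- r - mean(r)
  alive <- seq_len(p)
  order_ <- integer(0)
  score <- numeric(p)
  repeat {
    norms <- sqrt(colSums(Xc[, alive, drop = FALSE]^2))
    rn <- sqrt(sum(r^2))
    usable <- norms > 1e-10
    if (!any(usable) || rn < 1e-10) break
    co <- abs(colSums(Xc[, alive, drop = FALSE] * r)) /
      (pmax(norms, 1e-300) * rn)
    co[!usable] <- -1
    jj <- which.max(co)
    j <- alive[jj]
    order_ <- c(order_, j)
    score[j] <- co[jj]
    v <- Xc[, j] / norms[jj]
    alive <- alive[-jj]
    if (!length(alive)) break
    # orthogonalise remaining columns and the residual target against v
    Xc[, alive] <- Xc[, alive, drop = FALSE] -
      outer(v, as.vector(crossprod(Xc[, alive, drop = FALSE], v)))
    r <- r - v * sum(v * r)
  }
  list(order = c(order_, alive[order(alive)]), score = score)
}

#' Rank feature columns by discriminative power
#'
#' Orders the columns of a feature matrix by one of nine criteria:
#' two-sample p-values (`p_value`) and their Benjamini-Hochberg q-values
#' (`q_value`); absolute loadings on the first, second, or both principal
#' components of the (centred, unstandardised) feature values (`pca_pc1`,
#' `pca_pc2`, `pca_pc12` - the last taking the larger of the two); the
#' per-feature Fisher discriminant ratio (`lda_independent`); greedy
#' sequential forward / backward search maximising the multivariate Fisher
#' criterion on the pooled within-class covariance (`lda_forward`,
#' `lda_backward`, rank = selection / reverse-removal order, singular
#' covariances ridge-regularised); and Gram-Schmidt orthogonal forward
#' regression on the class indicator (`gram_schmidt`). Ties are broken by
#' ascending column index; constant columns are ranked last with a warning.
#'
#' @param matrix a [feature_matrix] with both classes present.
#' @param method one of [ranking_methods()].
#' @param max_steps for `lda_forward`: number of greedy steps before the
#'   remaining columns are appended by marginal ratio (default
#'   `min(p, 60)`).
#' @return An object of class `ranking_result`: list with `method`, `order`
#'   (a permutation of column indices, best first) and `score` (per
#'   column).
#' @export
rank_features <- function(matrix, method = ranking_methods(),
                          max_steps = NULL) {
  method <- match.arg(method)
  X <- matrix$values
  y <- matrix$labels
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L) {
    stop("both classes with >= 2 observations are required", call. = FALSE)
  }
  p <- ncol(X)
  const <- apply(X, 2L, function(c) max(c) - min(c) < 1e-12)
  if (any(const)) {
    warning(sum(const), " constant column(s) assigned worst rank")
  }
  ord_by <- function(score, decreasing) {
    # constant columns forced to the tail, ties by ascending index
    key <- if (decreasing) -score else score
    key[const] <- Inf
    order(key, seq_len(p))
  }
  res <- switch(method,
    p_value = {
      s <- welch_p_values(X, y)
      list(order = ord_by(s, FALSE), score = s)
    },
    q_value = {
      s <- stats::p.adjust(welch_p_values(X, y), method = "BH")
      list(order = ord_by(s, FALSE), score = s)
    },
    pca_pc1 = ,
    pca_pc2 = ,
    pca_pc12 = {
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      L <- abs(pc$rotation)
      s <- switch(method,
                  pca_pc1 = L[, 1L],
                  pca_pc2 = if (ncol(L) >= 2L) L[, 2L] else L[, 1L] * 0,
                  pca_pc12 = if (ncol(L) >= 2L) pmax(L[, 1L], L[, 2L])
                             else L[, 1L])
      list(order = ord_by(s, TRUE), score = s)
    },
    lda_independent = {
      s <- fisher_ratio(X, y)
      list(order = ord_by(s, TRUE), score = s)
    },
    lda_forward = {
      o <- lda_forward_order(X, y, max_steps)
      list(order = o, score = rank_to_score(o, p))
    },
    lda_backward = {
      o <- lda_backward_order(X, y)
      list(order = o, score = rank_to_score(o, p))
    },
    gram_schmidt = {
      g <- gram_schmidt_order(X, y)
      list(order = g$order, score = g$score)
    })
  structure(list(method = method, order = as.integer(res$order),
                 score = as.numeric(res$score)),
            class = "ranking_result")
}

rank_to_score <- function(order_, p) {
  s <- numeric(p)
  s[order_] <- p:1
  s
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> method %s, %d columns; top 5: %s\n",
              x$method, length(x$order),
              paste(utils::head(x$order, 5L), collapse = ", ")))
  invisible(x)
}

#' Top-k mutually decorrelated features
#'
#' Walks a ranking from best to worst, keeping a feature only if its
#' absolute Pearson correlation with every already-kept feature is at most
#' `max_abs_corr`, until `k` features are kept or the ranking is exhausted
#' (a warning is raised if fewer than `k` survive). `max_abs_corr = 1`
#' disables the filter.
#'
#' @param ranking a `ranking_result` from [rank_features()].
#' @param matrix the [feature_matrix] the ranking was computed on.
#' @param k number of features to keep (default 20).
#' @param max_abs_corr decorrelation threshold in `[0, 1]` (default 0.9).
#' @return Integer vector of kept column indices, best first.
#' @export
select_top_uncorrelated <- function(ranking, matrix, k = 20L,
                                    max_abs_corr = 0.9) {
  stopifnot(inherits(ranking, "ranking_result"), k >= 1L)
  X <- matrix$values
  kept <- integer(0)
  for (j in ranking$order) {
    if (length(kept) >= k) break
    if (stats::sd(X[, j]) < 1e-12) next
    if (length(kept) &&  max_abs_corr < 1) {
      r <- abs(stats::cor(X[, kept, drop = FALSE], X[, j]))
      if (any(r > max_abs_corr, na.rm = TRUE)) next
    }
    kept <- c(kept, j)
  }
  if (length(kept) < k) {
    warning(sprintf("only %d of %d requested features survive decorrelation",
                    length(kept), k))
  }
  kept
}

#' Region-wise top features
#'
#' Restricts the feature columns to each scalp region's channels, ranks them
#' within the region (default by the sequential backward discriminant
#' search, the criterion that performed best in whole-brain ranking), and
#' keeps the top `per_region` per region: five regions x five features gives
#' the 25-feature region-wise set. Region channels absent from the matrix
#' montage are reported; a region with fewer than `per_region` candidate
#' columns contributes all it has, with a warning.
#'
#' @param matrix a [feature_matrix].
#' @param map a [region_map] (default [region_map_default()]).
#' @param ranking_method ranking criterion within regions (default
#'   `"lda_backward"`).
#' @param per_region features kept per region (default 5).
#' @return Integer vector of selected column indices (region-major order),
#'   with the per-region breakdown in attribute `"regions"`.
#' @export
select_region_top <- function(matrix, map = region_map_default(quiet = TRUE),
                              ranking_method = "lda_backward",
                              per_region = 5L) {
  stopifnot(inherits(map, "region_map"))
  montage <- unique(matrix$descriptors$channel)
  unmatched <- setdiff(unlist(map$channels), montage)
  if (length(unmatched)) {
    message("region-map channels not in montage: ",
            paste(unmatched, collapse = ", "))
  }
  out <- integer(0)
  breakdown <- list()
  for (id in names(map$channels)) {
    cols <- which(matrix$descriptors$channel %in% map$channels[[id]])
    if (!length(cols)) {
      warning("region ", id, " has no candidate features; skipped")
      next
    }
    sub <- fm_subset(matrix, cols = cols)
    rk <- rank_features(sub, ranking_method)
    take <- min(per_region, length(cols))
    if (take < per_region) {
      warning(sprintf("region %s has only %d candidate features", id,
                      length(cols)))
    }
    sel <- cols[rk$order[seq_len(take)]]
    breakdown[[id]] <- sel
    out <- c(out, sel)
  }
  attr(out, "regions") <- breakdown
  out
}
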