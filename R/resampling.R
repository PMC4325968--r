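#' SMOTE parameters
#'
#' @param k_neighbours number of same-class nearest neighbours a synthetic
#'   point may interpolate toward (default 5, the original SMOTE
#'   convention).
#' @param amount per-class oversampling percentage (default 100: each class
#'   doubles).
#' @param seed integer seed fixing neighbour choice and interpolation.
#' @return An object of class `smote_params`.
#' @export
smote_params <- function(k_neighbours = 5L, amount = 100, seed = NULL) {
  if (k_neighbours < 1L) stop("k_neighbours must be >= 1", call. = FALSE)
  if (amount < 0) stop("amount must be >= 0", call. = FALSE)
  structure(list(k_neighbours = as.integer(k_neighbours), amount = amount,
                 seed = seed), class = "smote_params")
}

#' Synthetic minority oversampling (applied to both classes)
#'
#' For each seed observation, SMOTE picks one of its `k_neighbours`
#' same-class nearest neighbours (Euclidean distance in feature space) and
#' emits the point `seed + u * (neighbour - seed)` with `u` uniform on
#' `[0, 1]`, i.e. a point on the segment joining the pair. Both classes are
#' oversampled by `amount` percent; at the default 100%, a balanced 171/171
#' dataset becomes 342/342. Original rows are retained and distinguishable
#' via the matrix's `synthetic` flag.
#'
#' @param matrix a [feature_matrix].
#' @param params a [smote_params()].
#' @return A [feature_matrix] with the synthetic rows appended.
#' @export
smote_oversample <- function(matrix, params = smote_params()) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(params, "smote_params"))
  X <- matrix$values
  y <- matrix$labels
  k <- params$k_neighbours
  with_local_seed(params$seed, {
    new_rows <- list()
    new_labels <- character(0)
    for (cl in levels(droplevels(y))) {
      idx <- which(y == cl)
      n_cl <- length(idx)
      n_new <- round(n_cl * params$amount / 100)
      if (n_new == 0L) next
      if (n_cl <= k) {
        stop(sprintf("parameter error: class '%s' has %d members, need > k = %d",
                     cl, n_cl, k), call. = FALSE)
      }
      Xc <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1L, function(row) order(row)[seq_len(k)])
      nn <- matrix(nn, nrow = k)    # k x n_cl
      # each observation seeds floor(amount/100) points; the remainder of
      # seeds is drawn at random, as in the original SMOTE formulation
      per <- n_new %/% n_cl
      seeds <- rep(seq_len(n_cl), per)
      extra <- n_new - length(seeds)
      if (extra > 0L) seeds <- c(seeds, sample_int(n_cl, extra))
      for (s in seeds) {
        nb <- nn[sample_int(k, 1L), s]
        u <- stats::runif(1)
        new_rows[[length(new_rows) + 1L]] <- Xc[s, ] + u * (Xc[nb, ] - Xc[s, ])
        new_labels <- c(new_labels, cl)
      }
    }
    if (!length(new_rows)) return(matrix)
    synth <- do.call(rbind, new_rows)
    colnames(synth) <- colnames(X)
    feature_matrix(rbind(X, synth), matrix$descriptors,
                   c(as.character(y), new_labels),
                   c(matrix$synthetic, rep(TRUE, nrow(synth))))
  })
}
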