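#' Classifier specification
#'
#' Describes one of the nine reference classifiers behind the common
#' fit/score interface:
#' `LDC` (Gaussian classes, pooled covariance), `QDC` (class-specific full
#' covariance), `UDC` (class-specific diagonal covariance, i.e. uncorrelated
#' normal densities), `POLYC` (degree-2 polynomial expansion followed by a
#' linear discriminant), `LOGLC` (logistic regression), `KNNC` (k-nearest
#' neighbour vote), `TREEC` (binary decision tree with impurity splits),
#' `PARZENC` (Gaussian-kernel density per class) and `SVC` (support vector
#' machine, linear kernel by default).
#'
#' @param kind one of `"LDC"`, `"QDC"`, `"UDC"`, `"POLYC"`, `"LOGLC"`,
#'   `"KNNC"`, `"TREEC"`, `"PARZENC"`, `"SVC"`.
#' @param hyperparams kind-specific list: `k` for KNNC (default: chosen by
#'   inner 5-fold validation over 1, 3, 5, 7, 9), `bandwidth` for PARZENC
#'   (default: inner validation over a small multiplier grid around a
#'   normal-reference bandwidth), `kernel` and `cost` for SVC (defaults
#'   `"linear"`, 1).
#' @param seed integer seed for the stochastic parts of fitting (inner
#'   validation folds).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = classifier_kinds(), hyperparams = list(),
                            seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(hyperparams))
  structure(list(kind = kind, hyperparams = hyperparams, seed = seed),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
classifier_kinds <- function() {
  c("LDC", "QDC", "UDC", "POLYC", "LOGLC", "KNNC", "TREEC", "PARZENC", "SVC")
}

POSITIVE <- "seizure"

# standardise with train statistics; zero-variance columns pass through
standardise_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  list(mu = mu, sd = sd_)
}
standardise_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$mu, "-"), 2L, st$sd, "/")
}

well_conditioned <- function(S) {
  tryCatch({chol(S); rcond(S) > 1e-10},
           error = function(e) FALSE)
}

# class covariance with ridge fallback when (near-)singular
safe_cov <- function(Xc, diagonal = FALSE) {
  S <- stats::cov(Xc)
  if (diagonal) S <- diag(pmax(diag(S), 0), ncol(Xc))
  eps <- 1e-6 * sum(diag(S)) / max(1L, ncol(S))
  if (eps <= 0) eps <- 1e-8
  if (!well_conditioned(S)) {
    warning("singular covariance regularised with a diagonal ridge")
    # a small ridge can still be insufficient for exactly collinear data
    repeat {
      S <- S + diag(eps, ncol(S))
      if (well_conditioned(S)) break
      eps <- eps * 10
    }
  }
  S
}

gaussian_fit <- function(X, y, mode = c("pooled", "full", "diag")) {
  mode <- match.arg(mode)
  classes <- levels(droplevels(y))
  n <- nrow(X)
  means <- list(); covs <- list(); priors <- numeric(0)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    means[[cl]] <- colMeans(Xc)
    priors[cl] <- nrow(Xc) / n
  }
  if (mode == "pooled") {
    g1 <- y == classes[1L]
    S <- ((sum(g1) - 1) * stats::cov(X[g1, , drop = FALSE]) +
            (sum(!g1) - 1) * stats::cov(X[!g1, , drop = FALSE])) / (n - 2)
    eps <- max(1e-6 * sum(diag(S)) / max(1L, ncol(S)), 1e-10)
    if (!well_conditioned(S)) {
      warning("singular covariance regularised with a diagonal ridge")
      repeat {
        S <- S + diag(eps, ncol(S))
        if (well_conditioned(S)) break
        eps <- eps * 10
      }
    }
    covs <- stats::setNames(rep(list(S), length(classes)), classes)
  } else {
    for (cl in classes) {
      covs[[cl]] <- safe_cov(X[y == cl, , drop = FALSE],
                             diagonal = mode == "diag")
    }
  }
  list(classes = classes, means = means, covs = covs, priors = priors)
}

gaussian_log_dens <- function(X, mean_, cov_) {
  R <- chol(cov_)
  z <- forwardsolve(t(R), t(sweep(X, 2L, mean_, "-")))
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

gaussian_posterior <- function(model, X) {
  ll <- vapply(model$classes, function(cl) {
    gaussian_log_dens(X, model$means[[cl]], model$covs[[cl]]) +
      log(model$priors[cl])
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X),
               dimnames = list(NULL, model$classes))
  m <- apply(ll, 1L, max)
  post <- exp(ll - m)
  post / rowSums(post)
}

poly_expand <- function(X) cbind(X, X^2)

parzen_log_dens <- function(Xtrain_c, X, h) {
  # product Gaussian kernel, common bandwidth on standardised features
  d <- ncol(X)
  ll <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    q <- -rowSums(sweep(Xtrain_c, 2L, X[i, ], "-")^2) / (2 * h^2)
    m <- max(q)
    ll[i] <- m + log(mean(exp(q - m))) - d * log(h) - 0.5 * d * log(2 * pi)
  }
  ll
}

inner_folds <- function(y, folds = 5L) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Fit a seizure/nonseizure classifier
#'
#' Fits the classifier named by `spec` to a feature matrix. Features are
#' standardised with training mean and standard deviation inside the fit
#' (distance- and density-based kinds require it; it is harmless for the
#' others). Singular covariance matrices are ridge-regularised with a
#' warning. KNNC's `k` and PARZENC's bandwidth default to inner 5-fold
#' validation on the training data.
#'
#' @param spec a [classifier_spec()].
#' @param matrix a [feature_matrix] containing both classes.
#' @return An object of class `seizure_model`, scorable with [score()] or
#'   [predict()] on matrices carrying the same feature descriptors.
#' @export
fit_classifier <- function(spec, matrix) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(matrix, "feature_matrix"))
  y <- droplevels(matrix$labels)
  if (nlevels(y) < 2L) stop("both classes must be present", call. = FALSE)
  y <- factor(as.character(y), levels = c("nonseizure", "seizure"))
  st <- standardise_fit(matrix$values)
  X <- standardise_apply(matrix$values, st)
  hp <- spec$hyperparams
  fitted <- with_local_seed(spec$seed, switch(spec$kind,
    LDC = gaussian_fit(X, y, "pooled"),
    QDC = gaussian_fit(X, y, "full"),
    UDC = gaussian_fit(X, y, "diag"),
    POLYC = gaussian_fit(poly_expand(X), y, "pooled"),
    LOGLC = {
      df <- data.frame(X)
      names(df) <- sprintf("x%d", seq_len(ncol(X)))
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial()))
    },
    KNNC = {
      k <- hp$k
      if (is.null(k)) {
        grid <- c(1L, 3L, 5L, 7L, 9L)
        grid <- grid[grid < min(table(y))]
        if (!length(grid)) grid <- 1L
        fold <- inner_folds(y)
        err <- vapply(grid, function(kk) {
          mean(vapply(1:5, function(f) {
            tr <- fold != f
            if (!any(tr) || !all(table(y[tr]) > 0)) return(NA_real_)
            pr <- class::knn(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                             y[tr], k = kk)
            mean(pr != y[!tr])
          }, 0), na.rm = TRUE)
        }, 0)
        k <- grid[which.min(err)]
      }
      list(X = X, y = y, k = as.integer(k))
    },
    TREEC = {
      df <- data.frame(X)
      names(df) <- sprintf("x%d", seq_len(ncol(X)))
      rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class")
    },
    PARZENC = {
      d <- ncol(X)
      h0 <- (4 / (d + 2))^(1 / (d + 4)) * nrow(X)^(-1 / (d + 4))
      h <- hp$bandwidth
      if (is.null(h)) {
        grid <- h0 * c(0.5, 1, 2, 4)
        fold <- inner_folds(y)
        err <- vapply(grid, function(hh) {
          mean(vapply(1:5, function(f) {
            tr <- fold != f
            sc <- parzen_score(X[tr, , drop = FALSE], y[tr],
                               X[!tr, , drop = FALSE], hh)
            mean((sc >= 0.5) != (y[!tr] == POSITIVE))
          }, 0))
        }, 0)
        h <- grid[which.min(err)]
      }
      list(X = X, y = y, h = h)
    },
    SVC = {
      kern <- if (is.null(hp$kernel)) "linear" else hp$kernel
      cost <- if (is.null(hp$cost)) 1 else hp$cost
      fit <- e1071::svm(X, y, kernel = kern, cost = cost, scale = FALSE)
      dv <- attr(stats::predict(fit, X, decision.values = TRUE),
                 "decision.values")[, 1L]
      flip <- mean(dv[y == POSITIVE]) < mean(dv[y != POSITIVE])
      list(fit = fit, flip = flip)
    }))
  structure(list(spec = spec, standardise = st, fitted = fitted,
                 descriptors = matrix$descriptors,
                 classes = levels(y)),
            class = "seizure_model")
}

parzen_score <- function(Xtr, ytr, Xte, h) {
  l1 <- parzen_log_dens(Xtr[ytr == POSITIVE, , drop = FALSE], Xte, h) +
    log(mean(ytr == POSITIVE))
  l0 <- parzen_log_dens(Xtr[ytr != POSITIVE, , drop = FALSE], Xte, h) +
    log(mean(ytr != POSITIVE))
  1 / (1 + exp(pmin(700, pmax(-700, l0 - l1))))
}

#' Score observations with a fitted classifier
#'
#' Returns a continuous seizure score per observation - a posterior
#' probability (density-based kinds, logistic, tree, k-NN vote fraction) or
#' a logistic-mapped decision value (SVC), in every case monotone in
#' evidence for the seizure class - together with the predicted label at the
#' default threshold (posterior 0.5 / decision value 0). Scoring a matrix
#' whose feature descriptors differ from the training descriptors is a
#' contract error.
#'
#' @param model a `seizure_model` from [fit_classifier()].
#' @param matrix a [feature_matrix] with matching descriptors.
#' @return data.frame with columns `score` (numeric, higher = more
#'   seizure-like) and `label` (factor `"nonseizure"`/`"seizure"`).
#' @export
score <- function(model, matrix) {
  stopifnot(inherits(model, "seizure_model"),
            inherits(matrix, "feature_matrix"))
  if (!identical(model$descriptors[, c("feature", "channel", "band")],
                 matrix$descriptors[, c("feature", "channel", "band")])) {
    stop("contract error: feature descriptors do not match the training set",
         call. = FALSE)
  }
  X <- standardise_apply(matrix$values, model$standardise)
  f <- model$fitted
  s <- switch(model$spec$kind,
    LDC = , QDC = , UDC = gaussian_posterior(f, X)[, POSITIVE],
    POLYC = gaussian_posterior(f, poly_expand(X))[, POSITIVE],
    LOGLC = {
      df <- data.frame(X)
      names(df) <- sprintf("x%d", seq_len(ncol(X)))
      as.numeric(stats::predict(f, newdata = df, type = "response"))
    },
    KNNC = {
      pr <- class::knn(f$X, X, f$y, k = f$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == POSITIVE, win, 1 - win)
    },
    TREEC = {
      df <- data.frame(X)
      names(df) <- sprintf("x%d", seq_len(ncol(X)))
      stats::predict(f, newdata = df, type = "prob")[, POSITIVE]
    },
    PARZENC = parzen_score(f$X, f$y, X, f$h),
    SVC = {
      dv <- attr(stats::predict(f$fit, X, decision.values = TRUE),
                 "decision.values")[, 1L]
      if (f$flip) dv <- -dv
      stats::plogis(dv)
    })
  s <- as.numeric(s)
  data.frame(score = s,
             label = factor(ifelse(s >= 0.5, "seizure", "nonseizure"),
                            levels = c("nonseizure", "seizure")))
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf("<seizure_model> %s on %d features\n", x$spec$kind,
              nrow(x$descriptors)))
  invisible(x)
}

#' @param object,newdata,type standard predict arguments: a `seizure_model`,
#'   a [feature_matrix], and `"score"` or `"label"`.
#' @param ... unused.
#' @rdname score
#' @export
predict.seizure_model <- function(object, newdata,
                                  type = c("score", "label"), ...) {
  type <- match.arg(type)
  out <- score(object, newdata)
  if (type == "score") out$score else out$label
}
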