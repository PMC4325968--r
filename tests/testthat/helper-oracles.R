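# Independent brute-force oracles. These deliberately use plain loops and
# first-principles definitions, not the package's implementations.

bf_variance <- function(x) {
  mu <- sum(x) / length(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  s / (length(x) - 1)
}

bf_energy <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  s
}

bf_rms <- function(x) sqrt(bf_energy(x) / length(x))

bf_moment <- function(x, k) {
  mu <- mean(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^k
  s / length(x)
}

bf_skewness <- function(x) bf_moment(x, 3) / bf_moment(x, 2)^1.5

bf_kurtosis <- function(x) bf_moment(x, 4) / bf_moment(x, 2)^2

bf_entropy <- function(x) {
  tot <- bf_energy(x)
  h <- 0
  for (v in x) {
    p <- v * v / tot
    if (p > 0) h <- h - p * log(p)
  }
  h
}

# pair-counting AUC: P(score_pos > score_neg) + 0.5 P(equal)
bf_auc <- function(truth, scores) {
  pos <- scores[as.character(truth) == "seizure"]
  neg <- scores[as.character(truth) != "seizure"]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

bf_confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "seizure") {
      if (predicted[i] == "seizure") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (predicted[i] == "seizure") fp <- fp + 1 else tn <- tn + 1
    }
  }
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    error = (fp + fn) / length(truth))
}

# correlation-integral slope by direct pair counting on given points
bf_corr_dim_slope <- function(points, radii) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  m <- nrow(points)
  cr <- numeric(length(radii))
  for (ri in seq_along(radii)) {
    cnt <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (sqrt(sum((points[i, ] - points[j, ])^2)) < radii[ri]) cnt <- cnt + 1
    }
    cr[ri] <- cnt / (m * (m - 1) / 2)
  }
  keep <- cr > 0 & cr < 1
  stats::coef(stats::lm(log(cr[keep]) ~ log(radii[keep])))[[2L]]
}

# mean window repair by direct slicing
bf_window_mean <- function(x, i, half, missing_idx) {
  lo <- max(1L, i - half); hi <- min(length(x), i + half)
  idx <- setdiff(lo:hi, missing_idx)
  mean(x[idx])
}
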