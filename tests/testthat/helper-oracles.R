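# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain vectorized R, sharing no code
# with the package implementations they check.

# Sample entropy by explicit template enumeration: embed, compute all
# pairwise Chebyshev distances, count matches over i < j.
sampen_oracle <- function(x, m = 2, r_factor = 0.2) {
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_factor * s
  n <- length(x)
  nt <- n - m
  emb <- function(len) {
    sapply(seq_len(len), function(k) x[(0:(nt - 1)) + k])
  }
  cheb_pairs <- function(E) {
    D <- matrix(0, nt, nt)
    for (k in seq_len(ncol(E)))
      D <- pmax(D, abs(outer(E[, k], E[, k], "-")))
    sum(D[upper.tri(D)] <= r)
  }
  B <- cheb_pairs(emb(m))
  A <- cheb_pairs(emb(m + 1))
  if (B == 0) return(NA_real_)
  -log(A / B)
}

# Naive per-sample Hampel loop: centered window truncated at the edges,
# median and 1.4826 * median absolute deviation, replacement by the local
# median when the deviation exceeds n_sd dispersions.
hampel_oracle <- function(x, fs, window_seconds = 15, n_sd = 2) {
  n <- length(x)
  half <- floor(window_seconds * fs) %/% 2
  out <- x
  mask <- logical(n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - half):min(n, i + half)]
    med <- median(win)
    sigma <- 1.4826 * median(abs(win - med))
    if (abs(x[i] - med) > n_sd * sigma) {
      out[i] <- med
      mask[i] <- TRUE
    }
  }
  list(values = out, outlier = mask)
}

# AUC by exhaustive pair ordering with half credit for ties.
auc_oracle <- function(truth, scores, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Total integrated one-sided power of an mw_spectrum (trapezoid).
band_integral_total <- function(sp) {
  f <- sp$frequencies; p <- sp$power
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

# A linearly separable two-class toy table with grouped subjects.
make_toy_table <- function(n_subjects = 26, delta = 10, seed = 1,
                           n_noise = 1) {
  set.seed(seed)
  n <- 2 * n_subjects
  df <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2),
    label = rep(0:1, n_subjects))
  df$f1 <- rnorm(n) + df$label * delta
  for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  df
}

# Small fast cohort shared across test files (computed at most once per
# test run). Short phases keep extraction cheap while retaining >= 2 LF
# cycles per phase.
short_durations <- c(BL = 120, Forward = 60, Backward = 60,
                     ImmR = 60, DelR = 60, Rec = 60)

.shared <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.shared$cohort))
    .shared$cohort <- generate_cohort(
      synth_config(n_subjects = 8, seed = 42,
                   phase_durations = short_durations))
  .shared$cohort
}

shared_features <- function() {
  if (is.null(.shared$features))
    .shared$features <- suppressWarnings(extract_features(shared_cohort()))
  .shared$features
}
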