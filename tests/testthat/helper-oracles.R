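# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: plain double loops and direct formulas.

# naive circular convolution: y[i] = sum_j h[j] x[(i-j) mod n], 0-based lags
naive_circ_conv <- function(x, h) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_along(h)) {
      acc <- acc + h[j] * x[((i - 1L) - (j - 1L)) %% n + 1L]
    }
    y[i] <- acc
  }
  y
}

# two-pass 1-D a-trous filtering of a matrix: columns (dim 1) then rows
naive_separable_filter <- function(m, h_col, h_row) {
  tmp <- apply(m, 2, naive_circ_conv, h = h_col)
  t(apply(tmp, 1, naive_circ_conv, h = h_row))
}

# brute-force pairwise-ranking AUC: concordant pairs + half ties
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# pooled one-vs-rest expansion of a score matrix, for the micro-AUC oracle
pooled_expansion <- function(scores, truth) {
  K <- ncol(scores)
  list(scores = as.vector(scores),
       positive = as.vector(sapply(seq_len(K), function(k) truth == k)))
}

random_rgb <- function(h, w = h) array(stats::runif(h * w * 3), c(h, w, 3))

random_score_matrix <- function(n, k) {
  s <- matrix(stats::runif(n * k), n, k)
  s / rowSums(s)
}
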