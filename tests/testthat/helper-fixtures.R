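# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Two-class features separated only along a planted unit direction v:
# class means at +/- v, isotropic Gaussian noise elsewhere.
planted_features <- function(n_per_class, d, noise_sd, seed) {
  set.seed(seed)
  v <- stats::rnorm(d); v <- v / sqrt(sum(v^2))
  X <- rbind(
    matrix(stats::rnorm(n_per_class * d, 0, noise_sd), n_per_class, d) +
      matrix(v, n_per_class, d, byrow = TRUE),
    matrix(stats::rnorm(n_per_class * d, 0, noise_sd), n_per_class, d) -
      matrix(v, n_per_class, d, byrow = TRUE))
  list(X = X, labels = rep(0:1, each = n_per_class), v = v)
}

# Random symmetric PSD matrix via a Gram construction.
random_psd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(d * d), d, d)
  crossprod(A) / d
}

angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# Independent single-cell LSTM oracle: plain scalar arithmetic, no reuse of
# the package's gate-splitting code.
lstm_cell_oracle <- function(W, U, b, x, h, c) {
  hd <- length(h)
  z <- as.vector(W %*% x) + as.vector(U %*% h) + b
  sig <- function(t) 1 / (1 + exp(-t))
  i <- sig(z[1:hd]); f <- sig(z[(hd + 1):(2 * hd)])
  g <- tanh(z[(2 * hd + 1):(3 * hd)]); o <- sig(z[(3 * hd + 1):(4 * hd)])
  cn <- f * c + i * g
  list(h = o * tanh(cn), c = cn)
}

# Brute-force enumeration of every valid (anchor, positive, negative)
# triple over a label vector.
enumerate_triplets <- function(labels) {
  n <- length(labels)
  out <- matrix(0L, 0L, 3L)
  for (a in seq_len(n)) for (p in seq_len(n)) for (g in seq_len(n)) {
    if (p != a && labels[p] == labels[a] && labels[g] != labels[a]) {
      out <- rbind(out, c(a, p, g))
    }
  }
  out
}
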