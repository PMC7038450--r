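# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately written as plain double loops over the
# definitions; they must not share code with the package internals.

oracle_raw_moment <- function(grid, p, q) {
  acc <- 0
  for (r in seq_len(nrow(grid))) {
    for (cc in seq_len(ncol(grid))) {
      x <- cc - 1
      y <- r - 1
      acc <- acc + x^p * y^q * grid[r, cc]
    }
  }
  acc
}

oracle_central_moment <- function(grid, p, q, xbar, ybar) {
  acc <- 0
  for (r in seq_len(nrow(grid))) {
    for (cc in seq_len(ncol(grid))) {
      acc <- acc + (cc - 1 - xbar)^p * (r - 1 - ybar)^q * grid[r, cc]
    }
  }
  acc
}

oracle_central_and_hu <- function(grid) {
  m00 <- oracle_raw_moment(grid, 0, 0)
  eps <- max(1e-12, 1e-12 * max(abs(grid)))
  if (abs(m00) <= eps) return(numeric(10))
  xbar <- oracle_raw_moment(grid, 1, 0) / m00
  ybar <- oracle_raw_moment(grid, 0, 1) / m00
  mu <- function(p, q) oracle_central_moment(grid, p, q, xbar, ybar)
  eta <- function(p, q) mu(p, q) / abs(m00)^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  a <- n30 + n12
  b <- n21 + n03
  c(mu(2, 0), mu(1, 1), mu(0, 2),
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    a^2 + b^2,
    (n30 - 3 * n12) * a * (a^2 - 3 * b^2) + (3 * n21 - n03) * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    (3 * n21 - n03) * a * (a^2 - 3 * b^2) - (n30 - 3 * n12) * b * (3 * a^2 - b^2))
}

# Loop-based key-frame oracle over a frames matrix (rows = frames).
oracle_keyframes <- function(X) {
  n <- nrow(X)
  kf1 <- kf2 <- kf3 <- kf4 <- kf8 <- numeric(20)
  for (j in 1:20) {
    kf1[j] <- sum(X[, j]) / n
    pos <- 0; neg <- 0; tot <- 0
    for (i in seq_len(n - 1)) {
      d <- X[i + 1, j] - X[i, j]
      tot <- tot + d
      if (d > 0) pos <- pos + d else neg <- neg + d
    }
    kf2[j] <- tot
    kf3[j] <- pos
    kf4[j] <- abs(neg)
  }
  means <- numeric(n); sds <- numeric(n)
  for (i in seq_len(n)) {
    means[i] <- mean(X[i, ])
    sds[i] <- stats::sd(X[i, ])
  }
  for (j in 1:20) {
    acc <- 0
    for (i in seq_len(n)) {
      if (X[i, j] >= means[i]) acc <- acc + X[i, j]
    }
    kf8[j] <- acc / n
  }
  rbind(KF1 = kf1, KF2 = kf2, KF3 = kf3, KF4 = kf4,
        KF5 = X[which.max(means), ], KF6 = X[which.min(means), ],
        KF7 = X[which.max(sds), ], KF8 = kf8)
}

# Loop-based binning oracle: 26 bins over [-2, 2], clipped.
oracle_bin_counts <- function(values) {
  counts <- numeric(26)
  edges <- seq(-2, 2, length.out = 27)
  for (v in values) {
    b <- NA
    for (k in 1:26) {
      if (v >= edges[k] && v < edges[k + 1]) { b <- k; break }
    }
    if (is.na(b)) b <- if (v < -2) 1 else 26
    counts[b] <- counts[b] + 1
  }
  counts
}

random_stream <- function(n = 50, seed = 1, lo = 0, hi = 4095) {
  withr::with_seed(seed, {
    frame_stream(seq(0, by = 15, length.out = n),
                 matrix(sample(lo:hi, n * 20, replace = TRUE), nrow = n))
  })
}
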