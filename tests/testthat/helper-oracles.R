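# Independent straight-line oracles, written directly from the defining
# formulas and kept deliberately naive (explicit loops, no shared code with
# the package) so they can arbitrate the vectorized implementations.

# Percentage-bend correlation, definitional form.
oracle_pbcor <- function(x, y, bend = 0.2) {
  n <- length(x)
  scale_of <- function(v) {
    devs <- sort(abs(v - median(v)))
    m <- floor((1 - bend) * n + 0.5)
    devs[m]
  }
  location_of <- function(v, omega) {
    med <- median(v)
    lo <- 0L; hi <- 0L; total <- 0
    for (vi in v) {
      u <- (vi - med) / omega
      if (u < -1) lo <- lo + 1L
      else if (u > 1) hi <- hi + 1L
      else total <- total + vi
    }
    (total + omega * (hi - lo)) / (n - lo - hi)
  }
  wx <- scale_of(x); wy <- scale_of(y)
  phix <- location_of(x, wx); phiy <- location_of(y, wy)
  A <- numeric(n); B <- numeric(n)
  for (i in seq_len(n)) {
    u <- (x[i] - phix) / wx
    v <- (y[i] - phiy) / wy
    A[i] <- max(-1, min(1, u))
    B[i] <- max(-1, min(1, v))
  }
  r <- sum(A * B) / sqrt(sum(A^2) * sum(B^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tt, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up adjusted values, literal definition:
# q_(i) = min_{j >= i} p_(j) * m / j on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Classic Levene F: one-way ANOVA on |x - group mean|, by hand.
oracle_levene_F <- function(values, group) {
  group <- as.character(group)
  gl <- unique(group)
  k <- length(gl)
  n <- length(values)
  ad <- numeric(n)
  for (g in gl) {
    idx <- group == g
    ad[idx] <- abs(values[idx] - mean(values[idx]))
  }
  grand <- mean(ad)
  ssb <- 0; ssw <- 0
  for (g in gl) {
    idx <- group == g
    ssb <- ssb + sum(idx) * (mean(ad[idx]) - grand)^2
    ssw <- ssw + sum((ad[idx] - mean(ad[idx]))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# OLS coefficients by the normal equations, for hand-checkable designs.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# Cook's distance via leave-one-out refits of the simple regression:
# d_i = sum_j (yhat_j - yhat_j^(-i))^2 / (k * s^2).
oracle_cooks <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- oracle_ols(X, y)
  yhat <- X %*% beta
  s2 <- sum((y - yhat)^2) / (n - 2)
  d <- numeric(n)
  for (i in seq_len(n)) {
    bi <- oracle_ols(X[-i, , drop = FALSE], y[-i])
    d[i] <- sum((yhat - X %*% bi)^2) / (2 * s2)
  }
  d
}

# All size-m subsets of a set, as a list of index vectors.
oracle_subsets <- function(n, m) {
  utils::combn(n, m, simplify = FALSE)
}
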