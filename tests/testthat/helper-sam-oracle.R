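# Independent brute-force one-class SAM, written as plain loops straight
# from the definitions, as a second implementation to check the vectorized
# one against.  It shares nothing with the package internals beyond base R.

oracle_d_stat <- function(x, s0) {
  n <- length(x)
  xb <- sum(x) / n
  s <- sqrt(sum((x - xb)^2) / (n - 1)) / sqrt(n)
  xb / (s + s0)
}

# every sign vector of length n exactly once, via binary counting
oracle_all_signs <- function(n) {
  out <- matrix(1, 2^n, n)
  for (p in 0:(2^n - 1))
    for (j in 1:n)
      if (bitwAnd(p, bitwShiftL(1L, j - 1L)) > 0) out[p + 1, j] <- -1
  out
}

oracle_sam <- function(X, s0) {
  m <- nrow(X); n <- ncol(X)
  d <- numeric(m)
  for (g in 1:m) d[g] <- oracle_d_stat(X[g, ], s0)

  signs <- oracle_all_signs(n)
  P <- nrow(signs)
  perm_sorted <- matrix(0, P, m)
  for (p in 1:P) {
    dp <- numeric(m)
    for (g in 1:m) dp[g] <- oracle_d_stat(X[g, ] * signs[p, ], s0)
    perm_sorted[p, ] <- sort(dp)
  }

  ds <- sort(d)
  dbar <- numeric(m)
  for (i in 1:m) dbar[i] <- mean(perm_sorted[, i])
  dev <- ds - dbar
  i_up <- if (any(dbar >= 0)) min(which(dbar >= 0)) else m + 1L
  i_dn <- if (any(dbar <= 0)) max(which(dbar <= 0)) else 0L
  deltas <- sort(unique(abs(dev)))

  pooled <- as.vector(perm_sorted)
  qs <- quantile(pooled, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= qs[1] & d <= qs[2]) / (0.5 * m))

  nd <- length(deltas)
  cutup <- rep(Inf, nd); cutlow <- rep(-Inf, nd); fdr <- rep(NA_real_, nd)
  for (t in 1:nd) {
    if (i_up <= m)
      for (i in i_up:m) if (dev[i] >= deltas[t]) { cutup[t] <- ds[i]; break }
    if (i_dn >= 1)
      for (i in i_dn:1) if (-dev[i] >= deltas[t]) { cutlow[t] <- ds[i]; break }
    called <- sum(d >= cutup[t]) + sum(d <= cutlow[t])
    if (called > 0) {
      fp <- numeric(P)
      for (p in 1:P)
        fp[p] <- sum(perm_sorted[p, ] >= cutup[t]) +
          sum(perm_sorted[p, ] <= cutlow[t])
      fdr[t] <- min(1, pi0 * median(fp) / called)
    }
  }

  q <- rep(1, m)
  for (g in 1:m)
    for (t in 1:nd)
      if (!is.na(fdr[t]) && (d[g] >= cutup[t] || d[g] <= cutlow[t]))
        q[g] <- min(q[g], fdr[t])

  # same monotone repair rule: min FDR over self and all weaker genes
  o <- order(abs(d))
  running <- Inf
  for (i in seq_along(o)) {
    running <- min(running, q[o[i]])
    q[o[i]] <- running
  }
  list(d = d, q = q, pi0 = pi0)
}

# independent brute-force scan for the fudge factor over the full grid
oracle_choose_s0 <- function(s, xbar, grid = seq(0, 100, by = 5)) {
  cand <- quantile(s, sort(grid) / 100, names = FALSE, type = 7)
  breaks <- unique(quantile(s, seq(0, 1, by = 0.01), names = FALSE))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  best <- NA_real_; best_cv <- Inf
  for (s0 in cand) {
    d <- xbar / (s + s0)
    mads <- c()
    for (w in levels(win)) {
      dd <- d[win == w]
      if (!length(dd)) next
      mads <- c(mads, median(abs(dd - median(dd))) / 0.64)
    }
    if (length(mads) < 2 || mean(mads) == 0) next
    cv <- sd(mads) / mean(mads)
    if (cv < best_cv - 1e-15) { best_cv <- cv; best <- s0 }
  }
  if (is.na(best)) cand[1] else best
}
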