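# Independent oracles for the Mann-Whitney U test.

# exact two-sided p by full enumeration of group assignments
oracle_mwu_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all <- c(x, y)
  U_of <- function(xi, yi) sum(outer(xi, yi, `>`)) + 0.5 * sum(outer(xi, yi, `==`))
  u_obs <- U_of(x, y)
  combos <- combn(nx + ny, nx)
  mu <- nx * ny / 2
  us <- apply(combos, 2, function(idx) U_of(all[idx], all[-idx]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p.value = p)
}

# Monte-Carlo estimate of the two-sided p (sampling group labels)
oracle_mwu_mc <- function(x, y, B = 1e6, seed = 99) {
  set.seed(seed)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  mu <- nx * ny / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  hits <- 0L
  chunk <- 20000L
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    for (i in seq_len(b)) {
      idx <- sample.int(n, nx)
      u <- sum(r[idx]) - nx * (nx + 1) / 2
      if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1L
    }
    done <- done + b
  }
  hits / B
}
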