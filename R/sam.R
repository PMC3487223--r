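#' Settings for one-class SAM
#'
#' @param q_threshold Per-treatment significance cutoff on the q-value.
#' @param s0_grid Percentile grid (0..100) searched for the fudge factor.
#' @param exhaustive_limit Enumerate all `2^n` sign flips exactly once
#'   whenever that count does not exceed this limit; otherwise sample.
#' @param n_sampled_permutations Sample size in sampled mode.
#' @param rng_seed Seed for sampled mode.
#' @return A `sam_config` list.
#' @export
sam_config <- function(q_threshold = 0.05, s0_grid = seq(0, 100, by = 5),
                       exhaustive_limit = 4096,
                       n_sampled_permutations = 1000, rng_seed = 1L) {
  if (q_threshold <= 0 || q_threshold >= 1)
    stopf("q_threshold must lie in (0, 1)")
  if (any(s0_grid < 0 | s0_grid > 100))
    stopf("s0 percentile grid must lie within [0, 100]")
  structure(list(q_threshold = q_threshold, s0_grid = sort(s0_grid),
                 exhaustive_limit = exhaustive_limit,
                 n_sampled_permutations = n_sampled_permutations,
                 rng_seed = as.integer(rng_seed)),
            class = "sam_config")
}

#' One-class SAM relative difference
#'
#' `d = xbar / (s + s0)` where `xbar` is the mean log2 ratio across
#' arrays and `s = sd / sqrt(n)` its standard error.  The fudge factor
#' `s0` stabilizes `d` for genes whose variance estimate is near zero.
#'
#' @param values Numeric vector of log2 ratios (one gene, n >= 2 arrays).
#' @param s0 Non-negative fudge factor.
#' @return The d statistic (finite; zero iff the mean is zero).
#' @examples
#' one_class_d(c(0.5, 1.0, 1.5, 2.0), s0 = 0.1)
#' @export
one_class_d <- function(values, s0) {
  n <- length(values)
  if (n < 2) stopf("one_class_d needs at least 2 values")
  if (s0 < 0) stopf("s0 must be >= 0")
  xbar <- mean(values)
  s <- stats::sd(values) / sqrt(n)
  xbar / (s + s0)
}

# row-wise mean and standard error of a genes x arrays matrix
row_stats <- function(X) {
  n <- ncol(X)
  xbar <- rowMeans(X)
  s <- sqrt(pmax(rowSums(X^2) - n * xbar^2, 0) / (n - 1)) / sqrt(n)
  list(xbar = xbar, s = s, n = n)
}

#' Select the SAM fudge factor s0
#'
#' Scans candidate values of `s0` over percentiles of the standard
#' errors.  For each candidate, genes are partitioned into 100 windows
#' by quantiles of `s`, the median absolute deviation (scaled by 1/0.64)
#' of `d` is computed per window, and the candidate minimizing the
#' coefficient of variation of those window MADs is selected, ties
#' broken toward the smallest percentile.
#'
#' @param s Vector of per-gene standard errors.
#' @param xbar Vector of per-gene mean log2 ratios.
#' @param grid Percentile grid, see [sam_config()].
#' @return The selected `s0` (an element of the percentile set of `s`).
#' @export
choose_s0 <- function(s, xbar, grid = seq(0, 100, by = 5)) {
  stopifnot(length(s) == length(xbar))
  m <- length(s)
  if (m < 10) warnf("s0 selection with fewer than 10 genes is unstable")
  if (all(s == 0)) {
    warnf("all standard errors are zero; using a small positive s0")
    return(1e-8)
  }
  candidates <- stats::quantile(s, sort(grid) / 100, names = FALSE, type = 7)
  breaks <- unique(stats::quantile(s, seq(0, 1, by = 0.01), names = FALSE))
  win <- if (length(breaks) > 2)
    cut(s, breaks = breaks, include.lowest = TRUE) else factor(rep(1, m))
  cv <- vapply(candidates, function(s0) {
    d <- xbar / (s + s0)
    v <- tapply(d, win, function(x)
      stats::mad(x, constant = 1 / 0.64))
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  }, 0)
  if (all(is.na(cv))) return(candidates[1])
  candidates[which.min(cv)]
}

#' Sign-flip permutation ensemble for one-class SAM
#'
#' The one-class null (mean log2 ratio zero, symmetric errors) is
#' simulated by flipping the sign of whole arrays.  All `2^n` sign
#' vectors are enumerated exactly once when feasible; otherwise a seeded
#' sample is drawn.  Each permutation yields the full vector of d
#' statistics, sorted ascending.
#'
#' @param X Genes x arrays matrix of log2 ratios for one treatment.
#' @param s0 Fudge factor (held fixed across permutations).
#' @param config A [sam_config()].
#' @return List with `perm_d` (permutations x genes matrix of sorted d),
#'   `signs` (arrays x permutations), and `mode`.
#' @export
sign_flip_permutations <- function(X, s0, config = sam_config()) {
  n <- ncol(X)
  if (n < 2) stopf("need at least 2 arrays")
  exhaustive <- 2^n <= config$exhaustive_limit
  signs <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
  } else {
    with_seed(subseed(config$rng_seed, "sam-perm"),
              matrix(sample(c(-1, 1), n * config$n_sampled_permutations,
                            replace = TRUE),
                     nrow = config$n_sampled_permutations))
  }
  dimnames(signs) <- NULL
  # sum of squares is invariant under sign flips, so only the mean moves
  rs2 <- rowSums(X^2)
  xbar_p <- (X %*% t(signs)) / n                    # genes x perms
  s_p <- sqrt(pmax(rs2 - n * xbar_p^2, 0) / (n - 1)) / sqrt(n)
  d_p <- xbar_p / (s_p + s0)
  perm_d <- apply(d_p, 2, sort)                     # genes x perms, sorted
  list(perm_d = t(perm_d), signs = t(signs),
       mode = if (exhaustive) "exhaustive" else "sampled")
}

# asymmetric SAM cut thresholds and q-values from a permutation ensemble
#' Permutation q-values for one-class SAM
#'
#' Implements the SAM thresholding rule: order the observed d statistics
#' and compare them with the expected order statistics (the mean of the
#' sorted permuted d).  For every threshold Delta in the grid of
#' distinct |d - dbar| values, asymmetric cut points are found by
#' walking up (down) from the origin of the expected statistics to the
#' first gene whose deviation reaches Delta; genes beyond the cuts are
#' called.  The false-positive count is the median over permutations of
#' permuted d values beyond the cuts, scaled by the null proportion
#' pi0 = min(1, #\{d in \[q25, q75\] of pooled permuted d\} / (m/2)), and the
#' FDR at Delta is pi0 * medFP / #called.  A gene's q-value is the
#' minimum FDR over all Delta at which it is called, made monotone in
#' |d| and clipped to \[0, 1\].
#'
#' @param d Observed d statistics.
#' @param perm Result of [sign_flip_permutations()].
#' @return List with `q` (per gene), `pi0`, and the threshold table
#'   (`delta`, `cutlow`, `cutup`, `n_called`, `med_fp`, `fdr`).
#' @export
sam_qvalues <- function(d, perm) {
  m <- length(d)
  P <- nrow(perm$perm_d)
  ord <- order(d)
  ds <- d[ord]
  dbar <- colMeans(perm$perm_d)
  dev <- ds - dbar

  delta <- sort(unique(abs(dev)))
  # origin of the walks: the first non-negative / last non-positive expected
  # order statistic (a symmetric choice; dbar is antisymmetric under the
  # exhaustive sign-flip ensemble)
  i_up <- if (any(dbar >= 0)) which.max(dbar >= 0) else m + 1L
  i_dn <- if (any(dbar <= 0)) max(which(dbar <= 0)) else 0L

  # walking up from the origin: first index with dev >= Delta
  cutup <- rep(Inf, length(delta))
  if (i_up <= m) {
    up_idx <- i_up:m
    cm_up <- cummax(dev[up_idx])
    ju <- findInterval(delta, cm_up, left.open = TRUE) + 1L   # in up_idx
    hit <- ju <= length(up_idx)
    cutup[hit] <- ds[up_idx[ju[hit]]]
  }
  # walking down: first index (descending) with -dev >= Delta
  cutlow <- rep(-Inf, length(delta))
  if (i_dn >= 1) {
    down_idx <- i_dn:1
    cm_dn <- cummax(-dev[down_idx])
    jd <- findInterval(delta, cm_dn, left.open = TRUE) + 1L
    hit <- jd <= length(down_idx)
    cutlow[hit] <- ds[down_idx[jd[hit]]]
  }

  # counts of observed genes called at each Delta (call by value; a gene
  # exactly at the cut is called)
  n_up <- m - findInterval(cutup, ds, left.open = TRUE)
  n_dn <- findInterval(cutlow, ds)
  n_called <- n_up + n_dn

  # median permutation false positives beyond the cuts
  fp <- matrix(0, P, length(delta))
  for (p in seq_len(P)) {
    row <- perm$perm_d[p, ]
    fp[p, ] <- (m - findInterval(cutup, row, left.open = TRUE)) +
      findInterval(cutlow, row)
  }
  med_fp <- apply(fp, 2, stats::median)

  pooled <- as.vector(perm$perm_d)
  qs <- stats::quantile(pooled, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= qs[1] & d <= qs[2]) / (0.5 * m))

  fdr <- ifelse(n_called > 0, pmin(1, pi0 * med_fp / n_called), NA_real_)
  prefix_min <- cummin(ifelse(is.na(fdr), Inf, fdr))

  # cutup is non-decreasing and cutlow non-increasing in Delta, so the set
  # of Deltas calling a gene is a prefix of the grid
  t_up <- findInterval(d, cutup)                  # last Delta calling gene up
  t_dn <- findInterval(-d, -cutlow)               # last Delta calling gene down
  q <- rep(1, m)
  has_up <- t_up > 0
  q[has_up] <- pmin(q[has_up], prefix_min[t_up[has_up]])
  has_dn <- t_dn > 0
  q[has_dn] <- pmin(q[has_dn], prefix_min[t_dn[has_dn]])
  q[!is.finite(q)] <- 1

  # monotone repair: each gene takes the minimum estimated FDR over itself
  # and every weaker (smaller |d|) gene, so q never increases with |d|
  o <- order(abs(d))
  q[o] <- cummin(q[o])
  q <- pmin(pmax(q, 0), 1)

  list(q = q, pi0 = pi0,
       thresholds = data.frame(delta = delta, cutlow = cutlow, cutup = cutup,
                               n_called = n_called, med_fp = med_fp,
                               fdr = fdr))
}

#' Signed fold change from a mean log2 ratio
#'
#' Uses the reporting convention where decreases carry a minus sign:
#' `2^xbar` for `xbar >= 0` and `-2^(-xbar)` otherwise, so a halving is
#' written -2.0 and the magnitude is always at least 1.
#'
#' @param xbar Mean log2 ratio(s).
#' @param digits Decimal places used when `rounded = TRUE` (result
#'   tables print one decimal).
#' @param rounded Round for reporting?
#' @return Signed fold change(s).
#' @examples
#' signed_fold_change(c(0, 1, -1))
#' signed_fold_change(-0.766, rounded = TRUE)   # -1.7
#' @export
signed_fold_change <- function(xbar, digits = 1, rounded = FALSE) {
  fc <- ifelse(xbar >= 0, 2^xbar, -2^(-xbar))
  if (rounded) round(fc, digits) else fc
}

#' One-class SAM for one treatment
#'
#' Computes per-gene d statistics with an automatically selected fudge
#' factor, builds the sign-flip permutation ensemble, and derives
#' q-values and signed fold changes.
#'
#' @param ratios A `ratio_matrix` (or plain genes x arrays matrix).
#' @param treatment Treatment id selecting columns (ignored for plain
#'   matrices).
#' @param config A [sam_config()].
#' @return A `sam_result`: `table` (gene, xbar, s, d, q, fold_change),
#'   `s0`, `pi0`, permutation metadata and the treatment/tissue labels.
#' @examples
#' X <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), NULL))
#' fit <- sam(X)
#' head(fit$table)
#' @export
sam <- function(ratios, treatment = NULL, config = sam_config()) {
  if (inherits(ratios, "ratio_matrix")) {
    sel <- if (is.null(treatment)) rep(TRUE, ncol(ratios$ratios))
           else ratios$arrays$treatment == treatment
    if (!any(sel)) stopf("no arrays for treatment '%s'", treatment)
    tissue <- unique(ratios$arrays$tissue[sel])
    X <- ratios$ratios[, sel, drop = FALSE]
  } else {
    X <- as.matrix(ratios)
    tissue <- NA_character_
  }
  if (ncol(X) < 2) stopf("need at least 2 arrays")
  if (is.null(rownames(X))) rownames(X) <- sprintf("g%05d", seq_len(nrow(X)))
  st <- row_stats(X)
  s0 <- choose_s0(st$s, st$xbar, config$s0_grid)
  d <- st$xbar / (st$s + s0)
  perm <- sign_flip_permutations(X, s0, config)
  qv <- sam_qvalues(d, perm)
  tab <- data.frame(gene_id = rownames(X), xbar = st$xbar, s = st$s, d = d,
                    q = qv$q, fold_change = signed_fold_change(st$xbar),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, s0 = s0, pi0 = qv$pi0,
                 thresholds = qv$thresholds, n_arrays = ncol(X),
                 n_permutations = nrow(perm$perm_d), mode = perm$mode,
                 treatment = treatment %||% NA_character_, tissue = tissue,
                 q_threshold = config$q_threshold),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  called <- sum(x$table$q < x$q_threshold)
  cat(sprintf("One-class SAM (%s): %d genes, n = %d arrays, %d %s sign flips\n",
              x$treatment, nrow(x$table), x$n_arrays, x$n_permutations,
              x$mode))
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, %d genes at q < %g\n",
              x$s0, x$pi0, called, x$q_threshold))
  invisible(x)
}
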