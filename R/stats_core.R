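#' Multiple-testing adjustment
#'
#' Adjusts a vector of p-values by the Benjamini-Hochberg step-up procedure
#' or the Bonferroni method. The number of tests `m` may exceed the number of
#' p-values supplied (e.g. when only a pre-filtered subset is passed in).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method `"bh"` (step-up false discovery rate) or `"bonferroni"`.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Numeric vector of adjusted p-values, same length as `p`, in \[0, 1\].
#'   BH-adjusted values are monotone non-decreasing in the order of the raw
#'   p-values; Bonferroni returns `pmin(1, p * m)`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni"), m = length(p)) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and contain no NA")
  }
  if (m < length(p)) stop("m must be >= length(p)")
  stats::p.adjust(p, method = switch(method, bh = "BH", bonferroni = "bonferroni"),
                  n = m)
}

## Exact distribution of the signed-rank statistic (sum of positive ranks)
## with midranks: dynamic programming over the generating function
## prod_i (1 + x^(2*r_i)) / 2^n on doubled ranks so ties stay integral.
signed_rank_exact_p <- function(r, w_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[k+1] = #sign vectors with doubled statistic k
  f[1L] <- 1
  for (ri in r2) {
    g <- f
    idx <- (ri + 1L):(total + 1L)
    g[idx] <- g[idx] + f[idx - ri]
    f <- g
  }
  f <- f / sum(f)
  w2 <- round(2 * w_obs)
  lo <- sum(f[seq_len(total + 1L) - 1L <= w2])         # P(W <= w)
  hi <- sum(f[seq_len(total + 1L) - 1L >= w2])         # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test that paired differences `y - x` are symmetric about zero.
#' Zero differences are dropped before ranking (classical Wilcoxon
#' convention); if all differences are zero the p-value is 1 by convention.
#' The exact tie-aware null distribution is enumerated by dynamic programming
#' when at most `exact_max` non-zero differences remain; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @param exact_max Largest number of non-zero differences for which the exact
#'   null distribution is enumerated (default 25).
#' @param drop_zeros Drop zero differences before ranking (default `TRUE`).
#' @return List with `statistic` (sum of ranks of positive differences) and
#'   `p` (two-sided).
#' @export
paired_signed_rank <- function(x, y, exact_max = 25L, drop_zeros = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  if (drop_zeros) d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p = p)
}

## Exact rank-sum p with ties: enumerate all choose(N, n_a) assignments of the
## pooled midranks to group a. Only used when the enumeration is small.
rank_sum_enum_p <- function(r_all, n_a, u_obs) {
  idx <- utils::combn(length(r_all), n_a)
  ra <- colSums(matrix(r_all[idx], nrow = n_a))
  u <- ra - n_a * (n_a + 1) / 2
  mu <- n_a * (length(r_all) - n_a) / 2
  eps <- 1e-9
  mean(abs(u - mu) >= abs(u_obs - mu) - eps)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test that two independent samples come from the same
#' distribution. Exact when `length(a) * length(b) <= exact_max` (via the
#' closed-form null distribution without ties, or full enumeration of rank
#' splits when ties are present and the enumeration is small); otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Largest `n*m` for which the exact distribution is used.
#' @return List with `statistic` (Mann-Whitney U for the first sample) and
#'   `p` (two-sided).
#' @export
rank_sum <- function(a, b, exact_max = 400L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(r) > 0L
  if (n * m <= exact_max && !has_ties) {
    mu <- n * m / 2
    lo <- stats::pwilcox(u, n, m)
    hi <- 1 - stats::pwilcox(u - 1, n, m)
    p <- min(1, 2 * min(lo, hi))
  } else if (n * m <= exact_max && choose(n + m, n) <= 2e5) {
    p <- rank_sum_enum_p(r, n, u)
  } else {
    mu <- n * m / 2
    N <- n + m
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p = p)
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric-exact test of association in a 2x2 contingency table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"` or `"greater"` (odds ratio > 1 for the
#'   first row/column cell).
#' @return The exact p-value.
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  stats::fisher.test(table, alternative = switch(alternative,
    two_sided = "two.sided", greater = "greater"))$p.value
}
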