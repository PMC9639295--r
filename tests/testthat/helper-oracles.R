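## Independent brute-force oracles. These re-derive expected values from first
## principles and deliberately share no code with the package implementation.

## BH step-up, literal definition: adj_(i) = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  po <- p[o]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k)) adj[i] <- min(m * po[i:k] / seq(i, k))
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

## exact signed-rank two-sided p by full enumeration of sign vectors
signed_rank_brute <- function(x, y) {
  d <- (y - x)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

## exact rank-sum two-sided p by enumeration of all group splits
rank_sum_brute <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  idx <- utils::combn(n + m, n)
  u_all <- apply(idx, 2, function(i) sum(r[i])) - n * (n + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

## hypergeometric tail (greater) by direct summation
fisher_greater_oracle <- function(tab) {
  a <- tab[1, 1]
  k <- sum(tab[1, ]); K <- sum(tab[, 1]); N <- sum(tab)
  sum(vapply(a:min(k, K), function(x) {
    choose(K, x) * choose(N - K, k - x) / choose(N, k)
  }, numeric(1)))
}

## per-pair OLS with covariates: coefficient, t and p for the dosage term
ols_pair_oracle <- function(y, d, covariates) {
  X <- cbind(1, covariates, d)
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * xtx_inv[ncol(X), ncol(X)])
  beta <- unname(fit$coefficients[ncol(X)])
  t <- beta / se
  list(beta = beta, t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

## closed-form oracle for the balanced paired interaction model with
## condition-invariant covariates: OLS of per-genotype differences
diff_ols_oracle <- function(y_control, y_heat, d, covariates) {
  dy <- y_heat - y_control
  X <- cbind(1, covariates, d)
  fit <- stats::lm.fit(X, dy)
  df <- length(dy) - ncol(X)
  se <- sqrt(sum(fit$residuals^2) / df *
               chol2inv(chol(crossprod(X)))[ncol(X), ncol(X)])
  beta <- unname(fit$coefficients[ncol(X)])
  t <- beta / se
  list(beta = beta, se = se, df = df, t = t, p = 2 * stats::pt(-abs(t), df))
}

## independent implementation of the windowed greedy LD pruning rule:
## plain loops, scalar r^2, first violating pair in (earlier, later) scan order
ld_prune_oracle <- function(dosage, maf, pos, window = 50, step = 5,
                            r2_max = 0.99) {
  nv <- length(pos)
  keep <- rep(TRUE, nv)
  start <- 1
  repeat {
    win <- start:min(start + window - 1, nv)
    repeat {
      act <- win[keep[win]]
      if (length(act) < 2) break
      drop <- NULL
      for (jj in seq_along(act)[-length(act)]) {
        for (ii in (jj + 1):length(act)) {
          v1 <- dosage[, act[jj]]; v2 <- dosage[, act[ii]]
          if (stats::var(v1) == 0 || stats::var(v2) == 0) {
            r2 <- 1
          } else r2 <- stats::cor(v1, v2)^2
          if (r2 > r2_max) {
            pair <- c(act[jj], act[ii])
            drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
            else if (maf[pair[2]] < maf[pair[1]]) pair[2]
            else pair[which.max(pos[pair])]
            break
          }
        }
        if (!is.null(drop)) break
      }
      if (is.null(drop)) break
      keep[drop] <- FALSE
    }
    if (start + window - 1 >= nv) break
    start <- start + step
  }
  which(keep)
}
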