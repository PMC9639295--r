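## Shared fixtures. The default full-scale cohort and its pipeline report are
## expensive (~1 min), so they are built once and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- simulate_cohort(sim_config(seed = 20260101))
  }
  .fixture_cache$cohort
}

default_report <- function() {
  if (is.null(.fixture_cache$report)) {
    .fixture_cache$report <- run_pipeline(default_cohort(), seed = 1)
  }
  .fixture_cache$report
}

## a small cohort for cheap structural tests
small_cohort <- function(seed = 7, ...) {
  key <- paste0("small_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_cohort(
      sim_config(n_samples = 60, n_variants = 1500, n_genes = 300,
                 chrom_length_bp = 2e6, seed = seed, ...))
  }
  .fixture_cache[[key]]
}

## balanced paired interaction data with known truth for LMM tests
make_lmm_data <- function(n = 100, k = 5, theta = 0, cond_varying = FALSE,
                          sigma_g = 0.5, sigma_e = 0.7) {
  d <- rep(sample(c(0, 2), n, TRUE, c(0.7, 0.3)), 2)
  cond <- rep(c(0, 1), each = n)
  gid <- rep(sprintf("g%04d", seq_len(n)), 2)
  cov1 <- matrix(stats::rnorm((if (cond_varying) 2 * n else n) * k), ncol = k)
  cov <- if (cond_varying) cov1 else rbind(cov1, cov1)
  u <- stats::rnorm(n, 0, sigma_g)
  y <- 0.3 * d + 0.5 * cond + drop(cov %*% stats::rnorm(k, 0, 0.3)) +
    theta * d * cond + rep(u, 2) + stats::rnorm(2 * n, 0, sigma_e)
  list(y = y, d = d, cond = cond, cov = cov, gid = gid, n = n)
}
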