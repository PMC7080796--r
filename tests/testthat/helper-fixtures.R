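# Shared fixtures and independent oracles for the test suite.

# small cohort reused by several module tests (built once per run)
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_cohort(
      sim_config(n_samples = 80L, n_genes = 400L, seed = 11L))
  }
  .fixture_env$small
}

small_model <- function() {
  if (is.null(.fixture_env$small_model)) {
    sim <- small_sim()
    .fixture_env$small_model <- fit_bmr(sim$muts, sim$annot, sim$covariates)
  }
  .fixture_env$small_model
}

# study-condition cohort for the acceptance properties: 2000 genes,
# 300 samples, alpha_true = 10, with a fixed 70/30 train/test split
acc_fixture <- function() {
  if (!is.null(.fixture_env$acc)) return(.fixture_env$acc)
  sim <- simulate_cohort(sim_config(seed = 42L))
  samples <- sim$truth$samples$sample_id
  set.seed(4242L)
  train <- sort(sample(samples, floor(0.7 * length(samples))))
  test <- setdiff(samples, train)
  muts_train <- sim$muts[sim$muts$sample_id %in% train, , drop = FALSE]
  muts_test <- sim$muts[sim$muts$sample_id %in% test, , drop = FALSE]
  model_full <- fit_bmr(sim$muts, sim$annot, sim$covariates)
  model_train <- fit_bmr(muts_train, sim$annot, sim$covariates)
  rule <- select_included_genes(driver_statistic(model_train), 0.99)
  .fixture_env$acc <- list(sim = sim, train = train, test = test,
                           muts_train = muts_train, muts_test = muts_test,
                           model_full = model_full,
                           model_train = model_train, rule = rule)
  .fixture_env$acc
}

truth_of <- function(sim, ids) {
  tr <- sim$truth$samples
  tr[match(ids, tr$sample_id), , drop = FALSE]
}

# ---- independent oracles -----------------------------------------------------

# two-sided Fisher exact p by exhaustive enumeration over all 2x2 tables
# with the observed margins (sum of probabilities <= observed, with the
# conventional 1e-7 relative tolerance)
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# NB log-likelihood of the sample background rate, for grid-search oracles
nb_rate_loglik <- function(m, x, lambda_e, alpha) {
  sum(dnbinom(x, size = alpha, mu = m * lambda_e, log = TRUE))
}

# posterior mean of the gene rate by numeric integration (Gamma prior of
# mean lambda_glm / shape alpha, Poisson likelihood with exposure E)
posterior_mean_numeric <- function(alpha, y, E, lambda_glm) {
  shape <- alpha + y
  rate <- alpha / lambda_glm + E
  stats::integrate(function(x) x * stats::dgamma(x, shape, rate = rate),
                   0, Inf, rel.tol = 1e-12)$value
}

# plain rank-based Spearman for cross-checking
spearman_manual <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

maf_lines <- function(muts) {
  f <- tempfile(fileext = ".maf")
  write_maf(muts, f)
  on.exit(unlink(f))
  readLines(f)
}
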