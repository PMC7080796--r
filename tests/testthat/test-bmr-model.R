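test_that("sample background rates are synonymous counts over exposure", {
  sim <- small_sim()
  step1 <- estimate_context_rates(sim$muts, sim$annot)
  syn <- sim$muts[sim$muts$variant_class == "synonymous", ]
  cnt <- table(factor(syn$sample_id, levels = names(step1$m)))
  expect_equal(unname(step1$m),
               as.numeric(cnt) / sum(step1$e_syn))
  # exposure-weighted mean of the context rates is exactly 1
  A <- colSums(sim$annot$counts[, , "synonymous"])
  expect_equal(sum(step1$r * A) / sum(A), 1)
  expect_true(all(step1$r > 0))
})

test_that("duplicating every mutation doubles m and leaves r unchanged", {
  sim <- small_sim()
  s1 <- estimate_context_rates(sim$muts, sim$annot)
  doubled <- rbind(sim$muts, sim$muts)
  class(doubled) <- class(sim$muts)
  s2 <- estimate_context_rates(doubled, sim$annot)
  # exact up to the zero-count pseudocount, which does not rescale
  expect_equal(s2$r, s1$r, tolerance = 1e-3)
  expect_equal(s2$m, 2 * s1$m, tolerance = 1e-3)
})

test_that("flat-rate simulations recover context rates near 1", {
  sim <- simulate_cohort(sim_config(n_samples = 150L, n_genes = 500L,
                                    context_sdlog = 0, seed = 31L))
  step1 <- estimate_context_rates(sim$muts, sim$annot)
  # per-context Monte-Carlo bound: 4 / sqrt(expected count)
  A <- colSums(sim$annot$counts[, , "synonymous"])
  n_syn <- sum(sim$muts$variant_class == "synonymous")
  expected_c <- n_syn * A / sum(A)
  expect_true(all(abs(step1$r - 1) < pmax(4 / sqrt(expected_c), 0.02)))
  # mean absolute z-score ~ E|N(0,1)| = 0.80, no systematic miscalibration
  expect_lt(mean(abs(step1$r - 1) * sqrt(expected_c)), 1.2)
})

test_that("context rate estimates track the simulated truth", {
  fx <- acc_fixture()
  expect_gt(cor(fx$model_full$r, fx$sim$truth$r), 0.95)
})

test_that("the covariate GLM recovers simulated coefficients", {
  sim <- small_sim()
  model <- small_model()
  beta_true <- sim$truth$beta
  z <- abs(model$beta - beta_true) / model$beta_se
  expect_true(all(z < 3))
  # permuting gene order leaves estimates unchanged
  step1 <- estimate_context_rates(sim$muts, sim$annot)
  y <- model$obs_syn
  E <- sum(step1$m) * step1$e_syn
  cov <- impute_covariates(sim$covariates, sim$annot$genes)
  perm <- sample(length(y))
  f1 <- fit_covariate_glm(y, cov, E)
  f2 <- fit_covariate_glm(y[perm], cov, E[perm])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("constant covariates reduce the GLM to its intercept", {
  set.seed(5)
  G <- 200L
  E <- runif(G, 1e4, 1e5)
  names(E) <- paste0("g", seq_len(G))
  y <- rpois(G, 2e-4 * E)
  names(y) <- names(E)
  cov <- data.frame(expression = rep(1, G), replication_timing = rep(0, G),
                    row.names = names(E))
  # constant covariates are collinear with the intercept by design
  expect_error(fit_covariate_glm(y, cov, E), "collinear")
})

test_that("dispersion estimation recovers alpha and flags the Poisson limit", {
  set.seed(8)
  mu <- rep(20, 5000)
  y_nb <- rnbinom(5000, size = 10, mu = mu)
  a <- estimate_dispersion(y_nb, mu)
  expect_lt(abs(a - 10) / 10, 0.25)
  expect_false(attr(a, "poisson_limit"))

  y_pois <- rpois(5000, mu)
  a2 <- estimate_dispersion(y_pois, mu)
  expect_true(attr(a2, "poisson_limit") || a2 > 1e3)

  # counts exactly at their means: no over-dispersion at all
  a3 <- estimate_dispersion(rep(20L, 100), rep(20, 100))
  expect_true(attr(a3, "poisson_limit"))

  expect_error(estimate_dispersion(rep(0L, 100), rep(1, 100)), "all counts")
})

test_that("the conjugate consolidation matches its closed form and limits", {
  expect_equal(consolidate_bayes(20, 10, 1, 2), 22 / 12)
  # no data returns the prior mean
  expect_equal(consolidate_bayes(0, 0, 1.7, 3), 1.7)
  # data dominate as exposure grows; prior dominates as alpha grows
  expect_equal(consolidate_bayes(3e8, 1e8, 1, 2), 3, tolerance = 1e-7)
  expect_equal(consolidate_bayes(5, 10, 2, 1e12), 2, tolerance = 1e-10)
})

test_that("shrinkage: consolidated rates beat raw per-gene rates in MSE", {
  sim <- small_sim()
  model <- small_model()
  lam_true <- sim$truth$genes$lambda[match(model$genes,
                                           sim$truth$genes$gene)]
  ok <- !is.na(model$lambda_raw)
  mse_star <- mean((model$lambda_star[ok] - lam_true[ok])^2)
  mse_raw <- mean((model$lambda_raw[ok] - lam_true[ok])^2)
  expect_lte(mse_star, mse_raw)
  # consolidated estimate lies between the GLM and raw estimates
  lo <- pmin(model$lambda_glm[ok], model$lambda_raw[ok]) - 1e-12
  hi <- pmax(model$lambda_glm[ok], model$lambda_raw[ok]) + 1e-12
  expect_true(all(model$lambda_star[ok] >= lo & model$lambda_star[ok] <= hi))
})

test_that("expected counts are the rate product and are calibrated", {
  model <- structure(list(
    m = c(S1 = 1e-6), lambda_star = c(g1 = 2), e_syn = c(g1 = 1e4),
    e_nonsyn = c(g1 = 3e4), genes = "g1", alpha = 10), class = "BMRModel")
  expect_equal(unname(expected_counts(model, "synonymous")), 0.02)
  expect_error(expected_counts(model, samples = "nope"), "unknown sample")

  # total expected synonymous ~= total observed on the training cohort
  m <- small_model()
  expect_equal(sum(expected_counts(m, "synonymous")), sum(m$obs_syn),
               tolerance = 0.01)
})

test_that("driver statistics match tail-probability oracles", {
  mk <- function(y_non, mu_non, alpha) {
    structure(list(
      m = c(S1 = 1), lambda_star = c(g1 = 1), e_syn = c(g1 = 1),
      e_nonsyn = c(g1 = mu_non), genes = "g1", alpha = alpha,
      obs_syn = c(g1 = 0L), obs_nonsyn = c(g1 = y_non)), class = "BMRModel")
  }
  expect_equal(driver_statistic(mk(0L, 1, 10))$driver_pvalue, 1)
  # Poisson limit tail: P(Y >= 5) with mean 1
  p <- driver_statistic(mk(5L, 1, 1e9))$driver_pvalue
  expect_equal(p, 1 - ppois(4, 1), tolerance = 1e-6)
})

test_that("planted drivers rank on top and are recovered by q-value", {
  sim <- simulate_cohort(sim_config(n_samples = 100L, n_genes = 600L,
                                    n_drivers = 20L, driver_fold = 5,
                                    seed = 13L))
  model <- fit_bmr(sim$muts, sim$annot, sim$covariates)
  gs <- driver_statistic(model)
  is_driver <- sim$truth$genes$driver[match(gs$gene, sim$truth$genes$gene)]
  # AUC of driver recovery from q-values
  r <- rank(gs$driver_qvalue)
  auc <- 1 - (sum(r[is_driver]) - sum(is_driver) * (sum(is_driver) + 1) / 2) /
    (sum(is_driver) * sum(!is_driver))
  expect_gt(auc, 0.9)
  # q-values are monotone in p-values (BH property)
  ord <- order(gs$driver_pvalue)
  expect_true(all(diff(gs$driver_qvalue[ord]) > -1e-12))
  # drivers dominate the observed/expected ranking
  expect_gt(mean(rank(-gs$obs_exp_ratio)[is_driver] <= 40), 0.8)
})

test_that("model serialization round-trips bit-exactly", {
  model <- small_model()
  dir <- withr::local_tempdir()
  write_bmr_model(model, dir)
  back <- read_bmr_model(dir)
  for (fld in c("r", "m", "alpha", "beta", "lambda_glm", "lambda_star",
                "e_syn", "e_nonsyn", "exome_mb")) {
    expect_identical(unname(back[[fld]]), unname(model[[fld]]),
                     label = fld)
  }
  expect_identical(back$obs_syn, model$obs_syn)
})
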