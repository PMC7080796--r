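test_that("counting TMB is mutations over megabases", {
  mk <- function(n_non, n_syn = 0) {
    cls <- c(rep("nonsynonymous", n_non), rep("synonymous", n_syn))
    if (!length(cls)) {
      return(mutation_table(character(0), character(0), character(0),
                            integer(0), character(0), character(0),
                            character(0)))
    }
    mutation_table("S", "g", "c", seq_along(cls), "C", "T", cls)
  }
  expect_equal(counting_tmb(mk(10), 1)$tmb, 10)
  expect_equal(counting_tmb(mk(0), 1)$tmb, 0)
  expect_equal(counting_tmb(mk(37, 12), 0.8)$tmb, 46.25)
  expect_equal(counting_tmb(mk(37, 12), 0.8,
                            include = c("nonsynonymous", "synonymous"))$tmb,
               61.25)
  expect_error(counting_tmb(mk(1), 0), "positive")
})

test_that("gene inclusion takes the bottom fraction by observed/expected", {
  gs <- data.frame(gene = sprintf("g%04d", 1:2000),
                   obs_exp_ratio = runif(2000))
  expect_length(select_included_genes(gs, 1)$included_genes, 2000L)
  expect_length(select_included_genes(gs, 0)$included_genes, 0L)
  rule <- select_included_genes(gs, 0.9995)
  expect_length(rule$included_genes, 1999L)
  excluded <- setdiff(gs$gene, rule$included_genes)
  expect_equal(excluded, gs$gene[which.max(gs$obs_exp_ratio)])
  expect_error(select_included_genes(gs, 1.2), "fraction")
})

# a minimal hand-built model/annotation pair for MLE unit tests
toy_mle_setup <- function(lambda = c(2, 0.5, 1, 1.5, 1),
                          e_syn = c(2e3, 5e3, 1e3, 4e3, 3e3),
                          e_nonsyn = 3 * e_syn, alpha = 10) {
  G <- length(lambda)
  genes <- paste0("g", seq_len(G))
  ctx <- trinuc_contexts()
  counts <- array(0, dim = c(G, 96, 3),
                  dimnames = list(genes, ctx,
                                  c("synonymous", "nonsynonymous", "other")))
  counts[, 1, "synonymous"] <- e_syn      # all exposure in context 1, rate 1
  counts[, 1, "nonsynonymous"] <- e_nonsyn
  annot <- exome_annotation(counts)
  r <- setNames(rep(1, 96), ctx)
  model <- structure(list(
    r = r, m = c(TRAIN = 1e-6), alpha = alpha,
    lambda_star = setNames(lambda, genes),
    e_syn = setNames(e_syn, genes), e_nonsyn = setNames(e_nonsyn, genes),
    genes = genes, exome_mb = sum(e_syn + e_nonsyn) / 3 / 1e6),
    class = "BMRModel")
  list(model = model, annot = annot, genes = genes)
}

toy_muts <- function(counts_per_gene, genes, class = "synonymous") {
  g <- rep(genes, counts_per_gene)
  if (!length(g)) {
    return(mutation_table(character(0), character(0), character(0),
                          integer(0), character(0), character(0),
                          character(0)))
  }
  mutation_table("S1", g, "c", seq_along(g), "C", "T", class)
}

test_that("the Poisson-limit MLE has the closed form x / (lambda e)", {
  setup <- toy_mle_setup(lambda = 1, e_syn = 1e4, e_nonsyn = 0, alpha = 1e8)
  rule <- structure(list(fraction = 0, included_genes = character(0)),
                    class = "GeneInclusionRule")
  est <- predict_tmb_mle(toy_muts(7L, setup$genes), setup$model, setup$annot,
                         rule, sample_id = "S1")
  expect_equal(est$m_hat, 7 / 1e4, tolerance = 1e-6)
  expect_equal(est$flag, "")
})

test_that("the MLE matches a fine grid search of the NB likelihood", {
  setup <- toy_mle_setup()
  rule <- structure(list(fraction = 1, included_genes = setup$genes),
                    class = "GeneInclusionRule")
  set.seed(99)
  x <- rpois(5, 20)
  muts <- toy_muts(x, setup$genes)
  est <- predict_tmb_mle(muts, setup$model, setup$annot, rule,
                         sample_id = "S1")
  lambda_e <- setup$model$lambda_star *
    (setup$model$e_syn + setup$model$e_nonsyn)
  grid <- exp(seq(log(1e-10), log(1e-2), length.out = 10000))
  ll <- vapply(grid, nb_rate_loglik, numeric(1), x = x,
               lambda_e = lambda_e, alpha = setup$model$alpha)
  m_grid <- grid[which.max(ll)]
  # within grid resolution (log-spacing step)
  expect_lt(abs(log(est$m_hat) - log(m_grid)),
            diff(log(grid[1:2])) * 1.5)
  expect_equal(est$loglik, nb_rate_loglik(est$m_hat, x, lambda_e,
                                          setup$model$alpha))
})

test_that("zero mutations put the MLE at the lower bound with a flag", {
  setup <- toy_mle_setup()
  rule <- structure(list(fraction = 1, included_genes = setup$genes),
                    class = "GeneInclusionRule")
  est <- predict_tmb_mle(toy_muts(integer(0), character(0)), setup$model,
                         setup$annot, rule, sample_id = "S1")
  expect_equal(est$m_hat, 1e-10)
  expect_equal(est$flag, "lower_boundary")
  expect_lt(est$tmb, 0.01)
})

test_that("the MLE is invariant to gene order", {
  setup <- toy_mle_setup()
  rule <- structure(list(fraction = 1, included_genes = setup$genes),
                    class = "GeneInclusionRule")
  x <- c(5L, 3L, 9L, 1L, 4L)
  m1 <- predict_tmb_mle(toy_muts(x, setup$genes), setup$model, setup$annot,
                        rule)$m_hat
  perm <- c(3, 1, 5, 2, 4)
  m2 <- predict_tmb_mle(toy_muts(x[perm], setup$genes[perm]), setup$model,
                        setup$annot, rule)$m_hat
  expect_equal(m1, m2)
})

test_that("doubling the true rate doubles the estimate (median over draws)", {
  setup <- toy_mle_setup(lambda = rep(1, 200), e_syn = rep(5e3, 200),
                         alpha = 10)
  rule <- structure(list(fraction = 1, included_genes = setup$genes),
                    class = "GeneInclusionRule")
  lambda_e <- setup$model$e_syn + setup$model$e_nonsyn
  set.seed(3)
  ratios <- replicate(50, {
    m0 <- 5e-6
    x1 <- rnbinom(200, size = 10, mu = m0 * lambda_e)
    x2 <- rnbinom(200, size = 10, mu = 2 * m0 * lambda_e)
    f1 <- predict_tmb_mle(toy_muts(x1, setup$genes), setup$model,
                          setup$annot, rule)$m_hat
    f2 <- predict_tmb_mle(toy_muts(x2, setup$genes), setup$model,
                          setup$annot, rule)$m_hat
    f2 / f1
  })
  expect_lt(abs(median(ratios) / 2 - 1), 0.05)
})

test_that("cohort prediction emits all three methods per sample", {
  setup <- toy_mle_setup()
  rule <- structure(list(fraction = 1, included_genes = setup$genes),
                    class = "GeneInclusionRule")
  muts <- toy_muts(c(2L, 1L, 0L, 3L, 1L), setup$genes)
  out <- predict_cohort(muts, setup$model, setup$annot, rule)
  expect_equal(nrow(out), 3L)
  expect_setequal(out$method, c("counting", "counting_filtered", "ectmb"))
  # empty hotspot list: filtered counting equals plain counting
  expect_equal(out$tmb[out$method == "counting"],
               out$tmb[out$method == "counting_filtered"])
})

test_that("per-cancer-type inclusion defaults follow the mutagen split", {
  expect_equal(default_inclusion_fraction(c("LUAD", "COAD")), c(1, 0.9995))
})
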