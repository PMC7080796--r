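test_that("agreement on identical vectors is the exact identity report", {
  x <- c(1, 5, 9, 14, 22, 3)
  a <- agreement_metrics(x, x)
  expect_equal(a$spearman_r, 1)
  expect_equal(a$mae, 0)
  expect_equal(a$rmse, 0)
  expect_equal(a$slope, 1)
  expect_equal(a$sigma, 0)
  expect_equal(a$r_squared, 1)
})

test_that("agreement metrics follow their definitions on toy data", {
  ref <- c(1, 2, 3, 4)
  a <- agreement_metrics(ref, 2 * ref, cap = NULL)
  expect_equal(a$spearman_r, 1)
  expect_equal(a$slope, 2)

  # hand rank computation: rank diffs (1,-1,1,-1)(-1,1,-1,1), sum d^2 = 4,
  # so 1 - 6*4 / (4*15) = 0.6
  a2 <- agreement_metrics(c(1, 2, 3, 4), c(2, 1, 4, 3), cap = NULL)
  expect_equal(a2$spearman_r, 0.6)
  expect_equal(a2$spearman_r,
               spearman_manual(c(1, 2, 3, 4), c(2, 1, 4, 3)))

  # Spearman is invariant under strictly increasing transforms
  set.seed(12)
  x <- runif(30, 0, 35); y <- runif(30, 0, 35)
  expect_equal(agreement_metrics(x, y)$spearman_r,
               agreement_metrics(x, exp(y / 10))$spearman_r)

  # cap filter drops pairs with reference above 40
  ref2 <- c(1, 2, 3, 100)
  a3 <- agreement_metrics(ref2, ref2 + 1)
  expect_equal(a3$n, 3L)

  # constant reference flags Spearman as missing
  a4 <- agreement_metrics(rep(5, 5), 1:5)
  expect_true(is.na(a4$spearman_r))
  expect_equal(a4$flag, "constant_reference")

  expect_error(agreement_metrics(1:2, 1:2), "fewer than 3")
})

test_that("Bland-Altman analysis matches hand arithmetic", {
  x <- c(3, 8, 15, 21, 30)
  b0 <- bland_altman(x, x)
  expect_equal(b0$bias, 0)
  expect_equal(b0$loa_lower, 0)
  expect_equal(b0$loa_upper, 0)

  b1 <- bland_altman(x, x + 5)
  expect_equal(b1$bias, 5)
  expect_equal(b1$sd_diff, 0)
  expect_equal(unname(b1$loa_lower), 5)

  # d = (1, -1, 2, 0, 3): bias 1, sd = sqrt(2.5)
  ref <- c(10, 10, 10, 10, 10)
  pred <- ref + c(1, -1, 2, 0, 3)
  b2 <- bland_altman(ref, pred)
  expect_equal(b2$bias, 1)
  expect_equal(b2$sd_diff, sqrt(2.5), tolerance = 1e-12)
  expect_equal(b2$loa_lower, 1 - 1.96 * sqrt(2.5), tolerance = 1e-12)
  expect_equal(b2$loa_upper, 1 + 1.96 * sqrt(2.5), tolerance = 1e-12)
  expect_equal(round(b2$loa_lower, 3), -2.099)
  expect_equal(round(b2$loa_upper, 3), 4.099)

  # bias equals mean(pred) - mean(ref) exactly; CIs bracket their points
  set.seed(9)
  r <- runif(40, 0, 30); p <- r + rnorm(40)
  b3 <- bland_altman(r, p)
  expect_equal(b3$bias, mean(p) - mean(r))
  expect_true(b3$ci_bias[1] <= b3$bias && b3$bias <= b3$ci_bias[2])
  expect_true(b3$ci_loa_upper[1] <= b3$loa_upper &&
                b3$loa_upper <= b3$ci_loa_upper[2])
  expect_true(b3$loa_lower <= b3$bias && b3$bias <= b3$loa_upper)
})

test_that("threshold reports count the confusion matrix correctly", {
  perfect <- threshold_report(c(4, 8, 12, 18), c(4, 8, 12, 18))
  expect_true(all(perfect$f1 == 1 | is.na(perfect$f1)))

  r <- threshold_report(c(4, 12, 15), c(6, 12, 3), thresholds = 10)
  expect_equal(r$tp, 1); expect_equal(r$fp, 0)
  expect_equal(r$fn, 1); expect_equal(r$tn, 1)
  expect_equal(r$tpr, 0.5)
  expect_equal(r$ppv, 1)
  expect_equal(r$f1, 2 / 3)

  # nothing predicted positive: PPV undefined, TPR zero
  r2 <- threshold_report(c(12, 15, 3), c(1, 2, 0), thresholds = 10)
  expect_true(is.na(r2$ppv))
  expect_equal(r2$tpr, 0)

  expect_equal(nrow(threshold_report(c(4, 12, 15), c(6, 12, 3))), 16L)
})

test_that("subtype reports compute accuracy, F1 and Cohen's kappa", {
  s <- subtype_report(c("low", "high", "low"), c("low", "high", "low"))
  expect_equal(s$accuracy, 1)
  expect_equal(s$cohen_kappa, 1)

  # 2x2 confusion [[2,1],[1,2]]: kappa = 1/3
  truth <- c("low", "low", "low", "high", "high", "high")
  pred <- c("low", "low", "high", "low", "high", "high")
  s2 <- subtype_report(truth, pred)
  expect_equal(s2$accuracy, 4 / 6)
  expect_equal(s2$cohen_kappa, 1 / 3)

  # kappa of random labels is ~0
  set.seed(31)
  labs <- c("low", "high", "extreme")
  s3 <- subtype_report(sample(labs, 10000, TRUE, prob = c(0.5, 0.3, 0.2)),
                       sample(labs, 10000, TRUE, prob = c(0.5, 0.3, 0.2)))
  expect_lt(abs(s3$cohen_kappa), 0.05)
})

test_that("Fisher exact p-values match exhaustive enumeration", {
  # the [[10,0],[0,10]] diagonal table
  tab <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, fisher_enum_p(tab),
               tolerance = 1e-10)
  expect_equal(fisher_enum_p(tab), 1.082509e-05, tolerance = 1e-5)

  # battery of random tables with margins <= 40
  set.seed(77)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(t2) == 0 || any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher.test(t2)$p.value, fisher_enum_p(t2),
                 tolerance = 1e-10, label = paste(t2, collapse = ","))
  }
})

test_that("subtype characterization summarizes indels and MMR/POLE status", {
  muts <- mutation_table(
    rep(c("S1", "S2"), c(10, 4)),
    c(rep("G1", 7), "POLE", "MLH1", "G2", rep("G3", 3), "MSH2"),
    "c", 1:14, "C", "T",
    c(rep("synonymous", 5), "indel", "indel", "nonsynonymous",
      "nonsynonymous", "synonymous", rep("synonymous", 3), "synonymous"))
  asn <- data.frame(sample_id = c("S1", "S2"),
                    subtype = c("high", "low"))
  ch <- characterize_subtypes(muts, asn)
  s1 <- ch$samples[ch$samples$sample_id == "S1", ]
  expect_equal(s1$indel_fraction, 0.2)
  expect_true(s1$pole_mutated)
  expect_true(s1$mmr_mutated)
  s2 <- ch$samples[ch$samples$sample_id == "S2", ]
  expect_false(s2$mmr_mutated)       # MSH2 mutation is synonymous only
  expect_s3_class(ch$fisher, "data.frame")
  expect_true(all(ch$fisher$p_value >= 0 & ch$fisher$p_value <= 1))
})

test_that("a planted MMR-high cohort shows the expected association", {
  sim <- small_sim()
  tr <- sim$truth$samples
  ch <- characterize_subtypes(sim$muts,
                              data.frame(sample_id = tr$sample_id,
                                         subtype = tr$class))
  p_mmr_high <- ch$fisher$p_value[ch$fisher$subtype == "high" &
                                    ch$fisher$profile == "mmr"]
  p_pole_ext <- ch$fisher$p_value[ch$fisher$subtype == "extreme" &
                                    ch$fisher$profile == "pole"]
  expect_lt(p_mmr_high, 0.01)
  expect_lt(p_pole_ext, 0.01)
  # indel fractions track the subtype spec ordering: high > low > extreme
  st <- ch$subtypes
  f <- setNames(st$mean_indel_fraction, st$subtype)
  expect_gt(f[["high"]], f[["low"]])
  expect_gt(f[["low"]], f[["extreme"]])
})
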