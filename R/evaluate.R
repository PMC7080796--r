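# Method-agreement and classification evaluation battery.

.cap_pairs <- function(reference, predicted, cap) {
  stopifnot(length(reference) == length(predicted))
  keep <- !is.na(reference) & !is.na(predicted)
  if (!is.null(cap)) keep <- keep & reference <= cap
  list(ref = reference[keep], pred = predicted[keep])
}

#' Agreement metrics between a reference and a predicted TMB vector
#'
#' Spearman correlation, least-squares `predicted ~ reference` regression
#' (slope, intercept, R^2 and residual standard error
#' `sigma = sqrt(RSS/(n-2))`), plus MAE and RMSE on the raw pairs.  Only
#' pairs with `reference <= cap` enter (hypermutated outliers would
#' otherwise dominate every metric).
#'
#' @param reference reference TMB values (e.g. WES-based)
#' @param predicted predicted TMB values (same length)
#' @param cap reference cap in mut/Mb (default 40; `NULL` disables)
#' @return list of class `AgreementReport`: `spearman_r`, `r_squared`,
#'   `mae`, `rmse`, `slope`, `intercept`, `sigma`, `n`, `flag`
#' @export
agreement_metrics <- function(reference, predicted, cap = 40) {
  p <- .cap_pairs(reference, predicted, cap)
  n <- length(p$ref)
  if (n < 3L) stop("fewer than 3 pairs after cap filter")
  flag <- ""
  if (stats::sd(p$ref) == 0) {
    sp <- NA_real_
    flag <- "constant_reference"
    slope <- NA_real_; intercept <- NA_real_; sig <- NA_real_; r2 <- NA_real_
  } else {
    sp <- stats::cor(p$ref, p$pred, method = "spearman")
    fit <- stats::lm(p$pred ~ p$ref)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    rss <- sum(stats::residuals(fit)^2)
    sig <- sqrt(rss / (n - 2))
    tss <- sum((p$pred - mean(p$pred))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  }
  structure(list(spearman_r = sp, r_squared = r2,
                 mae = mean(abs(p$pred - p$ref)),
                 rmse = sqrt(mean((p$pred - p$ref)^2)),
                 slope = slope, intercept = intercept, sigma = sig,
                 n = n, flag = flag), class = "AgreementReport")
}

#' Bland-Altman analysis of two TMB measurements
#'
#' Differences are `predicted - reference`.  Reports the bias (mean
#' difference), the 95% limits of agreement `bias +/- 1.96 sd`, the
#' t-based 95% CI of the bias, and the limits' CIs using the
#' Bland-Altman standard error `sqrt(3 sd^2 / n)`.
#'
#' @inheritParams agreement_metrics
#' @return list of class `BlandAltmanReport`: `bias`, `loa_lower`,
#'   `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`, `sd_diff`, `n`
#' @export
bland_altman <- function(reference, predicted, cap = 40) {
  p <- .cap_pairs(reference, predicted, cap)
  n <- length(p$ref)
  if (n < 3L) stop("fewer than 3 pairs after cap filter")
  d <- p$pred - p$ref
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- sqrt(3 * s^2 / n)
  structure(list(
    bias = bias,
    loa_lower = bias - 1.96 * s,
    loa_upper = bias + 1.96 * s,
    ci_bias = c(bias - tq * se_bias, bias + tq * se_bias),
    ci_loa_lower = c(bias - 1.96 * s - tq * se_loa,
                     bias - 1.96 * s + tq * se_loa),
    ci_loa_upper = c(bias + 1.96 * s - tq * se_loa,
                     bias + 1.96 * s + tq * se_loa),
    sd_diff = s, n = n), class = "BlandAltmanReport")
}

.binary_scores <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred); tn <- sum(!truth & !pred)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(ppv) && tpr + ppv > 0) {
    2 * tpr * ppv / (tpr + ppv)
  } else NA_real_
  c(tp = tp, fp = fp, fn = fn, tn = tn, tpr = tpr, ppv = ppv, f1 = f1)
}

#' Threshold-sweep classification report
#'
#' For each threshold, the reference TMB defines the truth labels and the
#' predicted TMB is classified at the *same* cutoff; TPR, PPV, and F1 are
#' reported per threshold.  Undefined ratios (zero denominators) are NA.
#'
#' @inheritParams agreement_metrics
#' @param thresholds cutoffs in mut/Mb (default 5..20)
#' @return data.frame, one row per threshold
#' @export
threshold_report <- function(reference, predicted, thresholds = 5:20,
                             cap = 40) {
  p <- .cap_pairs(reference, predicted, cap)
  rows <- lapply(thresholds, function(t) {
    truth <- p$ref >= t
    pred <- p$pred >= t
    s <- .binary_scores(truth, pred)
    data.frame(threshold = t, t(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-class subtype classification report
#'
#' Confusion matrix, one-vs-rest F1/TPR/PPV per class, overall accuracy,
#' and Cohen's kappa `(p_o - p_e) / (1 - p_e)`.
#'
#' @param truth_labels,predicted_labels parallel label vectors
#'   (typically from `c("low","high","extreme")`)
#' @return list of class `ClassificationReport`: `confusion`, `per_class`
#'   (data.frame), `accuracy`, `cohen_kappa`, `n`
#' @export
subtype_report <- function(truth_labels, predicted_labels) {
  stopifnot(length(truth_labels) == length(predicted_labels))
  levs <- intersect(SUBTYPE_LABELS, unique(c(truth_labels, predicted_labels)))
  if (!length(levs)) levs <- sort(unique(c(truth_labels, predicted_labels)))
  tr <- factor(truth_labels, levels = levs)
  pr <- factor(predicted_labels, levels = levs)
  conf <- table(truth = tr, predicted = pr)
  n <- length(tr)
  per <- do.call(rbind, lapply(levs, function(l) {
    s <- .binary_scores(tr == l, pr == l)
    data.frame(subtype = l, tpr = s[["tpr"]], ppv = s[["ppv"]],
               f1 = s[["f1"]], stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  structure(list(confusion = conf, per_class = per, accuracy = p_o,
                 cohen_kappa = kappa, n = n),
            class = "ClassificationReport")
}

MMR_GENES <- c("MLH1", "MLH3", "MSH2", "MSH3", "MSH6", "PMS1", "PMS2")

#' Characterize TMB subtypes by indel fraction and MMR/POLE mutation status
#'
#' Per sample: the fraction of indel mutations and flags for at least one
#' non-synonymous mutation in POLE and in the mismatch-repair genes.  Per
#' subtype: sample counts, mutated percentages, mean indel fraction, and
#' two-sided Fisher exact tests of subtype membership against mutation
#' presence (one 2x2 test per subtype x profile).
#'
#' @param muts MutationTable for the cohort
#' @param assignments data.frame with `sample_id` and `subtype`
#' @param mmr_genes mismatch-repair gene set
#' @param pole_gene polymerase-epsilon gene name
#' @return list: `samples` (per-sample table), `subtypes` (summary),
#'   `fisher` (tests)
#' @export
characterize_subtypes <- function(muts, assignments, mmr_genes = MMR_GENES,
                                  pole_gene = "POLE") {
  stopifnot(all(c("sample_id", "subtype") %in% names(assignments)))
  missing <- setdiff(unique(muts$sample_id), assignments$sample_id)
  if (length(missing)) stop("assignments lack sample(s): ",
                            paste(utils::head(missing, 3), collapse = ", "))
  per_sample <- do.call(rbind, lapply(seq_len(nrow(assignments)), function(i) {
    s <- assignments$sample_id[i]
    ms <- muts[muts$sample_id == s, , drop = FALSE]
    tot <- nrow(ms)
    nonsyn <- ms[ms$variant_class == "nonsynonymous", , drop = FALSE]
    data.frame(
      sample_id = s, subtype = assignments$subtype[i], n_mut = tot,
      indel_fraction = if (tot > 0) sum(ms$variant_class == "indel") / tot
                       else NA_real_,
      pole_mutated = pole_gene %in% nonsyn$gene,
      mmr_mutated = any(mmr_genes %in% nonsyn$gene),
      stringsAsFactors = FALSE)
  }))
  subtypes <- do.call(rbind, lapply(split(per_sample, per_sample$subtype),
                                    function(d) {
    data.frame(subtype = d$subtype[1], n = nrow(d),
               n_pole = sum(d$pole_mutated),
               pct_pole = 100 * mean(d$pole_mutated),
               n_mmr = sum(d$mmr_mutated),
               pct_mmr = 100 * mean(d$mmr_mutated),
               mean_indel_fraction = mean(d$indel_fraction, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(subtypes) <- NULL
  fisher <- do.call(rbind, unlist(lapply(unique(per_sample$subtype),
                                         function(st) {
    lapply(c("pole_mutated", "mmr_mutated"), function(prof) {
      inn <- per_sample$subtype == st
      tab <- table(factor(inn, c(TRUE, FALSE)),
                   factor(per_sample[[prof]], c(TRUE, FALSE)))
      data.frame(subtype = st, profile = sub("_mutated", "", prof),
                 p_value = stats::fisher.test(tab)$p.value,
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  rownames(fisher) <- NULL
  list(samples = per_sample, subtypes = subtypes, fisher = fisher)
}
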