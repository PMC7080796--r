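# TMB prediction: counting baselines and the per-gene NB maximum-likelihood
# estimator of the sample background rate.

#' Counting-based TMB
#'
#' The standard measurement: number of mutations of the included impact
#' classes divided by the sequenced region size in Mb.
#'
#' @param muts MutationTable for one sample (or any set of records to count)
#' @param region_mb sequenced region size in megabases (> 0)
#' @param include impact classes to count (default non-synonymous only,
#'   the WES-standard convention)
#' @param sample_id,method labels carried into the output row
#' @return one-row data.frame (`sample_id`, `method`, `tmb`, `m_hat`,
#'   `loglik`, `n_mut_used`, `region_mb`, `flag`)
#' @export
counting_tmb <- function(muts, region_mb, include = "nonsynonymous",
                         sample_id = NA_character_, method = "counting") {
  if (!is.numeric(region_mb) || region_mb <= 0) {
    stop("region_mb must be positive")
  }
  n <- sum(muts$variant_class %in% include)
  data.frame(sample_id = sample_id, method = method, tmb = n / region_mb,
             m_hat = NA_real_, loglik = NA_real_, n_mut_used = n,
             region_mb = region_mb, flag = "", stringsAsFactors = FALSE)
}

#' Select the gene set whose non-synonymous mutations enter the MLE
#'
#' Genes are ranked ascending by their observed/expected mutation ratio
#' from the training cohort (high-ratio genes are likely drivers under
#' positive selection); the bottom `floor(fraction * G)` genes are
#' included.  Ties are broken by gene identifier for determinism.
#'
#' @param gene_summaries data.frame from [driver_statistic()]
#' @param fraction value in [0, 1]; 1 includes every gene, 0 none
#'   (synonymous-only prediction)
#' @return list of class `GeneInclusionRule`: `fraction`, `included_genes`
#' @export
select_included_genes <- function(gene_summaries, fraction) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  ord <- order(gene_summaries$obs_exp_ratio, gene_summaries$gene)
  k <- floor(fraction * nrow(gene_summaries))
  structure(list(fraction = fraction,
                 included_genes = gene_summaries$gene[ord][seq_len(k)]),
            class = "GeneInclusionRule")
}

# concave NB log-likelihood in t = log(m); score has a single root
.mle_background_rate <- function(x, lambda_e, alpha,
                                 lower = 1e-10, upper = 1e-2) {
  score <- function(t) {
    mu <- exp(t) * lambda_e
    sum(lambda_e * (x / pmax(mu, 1e-300) - (x + alpha) / (mu + alpha)))
  }
  tl <- log(lower); tu <- log(upper)
  if (all(x == 0) || score(tl) <= 0) {
    return(list(m = lower, flag = "lower_boundary"))
  }
  if (score(tu) >= 0) {
    return(list(m = upper, flag = "upper_boundary"))
  }
  root <- stats::uniroot(score, c(tl, tu), tol = 1e-10)$root
  list(m = exp(root), flag = "")
}

#' Maximum-likelihood TMB prediction for one sample
#'
#' Models each gene's panel-restricted SNV count as an independent
#' negative binomial with mean `m * lambda_star[g] * e_g`, where `e_g`
#' sums the gene's panel synonymous exposure and -- for genes passing the
#' inclusion rule -- its non-synonymous exposure, and maximizes the joint
#' likelihood over the sample background rate `m` (log-scale bounded
#' search; boundary hits are flagged, not errors).  The rate is converted
#' to TMB via the whole-exome expected non-synonymous background count:
#' `tmb = m_hat * sum_g lambda_star[g] e_nonsyn[g] / exome_mb`.
#'
#' @param muts MutationTable for a single sample, already restricted to the
#'   panel territory.
#' @param model fitted BMRModel.
#' @param annot ExomeAnnotation of the *covered* territory (the whole-exome
#'   annotation, or a panel-restricted/subset annotation for panels).
#' @param rule GeneInclusionRule from [select_included_genes()].
#' @param sample_id label for the output row.
#' @return one-row data.frame as in [counting_tmb()] with `method = "ectmb"`.
#' @export
predict_tmb_mle <- function(muts, model, annot, rule,
                            sample_id = NA_character_) {
  stopifnot(inherits(model, "BMRModel"), inherits(annot, "ExomeAnnotation"),
            inherits(rule, "GeneInclusionRule"))
  genes <- intersect(annot$genes, model$genes)
  if (!length(genes)) stop("no annotation genes known to the model")
  e_syn <- as.vector(annot$counts[genes, , "synonymous", drop = FALSE][, , 1] %*%
                       model$r)
  e_nonsyn <- as.vector(annot$counts[genes, , "nonsynonymous",
                                     drop = FALSE][, , 1] %*% model$r)
  incl <- genes %in% rule$included_genes
  e_bar <- e_syn + ifelse(incl, e_nonsyn, 0)
  lambda_e <- model$lambda_star[genes] * e_bar
  keep <- lambda_e > 0
  if (!any(keep)) stop("no panel genes with positive exposure")

  syn_ct <- table(factor(muts$gene[muts$variant_class == "synonymous"],
                         levels = genes))
  non_ct <- table(factor(muts$gene[muts$variant_class == "nonsynonymous"],
                         levels = genes))
  x <- as.integer(syn_ct) + ifelse(incl, as.integer(non_ct), 0L)

  fit <- .mle_background_rate(x[keep], lambda_e[keep], model$alpha)
  mu <- fit$m * lambda_e[keep]
  ll <- sum(stats::dnbinom(x[keep], size = model$alpha, mu = mu, log = TRUE))
  tmb <- fit$m * sum(model$lambda_star * model$e_nonsyn) / model$exome_mb
  data.frame(sample_id = sample_id, method = "ectmb", tmb = tmb,
             m_hat = fit$m, loglik = ll, n_mut_used = sum(x[keep]),
             region_mb = annot$exome_mb, flag = fit$flag,
             stringsAsFactors = FALSE)
}

#' Predict TMB for a cohort with all three methods
#'
#' Runs, per sample: plain counting, counting after hotspot filtering,
#' and the model-based MLE.  When a panel is supplied, mutations are first
#' restricted to its intervals, counting uses the panel's exonic size, and
#' the MLE uses the panel annotation (`panel_annot`, typically
#' `subset_annotation(annot, panel$gene_set)` for whole-gene panels or a
#' `build_exome_annotation(..., panel = panel)` rebuild for partial ones).
#'
#' @param muts MutationTable for the cohort.
#' @param model fitted BMRModel.
#' @param annot whole-exome ExomeAnnotation used at training time.
#' @param rule GeneInclusionRule.
#' @param panel optional PanelDefinition.
#' @param panel_annot optional panel-restricted ExomeAnnotation; defaults to
#'   `subset_annotation(annot, panel$gene_set)` when a panel is given.
#' @param hotspots optional hotspot table for the filtered-counting baseline
#'   (without it that baseline equals plain counting).
#' @return data.frame with one row per sample x method; per-sample MLE
#'   failures become flagged rows rather than aborting the cohort.
#' @export
predict_cohort <- function(muts, model, annot, rule, panel = NULL,
                           panel_annot = NULL, hotspots = NULL) {
  if (!is.null(panel)) {
    muts <- subset_to_panel(muts, panel)
    region_mb <- panel$exonic_mb
    if (is.null(panel_annot)) {
      panel_annot <- subset_annotation(annot, panel$gene_set)
    }
  } else {
    region_mb <- annot$exome_mb
    panel_annot <- annot
  }
  muts_filt <- if (is.null(hotspots)) muts else filter_hotspots(muts, hotspots)
  samples <- sort(unique(muts$sample_id))
  rows <- lapply(samples, function(s) {
    ms <- muts[muts$sample_id == s, , drop = FALSE]
    msf <- muts_filt[muts_filt$sample_id == s, , drop = FALSE]
    mle <- tryCatch(predict_tmb_mle(ms, model, panel_annot, rule,
                                    sample_id = s),
                    error = function(e) {
                      data.frame(sample_id = s, method = "ectmb",
                                 tmb = NA_real_, m_hat = NA_real_,
                                 loglik = NA_real_, n_mut_used = NA_integer_,
                                 region_mb = NA_real_,
                                 flag = paste0("error: ", conditionMessage(e)),
                                 stringsAsFactors = FALSE)
                    })
    rbind(counting_tmb(ms, region_mb, sample_id = s, method = "counting"),
          counting_tmb(msf, region_mb, sample_id = s,
                       method = "counting_filtered"),
          mle)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cancer-type default gene-inclusion fractions
#'
#' Cancer types dominated by environmental mutagenesis (bladder, melanoma,
#' and both lung carcinomas) use all genes; other types exclude the top
#' 0.05% of genes by observed/expected ratio.
#'
#' @param cancer_type TCGA-style code (e.g. "LUAD", "COAD")
#' @return inclusion fraction
#' @export
default_inclusion_fraction <- function(cancer_type) {
  full <- c("BLCA", "SKCM", "LUSC", "LUAD")
  ifelse(toupper(cancer_type) %in% full, 1.0, 0.9995)
}
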