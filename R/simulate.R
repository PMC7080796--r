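# Synthetic cohort generator: produces mutation calls, exposures,
# covariates and ground truth with the statistical structure the
# background model assumes, so the whole pipeline is testable without
# external data.

#' Default TMB subtype specification for the simulator
#'
#' Three classes on the log10-TMB scale mirroring the low / MMR-deficient
#' high / POLE-driven extreme structure of hypermutation-prone cohorts:
#' mixing proportions, class means/sds, indel fractions (~5% / ~17% / ~1%)
#' and per-class probabilities of carrying a non-synonymous MMR or POLE
#' mutation.
#' @return data.frame, one row per class
#' @export
default_subtype_spec <- function() {
  data.frame(
    name = c("low", "high", "extreme"),
    prop = c(0.60, 0.30, 0.10),
    mean_log10_tmb = c(1.20, 2.00, 2.80),
    sd_log10_tmb = c(0.20, 0.20, 0.20),
    indel_fraction = c(0.05, 0.17, 0.01),
    mmr_prob = c(0.05, 0.85, 0.20),
    pole_prob = c(0.02, 0.10, 0.92),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_samples cohort size
#' @param n_genes number of genes
#' @param gene_length_meanlog,gene_length_sdlog log-normal coding-length
#'   distribution (median ~1.5 kb)
#' @param context_sdlog spread of the true trinucleotide rate profile
#' @param alpha_true NB dispersion: the gene-level Gamma(shape, rate) =
#'   (alpha_true, alpha_true) rate multiplier
#' @param beta_true GLM truth `(intercept, log-expression, timing)`
#' @param n_drivers number of planted driver genes
#' @param driver_fold multiplicative non-synonymous excess of drivers
#' @param subtype_spec data.frame as [default_subtype_spec()]
#' @param seed integer master seed (stage sub-seeds are derived from it)
#' @return list of class `SimConfig`
#' @export
sim_config <- function(n_samples = 300L, n_genes = 2000L,
                       gene_length_meanlog = log(1500),
                       gene_length_sdlog = 0.45,
                       context_sdlog = 0.5,
                       alpha_true = 10,
                       beta_true = c(0, 0.5, -0.3),
                       n_drivers = 20L, driver_fold = 10,
                       subtype_spec = default_subtype_spec(),
                       seed = 1L) {
  if (abs(sum(subtype_spec$prop) - 1) > 1e-8) {
    stop("subtype_spec: proportions must sum to 1")
  }
  if (any(subtype_spec$sd_log10_tmb <= 0)) {
    stop("subtype_spec: sd_log10_tmb must be positive")
  }
  if (alpha_true <= 0) stop("alpha_true must be positive")
  if (driver_fold < 1) stop("driver_fold must be >= 1")
  if (n_drivers < 0 || n_drivers > n_genes) stop("n_drivers out of range")
  structure(as.list(environment()), class = "SimConfig")
}

.draw_contexts <- function(gene_idx, impact, W_syn, W_non) {
  # contexts drawn per (gene, impact) group proportional to rate x sites
  out <- integer(length(gene_idx))
  grp <- paste0(gene_idx, "_", impact)
  for (g in split(seq_along(gene_idx), grp)) {
    gi <- gene_idx[g[1]]
    w <- if (impact[g[1]] == "synonymous") W_syn[gi, ] else W_non[gi, ]
    if (sum(w) <= 0) w <- rep(1, 96)
    out[g] <- sample.int(96L, length(g), replace = TRUE, prob = w)
  }
  out
}

#' Simulate a whole-exome cohort with ground truth
#'
#' Generates per-gene exposure tables (context-by-impact counts of
#' possible changes), covariates correlated with the true gene rates,
#' log-normal-mixture sample background rates spanning ~3 orders of
#' magnitude, Poisson mutation counts given gene rates (gene rates carry
#' a Gamma(alpha, alpha) multiplier, so counts are marginally negative
#' binomial with dispersion `alpha_true`), planted driver genes with a
#' non-synonymous excess, subtype-specific indel fractions, and planted
#' MMR/POLE mutations.  Fully reproducible given the config seed.
#'
#' @param config `SimConfig` from [sim_config()]
#' @return list: `muts` (MutationTable), `annot` (ExomeAnnotation with gene
#'   intervals on a synthetic contig), `covariates`, `truth` (list with
#'   `samples` and `genes` data.frames), `config`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  G <- config$n_genes; S <- config$n_samples
  ctx <- .context_labels()

  ## ---- stage 1: genes -------------------------------------------------------
  set.seed(config$seed + 1000L)
  genes <- sprintf("G%04d", seq_len(G))
  L <- pmax(150L, as.integer(round(stats::rlnorm(
    G, config$gene_length_meanlog, config$gene_length_sdlog))))
  rho <- stats::rlnorm(96, 0, config$context_sdlog)      # true context rates
  comp <- stats::rlnorm(96, 0, 0.3)                      # sequence composition
  p_syn <- comp * 0.25 / sum(comp)
  p_non <- comp * 0.75 / sum(comp)
  prob <- c(p_syn, p_non)
  counts <- array(0L, dim = c(G, 96L, 3L),
                  dimnames = list(genes, ctx, IMPACT_LEVELS))
  draw <- vapply(seq_len(G),
                 function(g) stats::rmultinom(1, 3L * L[g], prob)[, 1],
                 integer(192))
  counts[, , "synonymous"] <- t(draw[1:96, ])
  counts[, , "nonsynonymous"] <- t(draw[97:192, ])

  A <- colSums(counts[, , "synonymous"])
  w <- A / sum(A)
  r_true <- rho / sum(w * rho)                 # exposure-weighted mean 1
  e_syn <- as.vector(counts[, , "synonymous"] %*% r_true)
  e_nonsyn <- as.vector(counts[, , "nonsynonymous"] %*% r_true)

  expression <- stats::rlnorm(G, 2, 1.2)
  timing <- stats::rnorm(G)
  lam_glm <- exp(config$beta_true[1] +
                   config$beta_true[2] * log(expression + 0.1) +
                   config$beta_true[3] * timing)
  norm <- sum(lam_glm * e_syn) / sum(e_syn)
  lam_glm <- lam_glm / norm                    # exposure-weighted mean 1
  beta0_true <- config$beta_true[1] - log(norm)
  v <- stats::rgamma(G, shape = config$alpha_true, rate = config$alpha_true)
  lambda <- lam_glm * v

  special <- c("POLE", MMR_GENES)
  special_idx <- sample.int(G, length(special))
  genes[special_idx] <- special
  dimnames(counts)[[1]] <- genes
  driver_idx <- sample(setdiff(seq_len(G), special_idx), config$n_drivers)
  driver <- seq_len(G) %in% driver_idx

  gap <- 100L
  start0 <- cumsum(c(0L, utils::head(L + gap, -1L)))
  gene_intervals <- data.frame(gene = genes, chrom = "chr1", start = start0,
                               end = start0 + L, stringsAsFactors = FALSE)
  annot <- exome_annotation(counts, gene_intervals = gene_intervals)
  tot_bg_nonsyn <- sum(lambda * e_nonsyn)

  ## ---- stage 2: samples -----------------------------------------------------
  set.seed(config$seed + 2000L)
  spec <- config$subtype_spec
  samples <- sprintf("S%04d", seq_len(S))
  cls <- sample.int(nrow(spec), S, replace = TRUE, prob = spec$prop)
  tmb_target <- 10^stats::rnorm(S, spec$mean_log10_tmb[cls],
                                spec$sd_log10_tmb[cls])
  m <- tmb_target * annot$exome_mb / tot_bg_nonsyn
  tmb_true <- m * tot_bg_nonsyn / annot$exome_mb   # == tmb_target
  pole_flag <- stats::rbinom(S, 1, spec$pole_prob[cls]) == 1
  mmr_flag <- stats::rbinom(S, 1, spec$mmr_prob[cls]) == 1

  ## ---- stage 3: mutation counts --------------------------------------------
  set.seed(config$seed + 3000L)
  driver_mult <- ifelse(driver, config$driver_fold, 1)
  W_syn <- sweep(counts[, , "synonymous"], 2, r_true, "*")
  W_non <- sweep(counts[, , "nonsynonymous"], 2, r_true, "*")

  rec_s <- list(); rec_g <- list(); rec_i <- list()
  for (s in seq_len(S)) {
    ys <- stats::rpois(G, m[s] * lambda * e_syn)
    yn <- stats::rpois(G, m[s] * lambda * e_nonsyn * driver_mult)
    nz_s <- which(ys > 0); nz_n <- which(yn > 0)
    gidx <- c(rep(nz_s, ys[nz_s]), rep(nz_n, yn[nz_n]))
    imp <- rep(c("synonymous", "nonsynonymous"),
               c(sum(ys[nz_s]), sum(yn[nz_n])))
    # planted MMR/POLE non-synonymous mutations
    extra <- integer(0)
    if (pole_flag[s]) extra <- c(extra, which(genes == "POLE"))
    if (mmr_flag[s]) extra <- c(extra, which(genes == sample(MMR_GENES, 1)))
    if (length(extra)) {
      gidx <- c(gidx, extra)
      imp <- c(imp, rep("nonsynonymous", length(extra)))
    }
    n_snv <- length(gidx)
    f <- spec$indel_fraction[cls[s]]
    n_indel <- stats::rpois(1, n_snv * f / (1 - f))
    if (n_indel > 0) {
      gidx <- c(gidx, sample.int(G, n_indel, replace = TRUE))
      imp <- c(imp, rep("indel", n_indel))
    }
    rec_s[[s]] <- rep(s, length(gidx)); rec_g[[s]] <- gidx; rec_i[[s]] <- imp
  }
  gidx <- unlist(rec_g); imp <- unlist(rec_i); sidx <- unlist(rec_s)

  pos <- start0[gidx] +
    as.integer(floor(stats::runif(length(gidx)) * L[gidx])) + 1L
  context <- rep(NA_character_, length(gidx))
  ref <- rep("A", length(gidx)); alt <- rep("-", length(gidx))
  is_snv <- imp != "indel"
  ci <- .draw_contexts(gidx[is_snv], imp[is_snv], W_syn, W_non)
  lab <- ctx[ci]
  context[is_snv] <- lab
  # emit half the SNVs on the purine strand for realism
  flip <- stats::runif(sum(is_snv)) < 0.5
  ref_py <- substr(lab, 3, 3); alt_py <- substr(lab, 5, 5)
  ref[is_snv] <- ifelse(flip, unname(COMPLEMENT[ref_py]), ref_py)
  alt[is_snv] <- ifelse(flip, unname(COMPLEMENT[alt_py]), alt_py)

  muts <- mutation_table(samples[sidx], genes[gidx], "chr1", pos, ref, alt,
                         imp, context)

  truth_samples <- data.frame(
    sample_id = samples, class = spec$name[cls], m = m, tmb = tmb_true,
    pole_mutated = pole_flag, mmr_mutated = mmr_flag,
    stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene = genes, length = L, lambda = lambda, lambda_glm = lam_glm,
    driver = driver, stringsAsFactors = FALSE)
  covariates <- data.frame(expression = expression,
                           replication_timing = timing,
                           row.names = genes)
  list(muts = muts, annot = annot, covariates = covariates,
       truth = list(samples = truth_samples, genes = truth_genes,
                    beta = c(beta0_true, config$beta_true[2:3]),
                    r = stats::setNames(r_true, ctx),
                    alpha = config$alpha_true),
       config = config)
}

#' Simulate a driver-enriched targeted panel
#'
#' Genes are sampled without replacement with probability proportional to
#' `1 + enrichment * driver_flag` until the cumulative coding size reaches
#' `target_mb`, emulating the hotspot/driver enrichment of commercial
#' panels.  The panel covers whole genes of the simulated exome.
#'
#' @param sim result of [simulate_cohort()]
#' @param enrichment driver-gene sampling weight multiplier (0 = uniform)
#' @param target_mb panel coding size in Mb (<= simulated exome size)
#' @param seed integer seed
#' @return PanelDefinition
#' @export
simulate_biased_panel <- function(sim, enrichment, target_mb, seed = 1L) {
  if (target_mb > sim$annot$exome_mb + 1e-9) {
    stop("target_mb exceeds the simulated exome size (",
         format(sim$annot$exome_mb, digits = 4), " Mb)")
  }
  set.seed(seed)
  tg <- sim$truth$genes
  wts <- 1 + enrichment * tg$driver
  ord <- sample(seq_len(nrow(tg)), nrow(tg), prob = wts)
  cum <- cumsum(tg$length[ord])
  k <- which(cum >= target_mb * 1e6)[1]
  if (is.na(k)) k <- nrow(tg)
  chosen <- tg$gene[ord[seq_len(k)]]
  gi <- sim$annot$gene_intervals
  panel_definition(gi[gi$gene %in% chosen, c("chrom", "start", "end")],
                   name = sprintf("sim_panel_%gMb", target_mb),
                   annot = sim$annot)
}

#' Write a simulated cohort to a directory
#'
#' Emits the MAF, annotation TSV, covariate TSV, and truth tables as
#' plain-text files.
#' @param sim result of [simulate_cohort()]
#' @param dir output directory
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(sim$muts, file.path(dir, "cohort.maf"))
  write_annotation(sim$annot, file.path(dir, "annotation.tsv"))
  cov <- data.frame(gene_id = rownames(sim$covariates), sim$covariates,
                    row.names = NULL)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annot$gene_intervals,
                     file.path(dir, "gene_intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
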