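# Three-step background mutation model.
#
# Step 1: trinucleotide context rates r[c] and sample-specific background
#         rates m[s] from synonymous SNVs (method of moments).
# Step 2: pooled negative-binomial GLM of per-gene synonymous totals on
#         expression and replication timing, offset by the step-1 exposure.
# Step 3: conjugate Gamma-Poisson consolidation of the GLM prediction and
#         the per-gene raw rate into the final gene multiplier lambda_star.

#' Estimate trinucleotide context rates and sample background rates
#'
#' Raw per-context rates are total synonymous counts divided by
#' (number of samples x synonymous exposure of the context), then
#' normalized to exposure-weighted mean 1; zero-count contexts receive a
#' 0.5 pseudocount so no rate is exactly zero.  Sample rates are each
#' sample's synonymous count divided by the total context-weighted
#' synonymous exposure of the exome.
#'
#' @param muts MutationTable (only synonymous SNVs with non-missing
#'   contexts are used for the context rates; every distinct sample in the
#'   table gets an m value, zero-count samples included).
#' @param annot ExomeAnnotation covering the genes of `muts`.
#' @return list with `r` (96 named rates), `m` (named per-sample rates),
#'   `e_syn`, `e_nonsyn` (context-weighted per-gene exposures).
#' @export
estimate_context_rates <- function(muts, annot) {
  stopifnot(inherits(annot, "ExomeAnnotation"))
  ctx <- .context_labels()
  samples <- sort(unique(muts$sample_id))
  if (!length(samples)) stop("no samples in mutation table")
  syn <- muts[muts$variant_class == "synonymous" & !is.na(muts$context), ,
              drop = FALSE]
  if (!nrow(syn)) stop("no synonymous SNVs with context available")
  unknown <- setdiff(unique(syn$gene), annot$genes)
  if (length(unknown)) {
    stop("mutation gene(s) absent from annotation: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  A <- colSums(annot$counts[, , "synonymous", drop = FALSE][, , 1])
  if (sum(A) <= 0) stop("zero total synonymous exposure in annotation")
  tot <- table(factor(syn$context, levels = ctx))
  tot <- as.numeric(tot)
  num <- ifelse(tot == 0, 0.5, tot)
  S <- length(samples)
  raw <- ifelse(A > 0, num / (S * A), NA_real_)
  w <- A / sum(A)
  scale <- sum(w * raw, na.rm = TRUE)
  r <- raw / scale
  r[is.na(r)] <- 1          # contexts with no exposure never contribute
  names(r) <- ctx

  e_syn <- as.vector(annot$counts[, , "synonymous"] %*% r)
  e_nonsyn <- as.vector(annot$counts[, , "nonsynonymous"] %*% r)
  names(e_syn) <- names(e_nonsyn) <- annot$genes

  syn_per_sample <- table(factor(syn$sample_id, levels = samples))
  m <- as.numeric(syn_per_sample) / sum(e_syn)
  names(m) <- samples
  list(r = r, m = m, e_syn = e_syn, e_nonsyn = e_nonsyn)
}

#' Negative-binomial GLM of per-gene synonymous totals on covariates
#'
#' Pools genes to estimate the common effect of expression level and
#' replication timing on the background rate:
#' `log mu_g = log E_g + b0 + b1 log(expression_g + 0.1) + b2 timing_g`,
#' where `E_g` is the step-1 exposure (sum over samples of m[s] times the
#' gene's context-weighted synonymous site count).  Fitted with
#' `MASS::glm.nb` (IRLS with profiled dispersion).
#'
#' @param y named integer vector of per-gene synonymous totals.
#' @param covariates data.frame with rownames = genes and columns
#'   `expression`, `replication_timing` (complete; see
#'   [impute_covariates()]).
#' @param exposure named numeric vector `E_g`; genes with zero exposure are
#'   excluded from the fit but still receive a fitted multiplier.
#' @return list with `beta` (length 3), `beta_se`, `lambda_glm` (named, all
#'   genes), `theta` (the glm.nb dispersion), `converged`.
#' @export
fit_covariate_glm <- function(y, covariates, exposure) {
  genes <- names(y)
  stopifnot(!is.null(genes), all(genes %in% rownames(covariates)),
            identical(names(exposure), genes))
  x1 <- log(covariates[genes, "expression"] + 0.1)
  x2 <- covariates[genes, "replication_timing"]
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) stop("collinear covariates: design is rank-deficient")
  use <- exposure > 0
  if (sum(use) < 10L) stop("fewer than 10 genes with positive exposure")
  dat <- data.frame(y = y[use], x1 = x1[use], x2 = x2[use],
                    off = log(exposure[use]))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ x1 + x2 + offset(off), data = dat,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # near-Poisson data can break the theta profiling; the quasi-fit keeps
    # the same mean structure
    fit <- stats::glm(y ~ x1 + x2 + offset(off), data = dat,
                      family = stats::poisson())
    theta <- Inf
  } else {
    theta <- fit$theta
  }
  beta <- unname(stats::coef(fit))
  beta_se <- unname(sqrt(diag(stats::vcov(fit))))
  names(beta) <- names(beta_se) <- c("intercept", "log_expression",
                                     "replication_timing")
  lambda_glm <- exp(beta[1] + beta[2] * x1 + beta[3] * x2)
  names(lambda_glm) <- genes
  list(beta = beta, beta_se = beta_se, lambda_glm = lambda_glm,
       theta = theta, converged = isTRUE(fit$converged))
}

#' Maximum-likelihood negative-binomial dispersion given fitted means
#'
#' Maximizes the NB log-likelihood over the shape `alpha`
#' (variance = mu + mu^2/alpha) by bounded search on log alpha in
#' [log 1e-2, log 1e6].  An estimate at the upper bound indicates the
#' Poisson limit (no detectable over-dispersion) and is flagged via the
#' `"poisson_limit"` attribute.
#'
#' @param y observed counts
#' @param mu fitted means (same length, positive where y can be positive)
#' @return scalar alpha with attribute `poisson_limit` (logical)
#' @export
estimate_dispersion <- function(y, mu) {
  stopifnot(length(y) == length(mu))
  keep <- mu > 0
  y <- y[keep]; mu <- mu[keep]
  if (length(y) < 10L) stop("fewer than 10 genes available")
  if (all(y == 0)) stop("all counts zero; dispersion not identifiable")
  nll <- function(la) -sum(stats::dnbinom(y, size = exp(la), mu = mu,
                                          log = TRUE))
  lo <- log(1e-2); hi <- log(1e6)
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-8)
  alpha <- exp(opt$minimum)
  attr(alpha, "poisson_limit") <- opt$minimum > hi - 1e-3
  alpha
}

#' Consolidate GLM and raw per-gene rates by a conjugate Bayes update
#'
#' With the gene's latent rate given a Gamma prior of mean `lambda_glm`
#' and shape `alpha` (the NB dispersion), and `y` observed events over
#' exposure `E`, the posterior mean of the rate is
#' `(alpha + y) / (alpha / lambda_glm + E)` -- the exact posterior of the
#' NB model's latent Gamma multiplier.  Genes without exposure return the
#' prior mean.
#'
#' @param y per-gene observed counts
#' @param exposure per-gene exposures `E_g`
#' @param lambda_glm per-gene prior means
#' @param alpha NB dispersion (prior shape), positive scalar
#' @return numeric vector `lambda_star`
#' @export
consolidate_bayes <- function(y, exposure, lambda_glm, alpha) {
  stopifnot(alpha > 0, all(exposure >= 0), all(lambda_glm > 0))
  out <- (alpha + y) / (alpha / lambda_glm + exposure)
  out[exposure == 0] <- lambda_glm[exposure == 0]
  out
}

#' Fit the full three-step background mutation model
#'
#' @param muts training MutationTable (whole-exome calls).
#' @param annot ExomeAnnotation for the training territory.
#' @param covariates per-gene covariate data.frame (`expression`,
#'   `replication_timing`; rownames = genes); missing genes are
#'   median-imputed.
#' @return object of class `BMRModel`.
#' @export
fit_bmr <- function(muts, annot, covariates) {
  unknown <- setdiff(unique(muts$gene), annot$genes)
  if (length(unknown)) {
    warning("dropping ", sum(muts$gene %in% unknown),
            " mutation(s) in gene(s) absent from the annotation")
    muts <- muts[!(muts$gene %in% unknown), , drop = FALSE]
  }
  covariates <- impute_covariates(covariates, annot$genes)
  step1 <- estimate_context_rates(muts, annot)

  count_by_gene <- function(cls) {
    v <- table(factor(muts$gene[muts$variant_class == cls],
                      levels = annot$genes))
    stats::setNames(as.integer(v), annot$genes)
  }
  obs_syn <- count_by_gene("synonymous")
  obs_nonsyn <- count_by_gene("nonsynonymous")

  E <- sum(step1$m) * step1$e_syn
  glm_fit <- fit_covariate_glm(obs_syn, covariates, E)
  mu_hat <- E * glm_fit$lambda_glm
  alpha <- estimate_dispersion(obs_syn, mu_hat)

  lambda_raw <- ifelse(E > 0, obs_syn / E, NA_real_)
  lambda_star <- consolidate_bayes(obs_syn, E, glm_fit$lambda_glm, alpha)

  structure(list(
    r = step1$r,
    m = step1$m,
    beta = glm_fit$beta,
    beta_se = glm_fit$beta_se,
    alpha = as.numeric(alpha),
    poisson_limit = isTRUE(attr(alpha, "poisson_limit")),
    lambda_glm = glm_fit$lambda_glm,
    lambda_raw = lambda_raw,
    lambda_star = lambda_star,
    e_syn = step1$e_syn,
    e_nonsyn = step1$e_nonsyn,
    obs_syn = obs_syn,
    obs_nonsyn = obs_nonsyn,
    genes = annot$genes,
    exome_mb = annot$exome_mb,
    n_train_samples = length(step1$m)
  ), class = "BMRModel")
}

#' @export
print.BMRModel <- function(x, ...) {
  cat("BMRModel:", length(x$genes), "genes,", x$n_train_samples,
      "training samples\n")
  cat("  dispersion alpha =", format(x$alpha, digits = 4),
      if (x$poisson_limit) "(Poisson limit)" else "", "\n")
  cat("  GLM beta =", paste(format(x$beta, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Expected background mutation counts per gene
#'
#' `E[y_g] = sum_s m[s] * lambda_star[g] * e_impact[g]` over the requested
#' samples.
#'
#' @param model fitted BMRModel
#' @param impact `"synonymous"` or `"nonsynonymous"`
#' @param samples sample ids (default: all training samples)
#' @return named numeric vector over the model's genes
#' @export
expected_counts <- function(model, impact = c("synonymous", "nonsynonymous"),
                            samples = NULL) {
  impact <- match.arg(impact)
  if (is.null(samples)) samples <- names(model$m)
  unknown <- setdiff(samples, names(model$m))
  if (length(unknown)) stop("unknown sample(s): ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  e <- if (impact == "synonymous") model$e_syn else model$e_nonsyn
  sum(model$m[samples]) * model$lambda_star * e
}

#' Per-gene driver statistics from the fitted background model
#'
#' For each gene the probability of observing at least the actual number
#' of non-synonymous mutations under the fitted NB background
#' (`mean = sum_s m[s] lambda_star[g] e_nonsyn[g]`, dispersion alpha),
#' with Benjamini-Hochberg adjusted q-values, plus the observed/expected
#' ratio over both impact classes used to rank genes for the TMB
#' gene-inclusion rule.
#'
#' @param model fitted BMRModel
#' @return data.frame (`gene`, `observed_syn`, `expected_syn`,
#'   `observed_nonsyn`, `expected_nonsyn`, `obs_exp_ratio`,
#'   `driver_pvalue`, `driver_qvalue`), one row per model gene.
#' @export
driver_statistic <- function(model) {
  stopifnot(inherits(model, "BMRModel"))
  exp_syn <- expected_counts(model, "synonymous")
  exp_nonsyn <- expected_counts(model, "nonsynonymous")
  y <- model$obs_nonsyn
  p <- ifelse(exp_nonsyn > 0,
              stats::pnbinom(y - 1L, size = model$alpha, mu = exp_nonsyn,
                             lower.tail = FALSE),
              as.numeric(y == 0))   # zero exposure: any observation -> p = 0
  q <- stats::p.adjust(p, method = "BH")
  denom <- exp_syn + exp_nonsyn
  ratio <- ifelse(denom > 0, (model$obs_syn + y) / denom, Inf)
  data.frame(gene = model$genes,
             observed_syn = as.integer(model$obs_syn),
             expected_syn = unname(exp_syn),
             observed_nonsyn = as.integer(y),
             expected_nonsyn = unname(exp_nonsyn),
             obs_exp_ratio = unname(ratio),
             driver_pvalue = unname(p),
             driver_qvalue = unname(q),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- serialization -----------------------------------------------------------

.fmt <- function(x) sprintf("%.17g", x)   # round-trips IEEE doubles exactly

#' Write a fitted BMRModel to a directory
#'
#' TSV tables for the vector parameters (context rates, sample rates,
#' per-gene multipliers/exposures) plus a JSON sidecar of scalars.
#' Numbers are written with 17 significant digits so the round trip is
#' bit-exact.
#'
#' @param model BMRModel
#' @param dir output directory (created if needed)
#' @export
write_bmr_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(data.frame(context = names(model$r), r = .fmt(model$r)),
    "context_rates.tsv")
  w(data.frame(sample_id = names(model$m), m = .fmt(model$m)), "samples.tsv")
  w(data.frame(gene = model$genes,
               lambda_glm = .fmt(model$lambda_glm),
               lambda_raw = .fmt(model$lambda_raw),
               lambda_star = .fmt(model$lambda_star),
               e_syn = .fmt(model$e_syn),
               e_nonsyn = .fmt(model$e_nonsyn),
               obs_syn = model$obs_syn,
               obs_nonsyn = model$obs_nonsyn), "genes.tsv")
  # numeric scalars as %.17g strings: JSON emitters round below the 17
  # significant digits a double needs to survive a round trip
  scal <- list(beta = .fmt(model$beta), beta_se = .fmt(model$beta_se),
               alpha = .fmt(model$alpha), poisson_limit = model$poisson_limit,
               exome_mb = .fmt(model$exome_mb),
               n_train_samples = model$n_train_samples)
  jsonlite::write_json(scal, file.path(dir, "scalars.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a BMRModel written by [write_bmr_model()]
#' @param dir model directory
#' @return BMRModel
#' @export
read_bmr_model <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  ctx <- rd("context_rates.tsv")
  smp <- rd("samples.tsv")
  gen <- rd("genes.tsv")
  scal <- jsonlite::read_json(file.path(dir, "scalars.json"),
                              simplifyVector = TRUE)
  nv <- function(x, n) stats::setNames(as.numeric(x), n)
  coef_names <- c("intercept", "log_expression", "replication_timing")
  structure(list(
    r = nv(ctx$r, ctx$context),
    m = nv(smp$m, smp$sample_id),
    beta = nv(scal$beta, coef_names),
    beta_se = nv(scal$beta_se, coef_names),
    alpha = as.numeric(scal$alpha),
    poisson_limit = isTRUE(scal$poisson_limit),
    lambda_glm = nv(gen$lambda_glm, gen$gene),
    lambda_raw = nv(gen$lambda_raw, gen$gene),
    lambda_star = nv(gen$lambda_star, gen$gene),
    e_syn = nv(gen$e_syn, gen$gene),
    e_nonsyn = nv(gen$e_nonsyn, gen$gene),
    obs_syn = stats::setNames(as.integer(gen$obs_syn), gen$gene),
    obs_nonsyn = stats::setNames(as.integer(gen$obs_nonsyn), gen$gene),
    genes = gen$gene,
    exome_mb = as.numeric(scal$exome_mb),
    n_train_samples = scal$n_train_samples
  ), class = "BMRModel")
}
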