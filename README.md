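# ectmb

Estimation and classification of tumor mutational burden (TMB) with an
explicit background mutation model.

## The problem

TMB — somatic non-synonymous mutations per megabase of sequenced coding
territory — predicts response to immune-checkpoint therapy. The reference
measurement counts mutations on a whole exome, but clinical assays sequence
targeted panels of 0.4–1.1 Mb that are deliberately enriched for cancer
driver genes. Because driver mutations are under positive selection, naive
counting on a panel over-estimates TMB (regression slope ~1.4–1.5 against
exome TMB); filtering against a hotspot database removes the bias but adds
variance and a database dependency. This package is for method developers
and bioinformaticians who need a panel-robust TMB estimate, and ships a
synthetic-cohort simulator so the entire pipeline is testable without any
external data.

## The model

A three-step background mutation model, trained on a whole-exome cohort:

1. **Context and sample rates.** Background SNV counts factorize as
   μ\_gsc = m\_s · λ\_g · r\_c · n\_gc: a sample rate m\_s, a gene multiplier
   λ\_g, a relative rate r\_c for each of the 96 pyrimidine-centered
   trinucleotide contexts, and the gene's count n\_gc of possible changes in
   that context (its *exposure*). r and m are estimated from synonymous
   mutations, which are assumed selectively neutral.
2. **Covariate GLM.** Per-gene synonymous totals are pooled in a
   negative-binomial log-link regression on log expression and replication
   timing, offset by the step-1 exposure; a shared NB dispersion α
   (variance = μ + μ²/α) is profiled at the fitted means.
3. **Conjugate consolidation.** Each gene's final multiplier is the exact
   Gamma–Poisson posterior mean λ\*\_g = (α + y\_g)/(α/λ\_glm,g + E\_g) —
   shrinkage between the pooled GLM prediction and the raw per-gene rate.

A new sample's TMB comes from 1-D maximum likelihood over its background
rate m, modeling each covered gene as an independent negative binomial with
mean m · λ\*\_g · ē\_g, where ē\_g counts the gene's synonymous exposure plus
— for genes below the driver-suspect cutoff of the observed/expected
ranking — its non-synonymous exposure. The concave log-likelihood is solved
by root finding on log m, and m̂ converts to mut/Mb via the whole-exome
expected non-synonymous background count.

Samples are classified into TMB-low / TMB-high / TMB-extreme by a Gaussian
mixture on log10(TMB + 0.1) fitted by EM (K chosen by BIC among 1–3), with
assignment scores computed with equal component weights by default. An
evaluation battery (Spearman/R²/MAE/RMSE/slope/σ, Bland–Altman bias and
limits of agreement, threshold sweeps, Cohen's kappa, Fisher exact subtype
characterization) mirrors how such methods are compared against exome TMB.

## Worked example

```r
library(ectmb)

sim   <- simulate_cohort(sim_config(seed = 1))     # 2000 genes, 300 samples
model <- fit_bmr(sim$muts, sim$annot, sim$covariates)
model
#> BMRModel: 2000 genes, 300 training samples
#>   dispersion alpha = 9.749
#>   GLM beta = -1.293,  0.522, -0.288

rule  <- select_included_genes(driver_statistic(model), 0.99)
panel <- simulate_biased_panel(sim, enrichment = 10, target_mb = 1)
pred  <- predict_cohort(sim$muts, model, sim$annot, rule, panel = panel)
```

Comparing each method's panel TMB against the simulated truth
(`agreement_metrics()` slope, `bland_altman()` bias):

```
counting           slope 1.44  bias  58.40  spearman 0.976
counting_filtered  slope 1.44  bias  58.40  spearman 0.976
ectmb              slope 1.00  bias  -0.10  spearman 0.973
```

Counting on the driver-enriched 1 Mb panel over-estimates TMB by ~44%
(no hotspot list was supplied here, so filtered counting is identical);
the model-based estimate stays calibrated. Classifying the cohort:

```r
gmm <- fit_gmm(sim$truth$samples$tmb, K = "auto", seed = 1)
gmm
#> GMMModel: K = 3 components on log10(TMB + 0.1)
#>     label        pi       mu     sigma2
#> 1     low 0.6102923 1.201288 0.04019748
#> 2    high 0.2413942 2.039219 0.02717998
#> 3 extreme 0.1483135 2.738630 0.06585400

asn <- assign_subtype(sim$truth$samples$tmb, gmm)
mean(asn$subtype == sim$truth$samples$class)
#> [1] 0.9633333
```

The three recovered components are the TMB-low, MMR-deficient TMB-high and
POLE-driven TMB-extreme classes the simulator plants.

A command-line interface wrapping the same functions is installed at
`inst/cli/ectmb` (subcommands `simulate`, `annotate`, `train`, `predict`,
`classify`, `evaluate`).

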