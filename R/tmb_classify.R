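# Gaussian mixture classification of log-transformed TMB into
# TMB-low / TMB-high / TMB-extreme subtypes.

SUBTYPE_LABELS <- c("low", "high", "extreme")

.gmm_loglik <- function(y, pi, mu, sigma2) {
  dens <- vapply(seq_along(pi), function(k) {
    pi[k] * stats::dnorm(y, mu[k], sqrt(sigma2[k]))
  }, numeric(length(y)))
  if (length(y) == 1L) dens <- matrix(dens, nrow = 1L)
  sum(log(rowSums(dens)))
}

.gmm_em <- function(y, K, mu0, max_iter = 500L, tol = 1e-8,
                    var_floor = 1e-10) {
  n <- length(y)
  pi <- rep(1 / K, K)
  mu <- mu0
  sigma2 <- rep(stats::var(y) + var_floor, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E step
    logd <- vapply(seq_len(K), function(k) {
      log(pi[k]) + stats::dnorm(y, mu[k], sqrt(sigma2[k]), log = TRUE)
    }, numeric(n))
    if (n == 1L) logd <- matrix(logd, nrow = 1L)
    mx <- apply(logd, 1, max)
    w <- exp(logd - mx)
    gamma <- w / rowSums(w)
    ll <- sum(mx + log(rowSums(w)))
    ll_trace <- c(ll_trace, ll)
    # M step
    nk <- colSums(gamma)
    if (any(nk < 1e-8)) return(NULL)     # empty component: degenerate start
    pi <- nk / n
    mu <- colSums(gamma * y) / nk
    sigma2 <- colSums(gamma * (outer(y, mu, "-")^2)) / nk
    if (any(sigma2 < var_floor)) return(NULL)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(pi = pi, mu = mu, sigma2 = sigma2, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, n_iter = length(ll_trace))
}

#' Fit a Gaussian mixture to log-transformed TMB
#'
#' TMB values are transformed as `y = log10(tmb + p0)` (the pseudocount
#' keeps zero-TMB samples finite) and fitted by EM.  Initial means are
#' quantile-spaced with random jitter across restarts; the best-likelihood
#' non-degenerate solution is kept.  `K = "auto"` selects the number of
#' components among 1-3 by BIC.  Components are sorted by mean and
#' labeled low / high / extreme.
#'
#' @param tmb non-negative TMB values (mut/Mb), length >= 10
#' @param K integer number of components, or `"auto"`
#' @param p0 pseudocount in mut/Mb before the log10 transform
#' @param n_restarts EM restarts per K
#' @param seed integer seed for the restart jitter (RNG state is restored)
#' @return object of class `GMMModel`: `K`, `pi`, `mu`, `sigma2`, `labels`,
#'   `p0`, `loglik`, `loglik_trace`, `bic`
#' @export
fit_gmm <- function(tmb, K = "auto", p0 = 0.1, n_restarts = 20L, seed = 1L) {
  if (length(tmb) < 10L) stop("need at least 10 samples")
  if (any(tmb < 0)) stop("negative TMB")
  y <- log10(tmb + p0)
  if (!all(is.finite(y))) stop("non-finite transformed TMB")
  Ks <- if (identical(K, "auto")) 1:3 else as.integer(K)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  best_by_k <- list()
  for (k in Ks) {
    qs <- stats::quantile(y, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    spread <- max(stats::sd(y), 1e-3)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      mu0 <- if (r == 1L) qs else qs + stats::rnorm(k, 0, spread / 4)
      fit <- .gmm_em(y, k, sort(mu0))
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
      if (k == 1L) break   # EM for one component is deterministic
    }
    if (is.null(best)) {
      if (length(Ks) == 1L) stop("all EM restarts degenerate for K = ", k)
      next
    }
    npar <- 3L * k - 1L
    best$bic <- -2 * best$loglik + npar * log(length(y))
    best$K <- k
    best_by_k[[as.character(k)]] <- best
  }
  if (!length(best_by_k)) stop("no non-degenerate mixture fit found")
  bics <- vapply(best_by_k, `[[`, numeric(1), "bic")
  sel <- best_by_k[[which.min(bics)]]
  ord <- order(sel$mu)
  structure(list(K = sel$K, pi = sel$pi[ord], mu = sel$mu[ord],
                 sigma2 = sel$sigma2[ord],
                 labels = SUBTYPE_LABELS[seq_len(sel$K)], p0 = p0,
                 loglik = sel$loglik, loglik_trace = sel$loglik_trace,
                 bic = sel$bic), class = "GMMModel")
}

#' @export
print.GMMModel <- function(x, ...) {
  cat("GMMModel: K =", x$K, "components on log10(TMB +", x$p0, ")\n")
  print(data.frame(label = x$labels, pi = x$pi, mu = x$mu,
                   sigma2 = x$sigma2))
  invisible(x)
}

#' Assign samples to TMB subtypes with the mixture's assignment score
#'
#' For each sample the per-component assignment score is the normalized
#' component density.  By default every component weight is set to 1
#' before normalization (equal-weight assignment compensates the
#' under-representation of hypermutated samples in training cohorts);
#' `use_weights = TRUE` uses the fitted mixing proportions instead.
#' Ties go to the lower-mean component.
#'
#' @param tmb TMB values in mut/Mb (or log-transformed values with
#'   `log_input = TRUE`)
#' @param model GMMModel
#' @param use_weights use fitted mixing proportions in the score
#' @param log_input `tmb` is already `log10(tmb + p0)`
#' @return data.frame with `subtype` and one `gamma_<label>` score column
#'   per component (rows sum to 1)
#' @export
assign_subtype <- function(tmb, model, use_weights = FALSE,
                           log_input = FALSE) {
  stopifnot(inherits(model, "GMMModel"))
  y <- if (log_input) tmb else log10(tmb + model$p0)
  if (any(!is.finite(y))) stop("non-finite log-TMB value(s)")
  wts <- if (use_weights) model$pi else rep(1, model$K)
  dens <- vapply(seq_len(model$K), function(k) {
    wts[k] * stats::dnorm(y, model$mu[k], sqrt(model$sigma2[k]))
  }, numeric(length(y)))
  if (length(y) == 1L) dens <- matrix(dens, nrow = 1L)
  gamma <- dens / rowSums(dens)
  # argmax with ties toward the lower-mean (first) component
  pick <- apply(gamma, 1, function(g) which(g >= max(g) - 1e-12)[1])
  out <- data.frame(subtype = model$labels[pick], stringsAsFactors = FALSE)
  for (k in seq_len(model$K)) out[[paste0("gamma_", model$labels[k])]] <-
    gamma[, k]
  out
}

#' Classify TMB by a fixed threshold
#'
#' @param tmb TMB values (mut/Mb)
#' @param threshold positive cutoff; values `>= threshold` are "high"
#' @return character vector of "low"/"high"
#' @export
classify_by_threshold <- function(tmb, threshold) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  ifelse(tmb >= threshold, "high", "low")
}

#' Write a GMMModel to JSON
#' @param model GMMModel
#' @param path output file
#' @export
write_gmm <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, pi = model$pi, mu = model$mu, sigma2 = model$sigma2,
         labels = model$labels, p0 = model$p0, loglik = model$loglik),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GMMModel from JSON
#' @param path file written by [write_gmm()]
#' @return GMMModel
#' @export
read_gmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(K = as.integer(x$K), pi = x$pi, mu = x$mu,
                 sigma2 = x$sigma2, labels = x$labels, p0 = x$p0,
                 loglik = x$loglik, loglik_trace = NULL, bic = NULL),
            class = "GMMModel")
}
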