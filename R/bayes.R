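#' Prior specification for the liability regression
#'
#' Flat prior on the intercept; `beta_j ~ N(0, w_j sigma2)` with
#' per-variant weights `w_j`; `sigma2 ~ ScaledInvChi2(nu, S2)`. The
#' liability threshold is fixed at 0 and the error variance at 1 for
#' identifiability.
#'
#' @param nu Prior degrees of freedom for `sigma2` (default 0.1).
#' @param S2 Prior scale for `sigma2` (default 0.1).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(nu = 0.1, S2 = 0.1) {
  if (nu <= 0 || S2 <= 0) stop("`nu` and `S2` must be > 0", call. = FALSE)
  structure(list(nu = nu, S2 = S2), class = "prior_spec")
}

#' MCMC settings for the Gibbs sampler
#'
#' @param n_iter Total Gibbs iterations (default 100000).
#' @param burn_in Discarded initial iterations (default 50000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 50).
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(n_iter = 100000L, burn_in = 50000L, thin = 50L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("`burn_in` must be < `n_iter`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "mcmc_settings")
}

#' Fit the weighted Bayesian multi-variant liability regression
#'
#' Runs a single Gibbs chain for the probit liability model with
#' per-variant shrinkage priors `beta_j ~ N(0, w_j sigma2)` and returns
#' per-variant posterior summaries. Initialization is `mu = 0`, `beta = 0`,
#' `sigma2 = S2`, with latent liabilities drawn from the truncated normal
#' consistent with the observed status. Chains are reproducible given
#' `set.seed()`.
#'
#' @param genotypes n x p minor-allele-count matrix (0/1/2).
#' @param status 0/1 disease status vector.
#' @param weights Per-variant prior weights in (0, 1]; a numeric vector, a
#'   `weight_vector` from [build_weights()], or `NULL` for all 1
#'   (no-weight scheme).
#' @param settings An [mcmc_settings()] object.
#' @param prior A [prior_spec()] object.
#' @param store_chains Keep thinned `sigma2` and `beta` draws (for
#'   diagnostics; memory scales with retained draws x p).
#' @return A `bvlr_fit`: list with `summary` (data.frame: id, post_mean,
#'   post_sd, z), `n_retained`, `mu_mean`, `settings`, `prior`, and
#'   optionally `sigma2_chain` / `beta_chain`.
#' @export
fit_bayes <- function(genotypes, status, weights = NULL,
                      settings = mcmc_settings(), prior = prior_spec(),
                      store_chains = FALSE) {
  X <- as.matrix(genotypes)
  storage.mode(X) <- "integer"
  status <- as.integer(status)
  if (ncol(X) < 1L) stop("candidate matrix is empty", call. = FALSE)
  if (length(unique(status)) < 2L)
    stop("both phenotype classes must be present", call. = FALSE)
  if (inherits(weights, "weight_vector")) weights <- weights$w
  if (is.null(weights)) weights <- rep(1, ncol(X))
  if (length(weights) != ncol(X) || any(weights <= 0))
    stop("`weights` must be positive, one per variant", call. = FALSE)
  res <- .gibbs_probit_cpp(X, status, as.numeric(weights),
                           prior$nu, prior$S2,
                           settings$n_iter, settings$burn_in, settings$thin,
                           0, rep(0, ncol(X)), prior$S2,
                           TRUE, TRUE, TRUE, store_chains)
  sd0 <- res$post_sd == 0
  if (any(sd0))
    warning(sum(sd0), " variant(s) had zero posterior SD; z set to 0")
  z <- ifelse(sd0, 0, res$post_mean / res$post_sd)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(X)))
  out <- list(summary = data.frame(id = ids, post_mean = res$post_mean,
                                   post_sd = res$post_sd, z = z,
                                   stringsAsFactors = FALSE),
              n_retained = res$n_retained, mu_mean = res$mu_mean,
              state = res$state, settings = settings, prior = prior)
  if (store_chains) {
    out$sigma2_chain <- res$sigma2_chain
    out$beta_chain <- res$beta_chain
  }
  class(out) <- "bvlr_fit"
  out
}

#' @export
print.bvlr_fit <- function(x, ...) {
  cat("Bayesian liability regression fit:", nrow(x$summary), "variants,",
      x$n_retained, "retained draws\n")
  top <- x$summary[order(-abs(x$summary$z)), ][seq_len(min(5, nrow(x$summary))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Maximum absolute standardized effect
#'
#' The family test statistic of the Bayesian method: `max_j |z_j|` with
#' `z_j` the posterior mean of `beta_j` divided by its posterior SD.
#'
#' @param fit A `bvlr_fit` or its `summary` data.frame.
#' @return A scalar.
#' @export
max_abs_z <- function(fit) {
  s <- if (inherits(fit, "bvlr_fit")) fit$summary else fit
  if (nrow(s) == 0L) stop("empty posterior summary", call. = FALSE)
  max(abs(s$z))
}

# Advance the Gibbs kernel `k` scans from a given state (used by the
# successive-conditional sampler correctness checks). The intercept can be
# held fixed because its flat prior is improper.
gibbs_advance <- function(X, status, weights, prior, state, k = 1L,
                          update_mu = FALSE) {
  res <- .gibbs_probit_cpp(X, as.integer(status), weights, prior$nu,
                           prior$S2, k, 0L, max(k, 1L),
                           state$mu, state$beta, state$sigma2,
                           update_mu, TRUE, TRUE, FALSE)
  res$state
}

#' Draw from a scaled inverse chi-square distribution
#'
#' `sigma2 = df * scale / chisq_df`; the conjugate family for a normal
#' variance.
#'
#' @param n Number of draws.
#' @param df Degrees of freedom.
#' @param scale Scale parameter.
#' @return Numeric vector of draws.
#' @export
rscaled_inv_chisq <- function(n, df, scale) {
  df * scale / stats::rchisq(n, df)
}
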