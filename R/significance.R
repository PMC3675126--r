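#' Random phenotype permutation
#'
#' Shuffles case/control statuses uniformly across individuals while
#' genotypes stay fixed, conserving LD structure under the null.
#'
#' @param status 0/1 status vector.
#' @return Permuted status vector (class counts preserved).
#' @export
permute_status <- function(status) {
  status[sample.int(length(status))]
}

# Permutation p-values: p_j = (B0_j + 1)/(B + 1), B0_j = number of null
# family statistics at least as extreme as the observed t_j. `larger_extreme`
# says whether extreme means large (|z|) or small (p-values).
perm_pvalue <- function(t_obs, null_stats, larger_extreme = TRUE) {
  B <- length(null_stats)
  b0 <- if (larger_extreme) {
    vapply(t_obs, function(t) sum(null_stats >= t), numeric(1))
  } else {
    vapply(t_obs, function(t) sum(null_stats <= t), numeric(1))
  }
  (b0 + 1) / (B + 1)
}

#' Permutation-based family-wise significance test
#'
#' Computes per-variant observed statistics on the unshuffled data
#' (single-variant test: the genotypic-test p-value; Bayesian model: the
#' absolute standardized effect |z|), then recomputes the family statistic
#' (min p over variants, or max |z|) on `B` phenotype shuffles. Each
#' variant's permutation p-value is `(B0 + 1)/(B + 1)` where `B0` counts
#' null family statistics at least as extreme as the variant's own
#' statistic (single-step min-p / max-z procedure; ties count as extreme).
#'
#' @param cohort A `cohort` (typically after [candidate_filter()]).
#' @param method `"svt"` (single-variant genotypic test) or `"bayes"`.
#' @param B Number of permutations (default 500).
#' @param alpha Family-wise significance threshold (default 0.01).
#' @param weights Prior weights for the Bayesian method (see [fit_bayes()]).
#' @param settings [mcmc_settings()] for the observed-data Bayesian fit.
#' @param perm_settings [mcmc_settings()] used for the permutation refits;
#'   defaults to `settings`. Reduced settings trade permutation-null
#'   precision for speed.
#' @param prior [prior_spec()] for the Bayesian method.
#' @return A `permutation_result`: list with `method`, `statistic`
#'   (per-variant observed statistic), `null_stats` (B family statistics),
#'   `perm_p`, `significant` (logical at `alpha`), `B`, `alpha`, and the
#'   per-variant table `table`.
#' @export
permutation_test <- function(cohort, method = c("svt", "bayes"), B = 500L,
                             alpha = 0.01, weights = NULL,
                             settings = mcmc_settings(),
                             perm_settings = settings,
                             prior = prior_spec()) {
  method <- match.arg(method)
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  X <- cohort$genotypes
  status <- cohort$status
  n <- length(status)

  if (method == "svt") {
    # columns of case_mat: observed status then B shuffles
    case_mat <- matrix(0, n, B + 1L)
    case_mat[, 1] <- status
    for (b in seq_len(B) + 1L) case_mat[sample.int(n), b] <- status
    res <- svt_pvalues_multi(X, case_mat)
    t_obs <- res$p[, 1]
    null_stats <- apply(res$p[, -1, drop = FALSE], 2, min)
    perm_p <- perm_pvalue(t_obs, null_stats, larger_extreme = FALSE)
    statistic <- t_obs
  } else {
    fit <- fit_bayes(X, status, weights = weights, settings = settings,
                     prior = prior)
    statistic <- abs(fit$summary$z)
    null_stats <- numeric(B)
    for (b in seq_len(B)) {
      fb <- fit_bayes(X, permute_status(status), weights = weights,
                      settings = perm_settings, prior = prior)
      null_stats[b] <- max_abs_z(fb)
    }
    perm_p <- perm_pvalue(statistic, null_stats, larger_extreme = TRUE)
  }

  structure(list(method = method, statistic = statistic,
                 null_stats = null_stats, perm_p = perm_p,
                 significant = perm_p <= alpha, B = B, alpha = alpha,
                 table = data.frame(id = cohort$variants$id,
                                    chrom = cohort$variants$chrom,
                                    causal = cohort$variants$causal,
                                    statistic = statistic, perm_p = perm_p,
                                    significant = perm_p <= alpha,
                                    stringsAsFactors = FALSE)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", x$method, "): B = ", x$B, ", alpha = ", x$alpha,
      "; ", sum(x$significant), " of ", length(x$significant),
      " variants significant\n", sep = "")
  invisible(x)
}
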