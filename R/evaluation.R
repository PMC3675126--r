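#' Study configuration for the two-stage simulation pipeline
#'
#' Bundles every tunable of the pipeline: pool simulation, dominant disease
#' model, GWAS and sequencing cohort sizes, candidate MAF bounds, weighting,
#' MCMC settings and the permutation budget.
#'
#' @param sim [sim_params()] for the haplotype pool (the seed field is
#'   overridden per replicate).
#' @param grr,baseline_risk Dominant disease model parameters.
#' @param k_causal Number of causal sites per replicate.
#' @param n_gwas_cases,n_gwas_controls GWAS-stage cohort quotas.
#' @param n_cases,n_controls Sequencing-stage cohort quotas.
#' @param maf_low,maf_high Candidate sample-MAF bounds (half-open).
#' @param gwas_maf_gt,gwas_alpha Common-SNP MAF threshold and significance
#'   level of the GWAS scan.
#' @param B,alpha Permutation count and family-wise threshold.
#' @param settings,perm_settings [mcmc_settings()] for observed-data and
#'   permutation Bayesian fits.
#' @param prior [prior_spec()].
#' @param max_pool_tries Pools regenerated (next derived seed) when fewer
#'   than `k_causal` sites qualify in a requested MAF interval.
#' @return A `study_config` object.
#' @export
study_config <- function(sim = sim_params(),
                         grr = 3, baseline_risk = 0.01, k_causal = 3L,
                         n_gwas_cases = 3000L, n_gwas_controls = 3000L,
                         n_cases = 500L, n_controls = 500L,
                         maf_low = 0.002, maf_high = 0.05,
                         gwas_maf_gt = 0.05, gwas_alpha = 1e-8,
                         B = 500L, alpha = 0.01,
                         settings = mcmc_settings(),
                         perm_settings = settings,
                         prior = prior_spec(),
                         max_pool_tries = 8L) {
  structure(as.list(environment()), class = "study_config")
}

method_label <- function(m) {
  if (m$method == "svt") "svt" else paste0("bayes_", m$scheme)
}

needs_weights <- function(methods) {
  any(vapply(methods, function(m) {
    m$method == "bayes" && m$scheme %in% c("r", "phastcons", "r_x_phastcons")
  }, logical(1)))
}

pool_qualifies <- function(pool, intervals, k) {
  reg <- central_region(pool$params$chrom_lengths[1])
  ok <- pool$sites$chrom == "causal" &
    pool$sites$pos >= reg[["lower"]] & pool$sites$pos <= reg[["upper"]]
  mafs <- pool$sites$maf[ok]
  all(vapply(intervals, function(iv) {
    sum(mafs >= iv[1] & mafs < iv[2]) >= k
  }, logical(1)))
}

# One (pool, interval) analysis: disease model, cohorts, candidate filter,
# weights if needed, then every requested method. Returns a
# `replicate_result`.
analyze_pool_interval <- function(pool, maf_interval, methods, config) {
  causal <- select_causal_sites(pool, maf_interval, config$k_causal)
  model <- disease_model(causal, config$grr, config$baseline_risk)
  seq_cohort <- sample_case_control(pool, model, config$n_cases,
                                    config$n_controls)
  cand <- candidate_filter(seq_cohort, config$maf_low, config$maf_high)
  causal_ids <- variant_ids(pool$sites)[causal$site_indices]

  components <- NULL
  if (needs_weights(methods)) {
    gwas <- sample_case_control(pool, model, config$n_gwas_cases,
                                config$n_gwas_controls)
    signals <- gwas_scan(gwas, config$gwas_maf_gt, config$gwas_alpha)
    ref <- gwas$genotypes[gwas$status == 0L, , drop = FALSE]
    cand_cols <- match(cand$variants$id, colnames(ref))
    r <- r_weight(ref[, cand_cols, drop = FALSE],
                  ref[, signals, drop = FALSE])
    pc3 <- sample_synthetic_phastcons(cand$variants$causal)
    components <- data.frame(
      r = r,
      vert = pc3$vert, mamm = pc3$mamm, prim = pc3$prim,
      composite = composite_phastcons(pc3$vert, pc3$mamm, pc3$prim))
    rm(gwas)
  }

  per_method <- lapply(methods, function(m) {
    if (m$method == "svt") {
      pr <- permutation_test(cand, "svt", B = config$B, alpha = config$alpha)
    } else {
      w <- if (m$scheme == "none") NULL else build_weights(components, m$scheme)
      pr <- permutation_test(cand, "bayes", B = config$B,
                             alpha = config$alpha, weights = w,
                             settings = config$settings,
                             perm_settings = config$perm_settings,
                             prior = config$prior)
    }
    sig_ids <- cand$variants$id[pr$significant]
    noncausal <- !cand$variants$causal
    on_causal <- cand$variants$chrom == "causal"
    list(label = method_label(m),
         significant = sig_ids,
         detected_causal = intersect(sig_ids, causal_ids),
         fp_causal_chrom = sum(pr$significant & noncausal & on_causal),
         n_noncausal_causal_chrom = sum(noncausal & on_causal),
         fp_null_chrom = sum(pr$significant & noncausal & !on_causal),
         n_noncausal_null_chrom = sum(noncausal & !on_causal))
  })
  names(per_method) <- vapply(per_method, `[[`, character(1), "label")

  structure(list(maf_interval = maf_interval, causal_ids = causal_ids,
                 n_candidates = ncol(cand$genotypes),
                 methods = per_method),
            class = "replicate_result")
}

#' Run one full simulation replicate
#'
#' Executes the full two-stage workflow once: coalescent pool, causal-site
#' selection in the requested MAF interval, sequencing cohort under the
#' dominant GRR model, candidate filtering, prior-weight construction when
#' the scheme needs it (GWAS cohort, scan, LD r and synthetic phastCons),
#' and the permutation significance test for both the single-variant and
#' the Bayesian method. Deterministic given `seed`.
#'
#' @param maf_interval `c(low, high)` causal MAF bounds.
#' @param scheme Weighting scheme for the Bayesian method (see
#'   [build_weights()]).
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @param methods Which methods to run; default both. Each element is a
#'   list with `method` (`"svt"`/`"bayes"`) and, for Bayes, `scheme`.
#' @return A `replicate_result`: causal variant ids, per-method significant
#'   sets and false-positive counts, and the candidate count.
#' @export
run_replicate <- function(maf_interval, scheme = "none",
                          config = study_config(), seed = 1L,
                          methods = list(list(method = "svt"),
                                         list(method = "bayes",
                                              scheme = scheme))) {
  set.seed(seed)
  pool <- simulate_qualifying_pool(list(maf_interval), config)
  analyze_pool_interval(pool, maf_interval, methods, config)
}

simulate_qualifying_pool <- function(intervals, config) {
  for (try in seq_len(config$max_pool_tries)) {
    params <- config$sim
    params$seed <- sample.int(2147483040L, 1L)
    pool <- simulate_pool(params)
    if (pool_qualifies(pool, intervals, config$k_causal)) return(pool)
  }
  stop("no qualifying pool after ", config$max_pool_tries, " tries",
       call. = FALSE)
}

#' Run a replicated power study
#'
#' Orchestrates `n_replicates` independent replicates. Within a replicate
#' one haplotype pool is shared across all requested causal-MAF intervals
#' (cohorts, causal sites, weights and tests are re-drawn per interval);
#' a pool that cannot supply `k_causal` qualifying sites for every interval
#' is regenerated with the next derived seed.
#'
#' @param maf_intervals List of `c(low, high)` causal MAF intervals.
#' @param methods List of method specifications (see [run_replicate()]).
#' @param n_replicates Number of replicates.
#' @param config A [study_config()].
#' @param seed Integer seed governing all randomness.
#' @param progress Print per-replicate progress lines.
#' @return List of `replicate_result` lists, one element per replicate,
#'   each a list over intervals; pass to [power_report()].
#' @export
run_study <- function(maf_intervals, methods = list(list(method = "svt")),
                      n_replicates = 50L, config = study_config(),
                      seed = 1L, progress = FALSE) {
  set.seed(seed)
  if (!is.list(maf_intervals[[1]]) && !is.numeric(maf_intervals[[1]]))
    stop("`maf_intervals` must be a list of c(low, high)", call. = FALSE)
  results <- vector("list", n_replicates)
  r <- 0L
  while (r < n_replicates) {
    # batch pool generation amortizes simulator start-up; files are read
    # and deleted one pool at a time to bound disk and memory use
    m <- min(10L, n_replicates - r)
    params <- config$sim
    params$seed <- sample.int(2147483040L, 1L)
    dir <- simulate_pool_files(params, n = m)
    for (i in seq_len(m)) {
      pool <- read_pool(dir, i, params)
      unlink(file.path(dir, sprintf("pool%d_%s.%s", i,
                                    rep(c("causal", "null"), 2),
                                    rep(c("sites", "bin"), each = 2))))
      if (!pool_qualifies(pool, maf_intervals, config$k_causal))
        pool <- simulate_qualifying_pool(maf_intervals, config)
      r <- r + 1L
      results[[r]] <- lapply(maf_intervals, function(iv)
        analyze_pool_interval(pool, iv, methods, config))
      rm(pool)
      if (progress) message("replicate ", r, "/", n_replicates, " done")
    }
    unlink(dir, recursive = TRUE)
  }
  results
}

#' Summarize power and false positive rates over replicates
#'
#' @param results Output of [run_study()] (or a list of `replicate_result`
#'   objects for a single interval).
#' @param interval_index Which interval of each replicate to summarize
#'   (ignored for flat lists of `replicate_result`).
#' @param method Method label, e.g. `"svt"`, `"bayes_none"`.
#' @return A `power_report`: list with `per_variant` power (detection
#'   proportion of each causal slot, in site order), `p_at_least_1`,
#'   `p_at_least_2`, `p_all`, `average` power, `fpr_causal_chrom`,
#'   `fpr_null_chrom` (replicate-averaged fractions), `mean_candidates` and
#'   `n_replicates`.
#' @export
power_report <- function(results, method = "svt", interval_index = 1L) {
  reps <- lapply(results, function(x) {
    if (inherits(x, "replicate_result")) x else x[[interval_index]]
  })
  k <- length(reps[[1]]$causal_ids)
  det <- t(vapply(reps, function(rr) {
    rr$causal_ids %in% rr$methods[[method]]$detected_causal
  }, logical(k)))
  n_det <- rowSums(det)
  fpr <- vapply(reps, function(rr) {
    m <- rr$methods[[method]]
    c(causal = if (m$n_noncausal_causal_chrom > 0)
        m$fp_causal_chrom / m$n_noncausal_causal_chrom else 0,
      null = if (m$n_noncausal_null_chrom > 0)
        m$fp_null_chrom / m$n_noncausal_null_chrom else 0)
  }, numeric(2))
  structure(list(per_variant = colMeans(det),
                 p_at_least_1 = mean(n_det >= 1),
                 p_at_least_2 = mean(n_det >= 2),
                 p_all = mean(n_det >= k),
                 average = mean(n_det / k),
                 fpr_causal_chrom = mean(fpr["causal", ]),
                 fpr_null_chrom = mean(fpr["null", ]),
                 mean_candidates = mean(vapply(reps, `[[`, numeric(1),
                                               "n_candidates")),
                 n_replicates = length(reps),
                 method = method),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("Power report (", x$method, ", ", x$n_replicates, " replicates)\n",
      sep = "")
  cat(sprintf("  average power     %.3f\n", x$average))
  cat(sprintf("  P(>=1 detected)   %.3f\n", x$p_at_least_1))
  cat(sprintf("  P(>=2 detected)   %.3f\n", x$p_at_least_2))
  cat(sprintf("  P(all detected)   %.3f\n", x$p_all))
  cat(sprintf("  FPR causal chrom  %.4f\n", x$fpr_causal_chrom))
  cat(sprintf("  FPR null chrom    %.4f\n", x$fpr_null_chrom))
  cat(sprintf("  mean candidates   %.1f\n", x$mean_candidates))
  invisible(x)
}
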