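#' Dominant disease model with genotypic relative risk
#'
#' Disease risk is `baseline_risk` for individuals carrying no copy of a
#' risk (minor) allele at any causal site and `baseline_risk * grr` for
#' carriers of one or more copies at one or more causal sites; the increase
#' is not multiplicative across loci.
#'
#' @param causal A `causal_spec` from [select_causal_sites()].
#' @param grr Genotypic relative risk (default 3).
#' @param baseline_risk Baseline disease probability (default 0.01).
#' @return A `disease_model` object.
#' @export
disease_model <- function(causal, grr = 3, baseline_risk = 0.01) {
  stopifnot(inherits(causal, "causal_spec"))
  if (baseline_risk <= 0 || baseline_risk * grr > 1)
    stop("need 0 < baseline_risk and baseline_risk * grr <= 1", call. = FALSE)
  structure(list(causal = causal, grr = grr, baseline_risk = baseline_risk,
                 mode = "dominant"),
            class = "disease_model")
}

#' Disease risk of one individual
#'
#' @param genotype_row Integer vector of minor-allele counts covering all
#'   pool sites (or at least the causal sites, indexed as in the pool).
#' @param model A [disease_model()].
#' @return The individual's disease probability.
#' @export
assign_risk <- function(genotype_row, model) {
  carrier <- any(genotype_row[model$causal$site_indices] > 0)
  if (carrier) model$baseline_risk * model$grr else model$baseline_risk
}

# Carrier status (any causal minor allele) for a batch of individuals given
# haplotype index pairs; looks only at the causal columns, so rejection
# sampling stays cheap.
carrier_status <- function(pool, model, h1, h2) {
  Hc <- pool$haplotypes[, model$causal$site_indices, drop = FALSE]
  (rowSums(Hc[h1, , drop = FALSE]) + rowSums(Hc[h2, , drop = FALSE])) > 0
}

#' Sample a case/control cohort from the pool
#'
#' Forms individuals by drawing pairs of haplotypes uniformly with
#' replacement from the pool, assigns disease status Bernoulli with the
#' dominant-model risk, and rejection-samples until exactly `n_cases` cases
#' and `n_controls` controls are collected.
#'
#' @param pool A `haplotype_pool`.
#' @param model A [disease_model()].
#' @param n_cases,n_controls Required cohort composition.
#' @param max_draws Guard against non-termination (maximum individuals
#'   simulated before giving up).
#' @return A `cohort`: list with `genotypes` (n x p minor-allele-count
#'   matrix), `status` (0/1 vector, cases first), and `variants`
#'   (data.frame with id, chrom, pos, sample `maf`, `causal` flag).
#' @export
sample_case_control <- function(pool, model, n_cases = 500L,
                                n_controls = 500L, max_draws = 5e6) {
  stopifnot(n_cases > 0L, n_controls > 0L)
  n_hap <- nrow(pool$haplotypes)
  case_idx <- matrix(integer(0), 0, 2)
  ctrl_idx <- matrix(integer(0), 0, 2)
  drawn <- 0
  # expected case rate ~ baseline_risk; draw in chunks sized accordingly
  chunk <- max(2000L, ceiling(1.5 * n_cases / model$baseline_risk / 4))
  while (nrow(case_idx) < n_cases || nrow(ctrl_idx) < n_controls) {
    if (drawn >= max_draws)
      stop("case/control quotas not met after ", drawn, " draws", call. = FALSE)
    m <- min(chunk, max_draws - drawn)
    h1 <- sample.int(n_hap, m, replace = TRUE)
    h2 <- sample.int(n_hap, m, replace = TRUE)
    risk <- ifelse(carrier_status(pool, model, h1, h2),
                   model$baseline_risk * model$grr, model$baseline_risk)
    dis <- stats::runif(m) < risk
    drawn <- drawn + m
    if (nrow(case_idx) < n_cases)
      case_idx <- rbind(case_idx, cbind(h1, h2)[dis, , drop = FALSE])
    if (nrow(ctrl_idx) < n_controls)
      ctrl_idx <- rbind(ctrl_idx, cbind(h1, h2)[!dis, , drop = FALSE])
  }
  case_idx <- case_idx[seq_len(n_cases), , drop = FALSE]
  ctrl_idx <- ctrl_idx[seq_len(n_controls), , drop = FALSE]
  idx <- rbind(case_idx, ctrl_idx)
  X <- pool$haplotypes[idx[, 1], , drop = FALSE] +
    pool$haplotypes[idx[, 2], , drop = FALSE]
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  new_cohort(X, status, pool$sites, model$causal$site_indices)
}

new_cohort <- function(X, status, sites, causal_sites = integer(0)) {
  f <- colMeans(X) / 2
  variants <- data.frame(
    id = variant_ids(sites),
    chrom = sites$chrom,
    pos = sites$pos,
    maf = pmin(f, 1 - f),
    pop_maf = sites$maf,
    causal = seq_len(nrow(sites)) %in% causal_sites,
    stringsAsFactors = FALSE)
  colnames(X) <- variants$id
  structure(list(genotypes = X, status = as.integer(status),
                 variants = variants),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", sum(x$status == 1), "cases /", sum(x$status == 0),
      "controls;", ncol(x$genotypes), "variants (",
      sum(x$variants$causal), "causal )\n")
  invisible(x)
}

#' Restrict a cohort to candidate variants by MAF
#'
#' Keeps variants whose MAF lies in `[maf_low, maf_high)`; monomorphic
#' columns are always dropped. Causal columns are retained only if they
#' pass the same filter.
#'
#' The MAF the filter acts on matters in a case/control sequencing sample:
#' cases are strongly over-sampled relative to a 1%-prevalence population,
#' so risk variants have inflated sample MAF -- a causal variant with
#' population MAF 4.5% typically exceeds 5% in a 500/500 cohort. Filtering
#' on the population ("pool") MAF therefore keeps the candidate set aligned
#' with the population frequency the causal variants were chosen by, and is
#' the default whenever population MAF metadata is available (simulated
#' cohorts); for cohorts loaded from files the sample MAF is used.
#'
#' @param cohort A `cohort`.
#' @param maf_low,maf_high Half-open MAF bounds (defaults 0.002 and 0.05).
#' @param basis `"auto"` (population MAF when available, else sample),
#'   `"pop"`, or `"sample"`.
#' @return The filtered `cohort`.
#' @export
candidate_filter <- function(cohort, maf_low = 0.002, maf_high = 0.05,
                             basis = c("auto", "pop", "sample")) {
  basis <- match.arg(basis)
  have_pop <- !is.null(cohort$variants$pop_maf) &&
    !anyNA(cohort$variants$pop_maf)
  if (basis == "auto") basis <- if (have_pop) "pop" else "sample"
  if (basis == "pop" && !have_pop)
    stop("population MAF metadata not available", call. = FALSE)
  f <- colMeans(cohort$genotypes) / 2
  maf <- pmin(f, 1 - f)
  fmaf <- if (basis == "pop") cohort$variants$pop_maf else maf
  keep <- maf > 0 & fmaf >= maf_low & fmaf < maf_high
  if (!any(keep))
    stop("no variant passes the candidate MAF filter", call. = FALSE)
  cohort$genotypes <- cohort$genotypes[, keep, drop = FALSE]
  cohort$variants <- cohort$variants[keep, , drop = FALSE]
  cohort$variants$maf <- maf[keep]
  rownames(cohort$variants) <- NULL
  cohort
}

#' Simulate liability-threshold phenotypes on fixed genotypes
#'
#' Exome-style phenotype simulation: genetic value `g = 1` for carriers of
#' a risk (minor) allele at any causal site, else 0; liability
#' `l = g + e` with `e ~ Normal(0, V_e)` and `V_e = V_g (1 - h2) / h2`
#' where `V_g` is the empirical variance of `g`. The sample median of `l`
#' splits the sample into equally many cases (above) and controls (below);
#' ties are broken by original order, lower half to controls.
#'
#' @param genotypes n x p minor-allele-count matrix.
#' @param causal_sites Column indices (or names) of the causal variants.
#' @param h2 Liability-scale heritability (default 0.10).
#' @return List with `status` (0/1, exactly `floor(n/2)` cases), `liability`,
#'   `g`, `V_g`, `V_e`, `h2`.
#' @export
simulate_liability_phenotypes <- function(genotypes, causal_sites, h2 = 0.10) {
  if (h2 <= 0 || h2 >= 1) stop("`h2` must be in (0, 1)", call. = FALSE)
  g <- as.numeric(rowSums(genotypes[, causal_sites, drop = FALSE] > 0) > 0)
  v_g <- stats::var(g)
  if (v_g == 0)
    stop("all individuals have the same genetic value; V_g = 0", call. = FALSE)
  v_e <- v_g * (1 - h2) / h2
  l <- g + stats::rnorm(length(g), 0, sqrt(v_e))
  n <- length(l)
  n_case <- n %/% 2L
  status <- integer(n)
  status[order(l, decreasing = TRUE)[seq_len(n_case)]] <- 1L
  list(status = status, liability = l, g = g, V_g = v_g, V_e = v_e, h2 = h2)
}
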