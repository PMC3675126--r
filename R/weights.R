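#' GWAS-stage scan for significant common-SNP signals
#'
#' Runs the single-variant genotypic test on every common SNP
#' (sample MAF > `maf_gt`) of a (typically large) GWAS cohort and returns
#' the indices of genome-wide-significant signals.
#'
#' @param gwas_cohort A `cohort`.
#' @param maf_gt Common-SNP MAF threshold; only variants with MAF strictly
#'   above it are tested (default 0.05). Population MAF is used when the
#'   cohort carries it (emulating array content chosen by population
#'   frequency), else sample MAF.
#' @param alpha Significance level (default 1e-8).
#' @return Integer vector of signal variant indices into
#'   `gwas_cohort$variants` (possibly empty).
#' @export
gwas_scan <- function(gwas_cohort, maf_gt = 0.05, alpha = 1e-8) {
  maf <- gwas_cohort$variants$pop_maf
  if (is.null(maf) || anyNA(maf)) maf <- gwas_cohort$variants$maf
  common <- which(maf > maf_gt)
  if (length(common) == 0L) return(integer(0))
  res <- svt_pvalues(gwas_cohort$genotypes[, common, drop = FALSE],
                     gwas_cohort$status)
  common[res$p < alpha]
}

#' LD-based r weight
#'
#' For each candidate variant, the maximum over GWAS signals of
#' `r = sqrt(r^2)`, where `r^2` is the squared genotype correlation between
#' candidate and signal computed in the LD reference sample (by convention
#' the GWAS controls). Values below 0.01 (including the no-signal and
#' undefined-correlation cases) are floored at 0.01.
#'
#' @param candidate_genotypes n_ref x p matrix of candidate genotypes in
#'   the LD reference sample.
#' @param signal_genotypes n_ref x s matrix of signal genotypes in the same
#'   sample (s may be 0).
#' @param floor Minimum weight value (default 0.01).
#' @return Numeric vector of r weights, one per candidate.
#' @export
r_weight <- function(candidate_genotypes, signal_genotypes, floor = 0.01) {
  p <- ncol(candidate_genotypes)
  if (is.null(signal_genotypes) || ncol(signal_genotypes) == 0L)
    return(rep(floor, p))
  r2 <- suppressWarnings(
    stats::cor(candidate_genotypes, signal_genotypes))^2
  r2[is.na(r2)] <- 0
  r <- sqrt(apply(r2, 1, max))
  r[!is.finite(r)] <- floor
  unname(pmax(r, floor))
}

#' Composite phastCons conservation score
#'
#' Weighted average of per-lineage phastCons scores,
#' `vert/2 + mamm/3 + prim/6`, floored at `floor`. Conservation over a
#' broader lineage scope gets more weight, reflecting stronger implied
#' functionality.
#'
#' @param vert,mamm,prim Vertebrate, mammal and primate phastCons scores in
#'   `[0, 1]` (vectorized).
#' @param floor Minimum composite value (default 0.01).
#' @return Numeric vector of composite scores.
#' @examples
#' composite_phastcons(0.16, 0.24, 0.95) # ~0.32
#' @export
composite_phastcons <- function(vert, mamm, prim, floor = 0.01) {
  vals <- c(vert, mamm, prim)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("phastCons components must lie in [0, 1]", call. = FALSE)
  pmax(vert / 2 + mamm / 3 + prim / 6, floor)
}

#' Synthetic per-lineage phastCons scores
#'
#' Stand-in sampling distributions for simulation studies: causal variants
#' draw each lineage score from a conservation-skewed Beta mixture
#' (`0.9 Beta(8, 1) + 0.1 Beta(1, 1)`, most mass near 1) and non-causal
#' variants from a background mixture
#' (`0.85 Beta(1, 20) + 0.15 Beta(3, 3)`, most mass near 0 with a
#' moderate-conservation tail). These are documented synthetic stand-ins,
#' not empirical phastCons distributions of any variant database.
#'
#' @param is_causal Logical vector, one entry per variant.
#' @param causal_mix,null_mix Lists with elements `prob` (mixture weight of
#'   the first component) and `shape1`, `shape2` (2-vectors of Beta
#'   parameters for the two components).
#' @return data.frame with columns `vert`, `mamm`, `prim` in `[0, 1]`.
#' @export
sample_synthetic_phastcons <- function(is_causal,
                                       causal_mix = list(prob = 0.9,
                                                         shape1 = c(8, 1),
                                                         shape2 = c(1, 1)),
                                       null_mix = list(prob = 0.85,
                                                       shape1 = c(1, 3),
                                                       shape2 = c(20, 3))) {
  draw <- function(n, mix) {
    comp <- 1L + (stats::runif(n) >= mix$prob)
    stats::rbeta(n, mix$shape1[comp], mix$shape2[comp])
  }
  one_lineage <- function() {
    out <- numeric(length(is_causal))
    out[is_causal] <- draw(sum(is_causal), causal_mix)
    out[!is_causal] <- draw(sum(!is_causal), null_mix)
    out
  }
  data.frame(vert = one_lineage(), mamm = one_lineage(),
             prim = one_lineage())
}

#' Build the per-variant prior weight vector
#'
#' Combines the weight components according to the chosen scheme -- raw
#' weight 1 (`none`), `r` (LD with GWAS signals), `phastcons` (composite
#' conservation), or their product (`r_x_phastcons`) -- and scales by the
#' maximum so the final weights lie in `[0.01, 1]` with max exactly 1.
#'
#' @param components data.frame with columns `r` and `composite` (both
#'   already floored at 0.01), one row per candidate variant.
#' @param scheme One of `"none"`, `"r"`, `"phastcons"`, `"r_x_phastcons"`.
#' @return A `weight_vector`: list with `w` (scaled weights), `raw`, and
#'   `scheme`.
#' @export
build_weights <- function(components,
                          scheme = c("none", "r", "phastcons",
                                     "r_x_phastcons")) {
  scheme <- match.arg(scheme)
  raw <- switch(scheme,
                none = rep(1, nrow(components)),
                r = components$r,
                phastcons = components$composite,
                r_x_phastcons = components$r * components$composite)
  w <- raw / max(raw)
  structure(list(w = w, raw = raw, scheme = scheme), class = "weight_vector")
}
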