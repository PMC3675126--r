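# Shared fixtures built in code (no files): hand-constructed haplotype
# pools and cohorts small enough for exact reasoning.

# A pool whose site frequencies are chosen exactly: `freqs` is a named list
# with elements `causal` and `null`, each a vector of pool MAFs. Haplotype
# rows carry the minor allele in a deterministic block pattern unless
# shuffle = TRUE.
make_toy_pool <- function(freqs, n_haplotypes = 1000L,
                          chrom_lengths = c(500000, 500000),
                          positions = NULL, shuffle = FALSE) {
  sites <- data.frame(chrom = character(0), pos = integer(0),
                      maf = numeric(0))
  H <- NULL
  for (ch in c("causal", "null")) {
    f <- freqs[[ch]]
    if (is.null(f)) next
    pos <- if (!is.null(positions[[ch]])) positions[[ch]] else
      as.integer(seq(1000, chrom_lengths[if (ch == "causal") 1 else 2] - 1000,
                     length.out = length(f)))
    for (i in seq_along(f)) {
      n_minor <- round(f[i] * n_haplotypes)
      col <- c(rep(1L, n_minor), rep(0L, n_haplotypes - n_minor))
      if (shuffle) col <- sample(col)
      H <- cbind(H, col)
      sites <- rbind(sites, data.frame(chrom = ch, pos = pos[i],
                                       maf = n_minor / n_haplotypes))
    }
  }
  rownames(sites) <- NULL
  colnames(H) <- paste0(sites$chrom, "_", sites$pos)
  structure(list(haplotypes = H, sites = sites,
                 params = sim_params(n_haplotypes = n_haplotypes,
                                     chrom_lengths = chrom_lengths)),
            class = "haplotype_pool")
}

# Causal spec pointing at given pool columns without random selection.
make_causal_spec <- function(site_indices, maf_interval = c(0, 0.5)) {
  structure(list(site_indices = as.integer(site_indices),
                 maf_interval = maf_interval,
                 k = length(site_indices)),
            class = "causal_spec")
}

# Cohort straight from a genotype matrix (minor-allele counts).
make_cohort <- function(X, status, chrom = "causal", causal = integer(0),
                        pop_maf = NULL) {
  p <- ncol(X)
  sites <- data.frame(chrom = rep(chrom, length.out = p),
                      pos = seq_len(p) * 100L,
                      maf = if (is.null(pop_maf)) pmin(colMeans(X) / 2,
                                                       1 - colMeans(X) / 2)
                            else pop_maf)
  bvlr:::new_cohort(X, status, sites, causal)
}

# Genotype column with exact class counts (aa, Aa, AA) for cases and
# controls; returns list(x, d).
geno_from_counts <- function(case_counts, control_counts) {
  x <- c(rep(0L, case_counts[1]), rep(1L, case_counts[2]),
         rep(2L, case_counts[3]),
         rep(0L, control_counts[1]), rep(1L, control_counts[2]),
         rep(2L, control_counts[3]))
  d <- rep(c(1L, 0L), c(sum(case_counts), sum(control_counts)))
  list(x = x, d = d)
}

# Hand-made replicate_result for summary arithmetic tests.
fake_rep <- function(detected, causal = c("A", "B", "C"),
                     fp_causal = 0, n_cc = 500, fp_null = 0, n_nc = 500) {
  structure(list(
    maf_interval = c(0.04, 0.05), causal_ids = causal, n_candidates = 1000,
    methods = list(svt = list(label = "svt", significant = detected,
                              detected_causal = intersect(detected, causal),
                              fp_causal_chrom = fp_causal,
                              n_noncausal_causal_chrom = n_cc,
                              fp_null_chrom = fp_null,
                              n_noncausal_null_chrom = n_nc))),
    class = "replicate_result")
}

# Independent likelihood-ratio oracle via iterative logistic fits.
glm_genotypic_lrt <- function(x, d) {
  cls <- factor(x)
  full <- stats::glm(d ~ cls, family = stats::binomial())
  null <- stats::glm(d ~ 1, family = stats::binomial())
  stat <- as.numeric(null$deviance - full$deviance)
  df <- nlevels(cls) - 1L
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}
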