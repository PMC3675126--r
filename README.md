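# bvlr — weighted Bayesian multi-variant liability regression

`bvlr` detects **causal variants** (not just association signals) in
case/control sequence data. All candidate variants in a region are fitted
jointly in a probit liability regression, and external evidence about each
variant — linkage disequilibrium (LD) with known GWAS signals, phastCons
sequence conservation — enters as a per-variant prior weight on the effect
size. A single-variant genotypic test and a full simulation study
(coalescent haplotype pool → GWAS stage → sequencing stage → power/FPR)
are included as the benchmark and the evaluation harness.

It is aimed at statistical geneticists analyzing targeted/exome
case-control sequence data around known GWAS loci, and at methodologists
who want a reproducible testbed for prior-weighted multi-variant models.

## Model

For individual *i* with genotypes *x<sub>ij</sub>* ∈ {0,1,2} (minor-allele
counts) and disease status *d<sub>i</sub>*:

```
y_i = mu + sum_j x_ij beta_j + e_i,   e_i ~ N(0, 1),   d_i = 1{y_i > 0}
beta_j ~ N(0, w_j sigma2),   sigma2 ~ Scaled-Inv-Chi2(nu = 0.1, S2 = 0.1),   p(mu) ∝ 1
```

The weights *w<sub>j</sub>* ∈ [0.01, 1] encode prior causality evidence:
`r` (max √r² with any genome-wide-significant GWAS SNP), `phastcons`
(composite conservation ½·vertebrate + ⅓·mammal + ⅙·primate), their
product, or uniform. Fitting is a Gibbs sampler (C++ core, R-seeded and
bit-reproducible); the per-variant statistic is the standardized effect
*z<sub>j</sub>* = posterior mean / posterior SD. Family-wise significance
for both methods comes from phenotype permutation: each variant's p-value
is (B₀+1)/(B+1) against the permutation distribution of the family
statistic (min p across variants, or max |z|).

## Worked example

One simulation replicate at causal MAF 4–5%, single-variant benchmark:

```r
library(bvlr)
set.seed(5)
pool   <- simulate_pool(sim_params(seed = 42))       # 15,000 haplotypes, 2 x 500 kb
causal <- select_causal_sites(pool, c(0.04, 0.05))   # 3 causal sites, central 100 kb
coh    <- sample_case_control(pool, disease_model(causal), 500, 500)
cand   <- candidate_filter(coh)                      # MAF in [0.2%, 5%)
cand
#> Cohort: 500 cases / 500 controls; 934 variants ( 3 causal )

pr <- permutation_test(cand, "svt", B = 200)
pr
#> Permutation test (svt): B = 200, alpha = 0.01; 5 of 934 variants significant
subset(pr$table, causal | significant)
#>                id  chrom causal    statistic      perm_p significant
#> 212 causal_203170 causal   TRUE 1.582208e-10 0.004975124        TRUE
#> 223 causal_217154 causal   TRUE 6.981336e-01 1.000000000       FALSE
#> 272 causal_272758 causal   TRUE 2.329891e-12 0.004975124        TRUE
#> 280 causal_285169 causal  FALSE 3.131504e-10 0.004975124        TRUE
#> 329 causal_336315 causal  FALSE 5.940837e-06 0.004975124        TRUE
#> 336 causal_342831 causal  FALSE 4.363827e-08 0.004975124        TRUE
```

Two of the three causal variants are detected (perm_p ≤ 0.01), along with
three linked passengers on the causal chromosome — exactly the behavior
the Bayesian model with informative weights is designed to improve on.
The Bayesian fit on the same candidates:

```r
fit <- fit_bayes(cand$genotypes, cand$status,
                 settings = mcmc_settings(4000, 2000, 2))
head(fit$summary[order(-abs(fit$summary$z)), ], 3)
#>                id   post_mean    post_sd        z
#> 272 causal_272758  0.14460855 0.07332519 1.972154
#> 212 causal_203170  0.11519179 0.07102051 1.621951
#> 280 causal_285169  0.10871193 0.07530516 1.443619
```

`run_study()` / `power_report()` repeat this end-to-end over replicates
and report per-variant power, P(≥1), P(≥2), P(all 3), average power, and
false-positive rates split by causal vs null chromosome. A thin CLI over
the same functions is at `inst/cli/bvlr.R`
(`simulate-pool`, `simulate-cohort`, `single-variant`, `fit-bayes`,
`permute`, `liability-phenotypes`, `full-sim`).

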