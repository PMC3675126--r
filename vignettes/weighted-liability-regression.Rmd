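---
title: "Detecting causal variants with weighted Bayesian liability regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting causal variants with weighted Bayesian liability regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bvlr)
```

## The problem

Sequencing studies of case/control cohorts routinely find many variants in
a disease-associated region, most of them rare and many in linkage
disequilibrium (LD) with one another. Single-variant association tests
localize *signals*, not *causes*: a non-causal variant in LD with a causal
one is just as significant, and rare causal variants are underpowered one
at a time. `bvlr` implements a multi-variant alternative: every candidate
variant enters one regression jointly, and external evidence about each
variant's plausibility — LD with known GWAS hits, sequence conservation —
enters the model as a per-variant prior weight that relaxes or tightens
the shrinkage on that variant's effect.

## The model

Let $d_i \in \{0,1\}$ be disease status and $x_{ij} \in \{0,1,2\}$ the
minor-allele count of variant $j$ in individual $i$. A latent liability

$$y_i = \mu + \sum_{j=1}^{p} x_{ij}\beta_j + e_i, \qquad e_i \sim N(0,1),$$

determines status through a threshold, $d_i = 1\{y_i > 0\}$ (threshold 0
and unit error variance fix the scale; this is a probit model). Priors:
$p(\mu) \propto 1$; $\beta_j \sim N(0,\, w_j\sigma^2)$ with known weights
$w_j \in [0.01, 1]$; $\sigma^2 \sim$ scaled-inverse-$\chi^2(\nu, S^2)$
with $\nu = S^2 = 0.1$ by default (a diffuse choice — these defaults have
infinite prior mean, which is deliberate: the data determine the effect
scale). A large $w_j$ lets variant $j$ carry a large effect; $w_j = 0.01$
shrinks it hard toward zero.

Fitting is by Gibbs sampling with data augmentation:

1. $y_i \mid \cdot \sim N(\mu + x_i'\beta, 1)$ truncated to $(0,\infty)$
   for cases and $(-\infty, 0]$ for controls;
2. $\mu \mid \cdot \sim N(\overline{y - X\beta},\, 1/n)$;
3. $\beta_j \mid \cdot \sim N\!\big(x_j'r_j / c_j,\, 1/c_j\big)$ with
   $r_j$ the residual excluding variant $j$ and
   $c_j = x_j'x_j + 1/(w_j\sigma^2)$, updated in ascending index order;
4. $\sigma^2 \mid \cdot \sim$ scaled-inverse-$\chi^2\!\big(\nu + p,\,
   (\nu S^2 + \sum_j \beta_j^2/w_j)/(\nu + p)\big)$.

These are the unique full conditionals of the joint posterior under
standard conjugacy. The update order (1)–(4) is fixed for
reproducibility; any fixed scan order is a valid Gibbs sampler for the
same posterior. The sampler is written in C++ with sparse genotype
columns (rare-variant matrices are ~97% zeros) and draws its randomness
from R's RNG, so `set.seed()` makes entire fits bit-reproducible.
One-sided truncated normals use plain rejection near the bulk and an
exponential-proposal rejection (Robert's method) in deep tails, where
inverse-CDF sampling loses accuracy. Defaults follow the reference
analysis: 100,000 iterations, 50,000 burn-in, thinning every 50th draw;
initialization is $\mu = 0$, $\beta = 0$, $\sigma^2 = S^2$ (results are
insensitive to initialization on data of the sizes used here). The
per-variant statistic is the standardized effect $z_j = m_j / s_j$
(posterior mean over posterior SD, SD with denominator $m - 1$ over
retained draws); if a chain is so short that draws do not vary, $z_j$ is
set to 0 with a warning rather than propagating an infinity.

## Prior weights

Three sources of per-variant evidence are supported, each floored at 0.01
so that no variant's effect is shrunk away entirely:

- **r weight** — the maximum over genome-wide-significant GWAS signals of
  $r = \sqrt{r^2}$ between candidate and signal, computed from genotype
  correlation in a control reference sample (the GWAS controls). The sign
  of the correlation is dropped; haplotype-phase estimation is not needed
  because $r^2$ is defined on genotypes here.
- **phastCons weight** — the composite conservation score
  $\tfrac12\,\text{vertebrate} + \tfrac13\,\text{mammal} +
  \tfrac16\,\text{primate}$, weighting broader lineage conservation more.
  The floor is applied after the weighted average.
- **r × phastCons** — the product of the two.

Whatever the scheme, raw weights are scaled by their maximum, so weights
are scale-invariant and the best-supported variant always has $w = 1$;
with no information (or no GWAS signal at all) every variant gets
$w = 1$ and the model degrades gracefully to the unweighted fit.

## Family-wise significance

Analytical null distributions are unavailable for the standardized
effects, and the candidate set is large and correlated, so significance
is assessed by phenotype permutation, which preserves LD exactly: shuffle
case/control labels $B$ times, recompute the *family* statistic each time
(the minimum genotypic-test p-value across variants for the
single-variant method; the maximum $|z|$ for the Bayesian model), and
assign each variant $p_j = (B_0 + 1)/(B + 1)$, where $B_0$ counts
permutations whose family statistic is at least as extreme as that
variant's own observed statistic (ties count as extreme — the
conservative direction). This single-step min-p/max-z construction
controls family-wise error: under the global null, *some* variant exceeds
the $\alpha$-quantile of the family-max distribution with probability
$\alpha$. The default is $B = 500$ and $\alpha = 0.01$; at that $B$ the
binomial standard error of a p-value near 0.01 is
$\sqrt{0.01 \times 0.99 / 500} \approx 0.004$. Note $\alpha = 0.01$
requires $B \ge 99$ — below that, $(B_0+1)/(B+1)$ cannot reach 0.01.

For the Bayesian method each permutation refits the full Gibbs chain.
`permutation_test()` accepts separate `perm_settings` so permutation
refits can run shorter chains than the observed-data fit; the package's
own test runs use reduced but matched-order settings (see below) to keep
a desk-scale budget. Shorter permutation chains add Monte-Carlo noise to
each $z$, which inflates the null maxima slightly and makes the
threshold conservative rather than anti-conservative.

## The simulation study

The package ships the full two-stage evaluation design as first-class,
tested code:

1. **Haplotype pool** (`simulate_pool()`): 15,000 haploid genomes over
   two independently assorting 500 kb chromosomes under the standard
   neutral constant-size coalescent with recombination
   ($N_e = 7500$ diploids, $\mu = \rho = 10^{-8}$/bp/generation).
   Generation is delegated to the msprime coalescent simulator through
   the system Python — the coalescent is standard plumbing here, and only
   $\theta$ and $\rho$ matter downstream. Sites are biallelic
   (infinite-sites style), positions 1-based integers, and every column
   is folded so 1 codes the pool minor allele. The simulator is verified
   against Watterson's closed-form expected segregating-site count and
   neutral-SFS and cross-chromosome-independence properties.
2. **Causal sites** (`select_causal_sites()`): three sites drawn
   uniformly among sites on the first ("causal") chromosome with
   population MAF in a chosen interval (the five study intervals are
   0.2–1%, 1–2%, 2–3%, 3–4%, 4–5%) and position in the central 100 kb,
   taken as $[L/2 - 50\,\text{kb} + 1,\; L/2 + 50\,\text{kb}]$ in 1-based
   coordinates (the boundary convention is ours; the region is otherwise
   unambiguous). Pools with fewer than three qualifying sites are
   regenerated with the next derived seed, which keeps the MAF design
   exact at a small compute cost.
3. **Disease model** (`disease_model()`, `sample_case_control()`):
   baseline risk 1%; carrying one or more causal minor alleles at any
   causal site multiplies risk by GRR = 3 (dominant; not multiplicative
   across loci). Individuals are formed from haplotype pairs drawn
   uniformly with replacement (the pool is 15× larger than any cohort,
   so reuse is negligible) and rejection-sampled to exact quotas — a
   3000/3000 GWAS cohort and an independent 500/500 sequencing cohort.
   Cohort sampling is verified against the closed-form carrier
   enrichment $P(\text{carrier}\mid\text{case}) = 3q/(3q + 1 - q)$.
4. **Candidate filter** (`candidate_filter()`): candidates are variants
   with MAF in $[0.2\%, 5\%)$; monomorphic columns are always dropped.
   The lower bound matters: without it the candidate count is far above
   the ~1000 of the reference design. For simulated cohorts the filter
   uses *population* MAF by default: a 500/500 case/control sample of a
   1%-prevalence disease over-samples carriers so strongly that a causal
   variant with population MAF 4.5% typically shows *sample* MAF above
   5%, and a sample-MAF filter would expel exactly the variants the
   study is about. For cohorts loaded from files (where no population
   MAF exists) the filter uses sample MAF.
5. **Weights**: the GWAS-stage scan tests common SNPs (population
   MAF > 5%, emulating array content) with the genotypic test and keeps
   signals at $p < 10^{-8}$; r weights use the 3000 GWAS controls as LD
   reference. Conservation scores in simulation come from documented
   synthetic stand-in distributions (below).
6. **Tests and summary** (`permutation_test()`, `run_study()`,
   `power_report()`): power of a causal variant is the fraction of
   replicates declaring it significant; false positive rate is the
   fraction of non-causal candidates declared significant, averaged over
   replicates and reported separately for the causal and the null
   chromosome (LD makes "false" positives on the causal chromosome a
   loose term). Causal variants that fail the candidate filter (e.g.
   monomorphic in the sequencing sample) count as non-detected.
   `run_study()` shares each replicate's haplotype pool across the MAF
   scenarios being compared — scenarios then differ only in causal-site
   choice and cohort draws, which pairs the comparisons and saves the
   dominant simulation cost.

### Synthetic conservation scores

The reference weighting scheme draws causal variants' phastCons scores
from an empirical distribution of pathogenic variants and non-causal
scores from a whole-chromosome background. Those empirical distributions
are not distributable, so `sample_synthetic_phastcons()` substitutes
documented Beta mixtures: causal lineage scores from
$0.9\,\text{Beta}(8,1) + 0.1\,\text{Beta}(1,1)$ (mass near 1), non-causal
from $0.85\,\text{Beta}(1,20) + 0.15\,\text{Beta}(3,3)$ (mass near 0 with
a moderate-conservation tail, mirroring the observed background where a
fair share of variants have composite scores between 0.1 and 1). These
are *stand-ins*: conclusions that depend on the exact empirical shapes —
notably the absolute power of the phastCons-weighted schemes — are only
qualitatively reproducible, and the package's checks treat them that way
(ordering, not levels). The mixtures are function arguments, so users
with real conservation tracks can pass their own scores instead.

### Exome-style phenotypes

For fixed real genotype panels, `simulate_liability_phenotypes()`
implements the liability construction used for exome data: genetic value
$g_i = 1$ for carriers of any causal minor allele, error variance set so
that $h^2 = V_g/(V_g + V_e)$ equals 10% (so $V_e = 9 V_g$), and a median
split of liability into equal cases and controls (ties broken by
original order, lower half to controls — liabilities are continuous, so
the rule only matters for degenerate inputs).

## Numerical and design choices

- The genotypic single-variant test is a likelihood-ratio test of status
  on genotype *class* (2 df; 1 df when no minor-allele homozygote is
  observed in the analyzed sample — the combined sample, which is the
  natural reading). Because the class model is saturated, the LRT equals
  the contingency-table G-statistic, which the package computes in
  closed form (with $0\log 0 = 0$ for empty cells) and validates against
  iterative logistic fits; the Wald statistic is avoided because it
  degenerates under separation at rare counts. This closed form is what
  makes $B$ permutations over ~1000 variants a sub-second matrix
  operation.
- Permutation p-values use "at least as extreme" (ties included), the
  conservative convention.
- The prior used in the sampler-correctness checks has $\nu = 8$–$9$
  rather than the analysis default 0.1, because a scaled-inverse-$\chi^2$
  with $\nu \le 4$ has no finite variance (and with $\nu \le 2$ no mean),
  so prior-moment comparisons would be meaningless at the default. The
  checks exercise the same code path.
- Degenerate inputs fail loudly: monomorphic columns and single-class
  phenotypes are errors for direct tests (p = 1 inside min-p, where a
  convention is required), $V_g = 0$ is an error for the liability
  simulator, and a non-finite sampler state aborts with the iteration
  index.

## Problem sizes used in the package's own checks

The shipped tests and the acceptance script re-run the study at reduced
scale, chosen as the smallest sizes at which the comparisons retain
statistical meaning: 50 replicates with $B = 200$ for the single-variant
power/FPR surfaces (tolerances are 3 binomial SEs at those sizes); 8–10
replicates with $B = 120$ and shortened chains (3000/1000 observed,
1200/400 thinned by 2 for permutations) for the Bayesian no-weight power
point; 5 replicates, $B = 99$, for the qualitative weight-scheme
ordering. Sampler correctness uses a 20-individual, 3-variant instance
(500 successive-conditional replicates) plus a 2000-individual probit
comparison. At these scales a full check pass is ~20 minutes on one CPU.

## Known limitations

- No covariates: the permutation scheme shuffles phenotypes marginally
  and would break confounder structure; covariate-preserving permutation
  is out of scope.
- The coalescent pool is neutral and constant-size: no demography,
  selection, or gene conversion. LD patterns of real populations (and of
  fragment-approximation simulators) will differ quantitatively.
- Prior means are zero for all variants; encoding directional prior
  beliefs (e.g. conserved variants are deleterious) would need a
  different prior family and sampler.
- The synthetic conservation mixtures are not the empirical pathogenic /
  background distributions; absolute power under conservation weighting
  is not comparable to analyses using real tracks.
- Inference is a single chain; the permutation budget, not chain
  diagnostics, is the practical limit on accuracy, and no multi-chain
  convergence machinery is included.
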