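"""Neutral coalescent haplotype pool generation (msprime backend).

Writes, for each replicate pool and each of two independently assorting
chromosomes ("causal", "null"):

  pool<i>_<chrom>.sites  : whitespace table, columns pos (1-based bp) and
                           pool minor-allele frequency
  pool<i>_<chrom>.bin    : uint8 haplotype matrix, site-major (all samples of
                           site 1, then site 2, ...), 1 = minor allele

Sites are biallelic under a binary (infinite-sites-like) mutation model on a
discrete genome; sites left non-polymorphic by recurrent mutation are
dropped.  Columns with derived-allele frequency > 0.5 are folded so that 1
always codes the pool minor allele.

Usage:
  python poolsim.py OUTDIR N_REPS N_HAPLOTYPES NE LEN1 LEN2 MU RHO SEED
"""

import sys

import msprime
import numpy as np


def simulate_chrom(n_hap, ne, length, mu, rho, seed):
    ts = msprime.sim_ancestry(
        samples=n_hap // 2,
        ploidy=2,
        population_size=ne,
        sequence_length=length,
        recombination_rate=rho,
        random_seed=seed,
    )
    mts = msprime.sim_mutations(
        ts, rate=mu, model=msprime.BinaryMutationModel(), random_seed=seed + 1
    )
    if mts.num_sites == 0:
        return np.zeros((0, n_hap), dtype=np.uint8), np.zeros(0, dtype=np.int64)
    g = mts.genotype_matrix().astype(np.uint8)
    pos = np.array([int(s.position) + 1 for s in mts.sites()], dtype=np.int64)
    freq = g.mean(axis=1)
    keep = (freq > 0) & (freq < 1)
    g, pos, freq = g[keep], pos[keep], freq[keep]
    flip = freq > 0.5
    g[flip] = 1 - g[flip]
    return g, pos


def main(argv):
    outdir, n_reps, n_hap, ne = argv[1], int(argv[2]), int(argv[3]), int(argv[4])
    len1, len2 = float(argv[5]), float(argv[6])
    mu, rho, seed = float(argv[7]), float(argv[8]), int(argv[9])
    rng_seeds = np.random.default_rng(seed).integers(1, 2**31 - 5, size=2 * n_reps)
    for i in range(n_reps):
        for k, (chrom, length) in enumerate([("causal", len1), ("null", len2)]):
            g, pos = simulate_chrom(n_hap, ne, length, mu, rho, int(rng_seeds[2 * i + k]))
            maf = g.mean(axis=1)
            with open(f"{outdir}/pool{i + 1}_{chrom}.sites", "w") as fh:
                for p, f in zip(pos, maf):
                    fh.write(f"{p} {f:.10f}\n")
            g.tofile(f"{outdir}/pool{i + 1}_{chrom}.bin")
    print("OK")


if __name__ == "__main__":
    main(sys.argv)
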