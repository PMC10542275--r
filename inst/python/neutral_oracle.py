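#!/usr/bin/env python
"""Independent neutral-coalescent oracle (msprime/tskit).

Simulates neutral samples under a constant-size model with the given
parameters and prints summary quantities as JSON: mean segregating sites,
mean pairwise diversity (per region), and percentiles of the Tajima's D
null distribution (tskit's implementation). Used only as a cross-validation
oracle for the package's own coalescent engine.

Usage:
  python neutral_oracle.py twoN n L mu r reps seed

twoN is the number of chromosomes in the (diploid) population, i.e. 2N; the
simulation uses haploid individuals with population_size = twoN so that the
pairwise coalescence rate is 1/(2N) per generation.
"""
import json
import sys

import msprime
import numpy as np


def main():
    twoN, n, L, mu, r, reps, seed = (
        float(sys.argv[1]), int(sys.argv[2]), float(sys.argv[3]),
        float(sys.argv[4]), float(sys.argv[5]), int(sys.argv[6]),
        int(sys.argv[7]))
    S = np.zeros(reps)
    pi = np.zeros(reps)
    D = np.full(reps, np.nan)
    rng = np.random.default_rng(seed)
    reps_iter = msprime.sim_ancestry(
        samples=n, ploidy=1, population_size=twoN, sequence_length=L,
        recombination_rate=r, num_replicates=reps, random_seed=seed)
    for i, ts in enumerate(reps_iter):
        mts = msprime.sim_mutations(
            ts, rate=mu, random_seed=int(rng.integers(1, 2**31 - 1)),
            discrete_genome=False)
        S[i] = mts.num_sites
        pi[i] = mts.diversity(span_normalise=False)
        if mts.num_sites > 0:
            D[i] = mts.Tajimas_D()
    Dv = D[~np.isnan(D)]
    out = {
        "mean_S": float(S.mean()),
        "sd_S": float(S.std(ddof=1)),
        "mean_pi": float(pi.mean()),
        "sd_pi": float(pi.std(ddof=1)),
        "D_q05": float(np.quantile(Dv, 0.05)),
        "D_q50": float(np.quantile(Dv, 0.50)),
        "D_q95": float(np.quantile(Dv, 0.95)),
        "n_D": int(Dv.size),
        "reps": reps,
    }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
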