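---
title: "Models and methods: simulating the power of neutrality tests for selective sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating the power of neutrality tests for selective sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Purpose

`sweeppower` measures, by simulation, how well four classical neutrality
tests detect selective sweeps: two site-frequency-spectrum (SFS) tests
(Tajima's D and Fay & Wu's H) and two haplotype tests (rEHH and iHS). A
"measurement" here is always a power or a false-positive rate (FPR): the
fraction of simulated data sets whose statistic falls in the 5% one-sided
tail of an empirical null distribution that is itself simulated. Nothing is
compared to an analytic null anywhere, which is why the package spends most
of its effort on the simulation engine.

The pipeline is

1. a **Wright-Fisher trajectory** of the selected allele's frequency,
2. a **structured coalescent with recombination** conditioned on that
   trajectory, which yields a haplotype sample,
3. the **four statistics** on that sample,
4. **power/FPR estimation** against simulated nulls over parameter grids.

## The selection model

Genotype fitnesses are `1 : 1 + 2hs : 1 + 2s` for ancestral homozygotes,
heterozygotes, and derived homozygotes. With the default `h = 0.5` the
heterozygote advantage equals `s`, i.e. selection is additive with
coefficient `s` per allele copy — the convention of the forward trajectory
generators that accompany structured-coalescent sweep samplers, under which
`Ns` is the usual strength parameter and a conditioned sweep completes in
roughly `(2/s) log(4Ns)` generations. Each generation applies deterministic
selection to the parental frequency and then binomial drift with `2N(t)`
trials, so frequencies always live on the lattice `k / (2N(t))` of the
offspring generation, and 0 and 1 are absorbing.

Dominance is exposed but defaults to semidominance; none of the shipped
study conditions override it.

### Trajectory conditioning

Three conditioning schemes reflect three scientific questions:

* **SDN** (selection on a de novo mutation, `simulate_sdn`): the allele
  arises at frequency `1/(2N)` a fixed number of generations ago and the
  forward path is rejected until it is **non-lost** at present (fixation
  allowed — Tajima's D famously retains power after fixation, and the loss
  of rEHH/iHS power after fixation is one of the effects the package is
  built to exhibit; a `segregating` condition is available).
* **CURRENT_FREQ** (`simulate_current_freq`): the path is conditioned on
  its present-day frequency falling in a bin (default grids use width
  0.05). The correctness baseline, valid under any demography, is forward
  simulation from a de novo mutation at an origin time drawn uniformly on
  `[1, t_max]` with rejection on the final frequency; `t_max` defaults to
  `8 * reference_N` generations, large enough to cover the ages of both
  selected and common neutral alleles. For constant-size models a
  backward accelerator draws the present-day lattice frequency uniformly
  in the bin and walks backward with binomial resampling under reversed
  fitness weights (`1/(1+2s)` per derived copy, neutral when `s = 0`)
  until the origin, rejecting paths that reach fixation backward. The
  accelerator is validated against the forward baseline by a two-sample
  test on origin-time distributions (it is orders of magnitude faster for
  the high-frequency bins needed by frequency-matched nulls, where forward
  rejection is hopeless).
* **SSV** (selection on standing variation, `simulate_ssv`): the allele is
  neutral until `t_sel` generations ago, when selection begins at
  frequency `p1`. The recent segment is a forward selected path from `p1`;
  the ancestral segment extends backward from `p1` by neutral binomial
  resampling until absorption at zero, rejecting paths that hit one —
  neutral Wright-Fisher serves as its own approximate time reversal, an
  approximation bounded by the brute-force oracle tests.

Every rejection sampler gives up with a diagnostic error after a
configurable number of attempts (default `1e6`).

## The structured coalescent

Samples are generated backward in time. While the focal allele is
polymorphic in the look-back population, each lineage belongs to the
derived or the ancestral allelic class; with frequency `p` and diploid size
`N` at the parent generation, the class sizes are `n_D = max(round(2Np),
k_D)` (the floor keeps coalescence probabilities below one on the lattice)
and `n_A = max(2N - n_D, k_A)`.

* **Coalescence** happens only within a class, at probability
  `C(k,2)/n_class` per generation, at most one merger per class per
  generation; any generation whose coalescence probability exceeds 0.1 is
  subdivided into equal sub-steps so the one-merger approximation stays
  accurate.
* **Recombination** hits each lineage with probability `r` times its bp
  span — from the leftmost to the rightmost point of its ancestral
  material *and the focal site*, because a breakpoint between the material
  and the selected site changes the material's allelic background. The
  fragment not containing the focal site joins the derived background with
  probability `p`. Per-lineage recombination probabilities are at most
  `rL = 0.005` for the shipped regions, far below the subdivision
  threshold.
* At the **origin** of the trajectory all remaining derived lineages merge
  (the focal mutation event) and the merged lineage joins the ancestral
  class; older than the origin a single-class neutral coalescent continues
  until every bp position has reached its MRCA. Once rates are
  generation-constant (single class, fixed epoch), the engine samples the
  waiting time to the next event-bearing generation directly from the
  exact per-generation Bernoulli model instead of looping, which is what
  makes 500-kb samples with `4Nr L = 200` affordable.

Ancestral material is tracked as intervals annotated with the set of
descendant sample chromosomes (a 128-bit mask, so up to 128 chromosomes);
material whose descendant set is complete has reached its MRCA and is
pruned. Every lineage's lifetime is emitted as an edge record; mutations
are dropped afterwards as Poisson(`mu` x duration x carried bp) per record
with uniform positions — monomorphic columns are impossible by
construction, matching infinite-sites output conventions. When the focal
allele is polymorphic in the sample it appears as an ordinary column at its
position (a flag excludes it from the SFS statistics if desired).

The engine is validated three ways: closed-form neutral moments
(`E[T_total] = 4N a_{n-1}`, Watterson's `E[S]`, `E[xi_i] = theta/i`),
distributional agreement with msprime/tskit at the default sample size,
and — for the structured part — exact agreement with a parent-tracking
diploid forward simulator at `N = 50, n = 6`, where the genealogy
distribution of samples drawn at fixation is known by construction.

## The statistics and their undefined states

* **Tajima's D** uses the textbook normalization; it is undefined when
  `S = 0` (common immediately after a completed sweep — those replicates
  count as non-significant).
* **Fay & Wu's H** is the unnormalized `theta_pi - theta_H` from the
  unfolded spectrum; significance comes from the simulated null, so the
  later variance normalization adds nothing here. `H = 0` when `S = 0`.
* **EHH/rEHH**: EHH is the probability that two random carriers of a core
  allele are identical over all polymorphic columns between the core and a
  target position; rEHH is the derived/ancestral ratio at a fixed distance
  (25,000 bp = 0.025 cM at the simulated rates). Undefined when either
  class has fewer than two carriers — in particular when the derived
  allele is fixed in the sample, which is the mechanism behind the
  haplotype tests' power collapse after fixation.
* **iHS** (unstandardized) integrates each class's EHH decay curve
  outward from the focal site by the trapezoid rule, truncated at the
  first marker where EHH < 0.05 (that marker included), and reports
  `ln(iHH_A / iHH_D)`. Integration is one-sided because the shipped
  haplotype design places the target at the region edge. Instead of the
  genome-scan standardization by frequency bin, the unstandardized value
  is compared to a frequency-matched null — equivalent in tail
  probability, with no extra standardization parameters to choose.

Sweeps push D and H into the lower tail, rEHH into the upper tail, and
`ln(iHH_A/iHH_D)` into the lower tail.

## Power and false-positive rates

Power is the fraction of data replicates at or beyond the empirical
`alpha`-tail order statistic (rank `ceiling(alpha * n_null)` from the tail)
of the null; undefined values are non-significant among data replicates and
excluded (counted) from nulls. The default design uses 200 data
replicates per cell, `alpha = 0.05`, one-sided.

Null construction differs by statistic family: SFS statistics use
unconditioned neutral replicates (1,000 by default — a 200-replicate null
makes the 5% threshold itself noisy); haplotype statistics use neutral
replicates whose focal variant is frequency-matched to each data replicate
in bins of width 0.05 (200 per bin by default), generated through the
backward accelerator, because EHH-based statistics depend strongly on core
frequency. FPR estimation is the same machinery with neutral data, and the
null demography may deliberately differ from the data demography to study
misspecification (expansion and bottleneck grids).

Proportions carry Wilson 95% intervals, appropriate for 200 replicates at
extreme proportions.

## Study conditions and scaling

The shipped configurations define the package's default study conditions:
diploid populations; samples of 120 chromosomes; `mu = r = 1e-8` per site
per generation; 10-kb regions with a central target for the SFS tests and
500-kb regions with the target at the edge for the haplotype tests; basic
demographies (constant `N = 5000`; expansions with `N0/N1 = 10` at
`t1 ∈ {0.1, 0.3, 0.5}` x `reference_N`; bottlenecks with `N0/Nb = 20`,
500-generation duration, ending `tb ∈ {0.05, 0.2, 0.5}` x `reference_N`;
all with the same long-term effective size 5,000), plus a constant
`N = 10,000` model with selection starting 2,000 generations before
present for the headline four-test table. N-scaled times are converted
with `reference_N = 5000`, the common effective size of the basic grid,
since the source text leaves the scaling N implicit. Human-like histories
are supported as arbitrary piecewise models; the shipped East-Asian-like
config is an *illustrative synthetic* template, not a calibrated
reproduction of any published inference (those parameterizations live in
supplementary material this package does not mirror).

The test suite runs reduced problem sizes chosen to keep each check's
Monte-Carlo error well inside its assertion band: closed-form checks at
`N = 500`, the forward-oracle comparison at `N = 50`, directional grids at
`N = 2000` with `2Ns` preserved (and mutation rates raised to keep
region-wide `theta` near the default conditions'); the headline table runs at full
size.

## What the generator does and does not emulate

The simulator produces exactly the data-generating process assumed by the
original analysis: panmictic piecewise-constant diploid demography, a
single selected biallelic site, infinite-sites mutation, uniform
recombination without interference or gene conversion, and known ancestral
states. Passing tests therefore demonstrate the statistical behaviour of
the four tests *under that model*. Real data add ascertainment,
mis-specified ancestral states, non-crossover gene conversion, cryptic
structure and sequencing error, none of which are emulated; conclusions
about real scans inherit those caveats.

## Numerical choices, degenerate inputs, known limitations

* All randomness flows through R's RNG; every top-level entry point takes
  or respects a seed, and identical seeds give byte-identical outputs.
* Lattice effects: frequencies are exact ratios `k/(2N)`; the trajectory
  origin is the oldest positive-frequency generation. Backward-derived
  paths may reach the origin with more than one copy (the remaining
  derived lineages are merged there); forward paths always start at one
  copy.
* Sample sizes are capped at 128 chromosomes by the leaf-mask layout —
  ample for the 120-chromosome design.
* Degenerate inputs are first-class: `mu = 0` yields empty samples,
  fixed-at-present alleles yield all-derived samples with no focal column,
  `S = 0` yields the documented undefined statistics.
* The backward accelerator for selected current-frequency paths uses the
  reversed-fitness heuristic; it is gated by an equivalence test rather
  than proved, and bins touching fixation fall back to forward rejection.
* Reported power at any given operating point depends on modelling
  conventions that differ between sweep-simulation pipelines (fitness
  parameterization, survival conditioning, null construction); the package
  states its choices here and exposes each as a parameter, so comparisons
  with other implementations should match these conventions first.
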