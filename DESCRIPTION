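Package: sweeppower
Title: Power and False-Positive Rates of Neutrality Tests for Selective Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based estimation of the power and false-positive rate
    of four neutrality tests (Tajima's D, Fay and Wu's H, rEHH, and iHS) for
    detecting selective sweeps. Provides Wright-Fisher simulation of
    derived-allele frequency trajectories under configurable piecewise-constant
    demography and selection on de novo mutations or standing variation, a
    trajectory-conditioned structured coalescent with recombination to generate
    haplotype samples, implementations of the four statistics with explicit
    undefined-value accounting, and empirical-null power and false-positive
    rate estimation over parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
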