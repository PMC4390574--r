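Package: sweepmk
Title: Selection Scans, McDonald-Kreitman Tests and DFE-Based Alpha for
    Coding Polymorphism Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-test analysis of selection on protein-coding loci sampled
    from two closely related species plus an outgroup. Provides codon-aware
    polymorphism summaries (segregating sites, Watterson's theta, synonymous
    and nonsynonymous pi, folded and unfolded site frequency spectra with
    hypergeometric projection), McDonald-Kreitman tests with neutrality index
    and Nei-Gojobori dN/dS, a Hudson coalescent simulator with recombination
    under constant, exponential-growth and three-epoch bottleneck demographies
    for null distributions under uniform parameter priors, a
    SweepFinder/SweeD-style composite-likelihood-ratio sweep scan, an
    OmegaPlus-style linkage-disequilibrium omega scan, gamma-DFE based
    estimation of the adaptive proportion alpha with MCMC credibility
    intervals, grouped Benjamini-Hochberg correction, and a
    chromosome-matched bootstrap test of overlap with genomic outlier
    regions. A synthetic-data module generates coalescent haplotypes, codon
    alignments with planted MK composition, sweep-distorted spectra and toy
    outlier universes so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
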