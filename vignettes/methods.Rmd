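---
title: "Methods: multi-test selection analysis of coding loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-test selection analysis of coding loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepmk)
```

`sweepmk` implements the analysis toolkit used in candidate-gene surveys of
selection on protein-coding loci sampled from two closely related species
(for instance two *Drosophila* species with a third species as outgroup):
codon-aware polymorphism summaries, McDonald–Kreitman (MK) tests, two
sweep scans judged against coalescent simulations, an estimate of the
adaptive proportion of amino-acid fixations from the distribution of
fitness effects (DFE), grouped multiple-testing correction, and a
chromosome-matched bootstrap for enrichment near genome-scan outliers.
This vignette records the models, the numerical choices, and the
deliberately open design decisions.

## Codon handling and summary statistics

Alignments are validated against the alphabet `A/C/G/T/-/N` and classified
codon by codon under the standard genetic code. Columns carrying a gap or
`N` in any sequence are excluded (*complete deletion*, the DnaSP default),
and a codon is retained only when all three of its columns survive — the
classification of a single position always needs its full codon context.
Each retained position receives a fold class by substituting all three
alternative bases into the reference codon: 0-fold (every change alters
the amino acid), 4-fold (none does), or 2-fold otherwise. The reference
codon is the majority codon among the ingroup sequences, with alphabetical
tie-breaking, which makes classification invariant to sequence order;
reference codons that are stops are excluded with a warning. Potential
synonymous/nonsynonymous site counts follow Nei and Gojobori: each codon
position contributes its fraction of synonymous one-step changes (0, 1/3,
2/3 or 1), so `L_syn + L_nonsyn` is exactly 3 per codon, averaged over
sequences.

Per-species summaries report segregating sites `S`, Watterson's
`theta_w = S / (a_n L)` with `a_n = sum(1/i)`, and pairwise diversity `pi`
with its synonymous/nonsynonymous decomposition. Whether the per-site
denominators run over all gap-free columns or only complete codons is not
decidable from summary tables alone, so `summarize_locus(sites =)` exposes
both conventions; the default (`"all"`) is the DnaSP-like one. Site
frequency spectra are computed unfolded (ancestral state = outgroup
consensus; sites where the outgroup is ambiguous or carries a third state
are dropped) or folded. Downsampling to a common sample size uses the
hypergeometric projection in expectation form; a seeded single-realization
mode mirrors literal random subsampling of alleles. Projection and folding
commute, which the tests check exactly for small samples.

## MK tests

The MK table contrasts pooled polymorphism in the two ingroup species
(a site segregating in either species counts once) with fixed differences
(both species monomorphic, different states); the outgroup is not required
to match either ingroup state — it is used only to orient codon contexts
and to polarize spectra. Counted sites are classified synonymous or
nonsynonymous in their codon context. For codons varying at more than one
position we classify each varying column in the context whose remaining
positions take the outgroup state (falling back to the majority codon) —
this is equivalent to choosing the outgroup-parsimonious mutational
pathway and keeps all counts integral, which the fractional
pathway-averaging alternative would not; `multi_hit = "exclude"` drops
such codons instead. Segments of one gene are pooled (counts summed)
before testing.

The default test is the Pearson chi-square with 1 df and *no* continuity
correction, which reproduces the published p-values for the
germline-stem-cell survey tables this package is built around (`Yb`
1e-05, `stwl` 0.015, `nos` 0.046, `piwi` 0.416, `cycA` 0.414, `pum`
0.506); likelihood-ratio G and the two-sided Fisher exact test are
options. One published value (`zpg`, 0.230) matches neither the
uncorrected chi-square (0.183) nor the G-test (about 0.21); the variant
used for that small-expected-count table is unknown, and we do not force
agreement. A zero row or column margin (as for a divergence-free gene)
raises a classed error rather than returning a number. The neutrality
index `NI = (P_n/P_s)/(D_n/D_s)` and `alpha_mk = 1 - NI` accompany every
test. Between-species `dN/dS` uses Nei–Gojobori counting with
minimum-pathway averaging and Jukes–Cantor correction, with an explicit
saturation error at `p >= 3/4`.

```{r}
mk_test(mk_table(86, 62, 80, 149, locus_name = "Yb"))
```

## Coalescent simulator and null distributions

`simulate_coalescent()` implements Hudson's coalescent with recombination.
Time is measured in coalescent units — the expected pairwise coalescence
time — with per-pair coalescence rate 1 and infinite-sites mutations at
rate `theta_locus/2` per unit branch length, the scaling under which
`E[pi] = theta` and `E[S] = theta * a_n`, as for `ms -t`. Three
demographic scenarios are supported: constant size; exponential growth at
rate `r` (size `exp(-r t)` backwards in time, optionally frozen beyond an
onset time); and a three-epoch bottleneck (sizes 1, `n_mid`, `n_anc` with
change times `t1 < t2`). Demography enters through the analytic inverse
of the cumulative coalescence intensity, so a zero growth rate or an
all-equal-size bottleneck reproduces the constant model *exactly*,
replicate by replicate, under a shared seed. Recombination is a competing
exponential clock on each lineage's breakable span; marginal trees per
non-recombining segment are extracted from the event log and mutations
dropped per segment. The implementation was cross-checked during
development against an independent coalescent simulator on matched
parameters (growth and bottleneck total branch lengths and segregating
site counts); the released tests verify the Watterson/pairwise
calibrations and the `1/i` neutral spectrum internally.

Null distributions for the scan statistics draw every replicate's
parameters from uniform priors (`draw_priors()`), simulate under the
chosen demography, and evaluate the statistic with the same settings used
on the observed data. The per-species mutation priors default to the
ranges used in the motivating survey (0.006–0.009 per site for one
species; 0.003–0.04 for the other, the observed range across its loci).
The demographic parameter ranges of the original study's supplement are
not reproduced in its text, so no demographic priors ship as defaults —
they must be supplied in the configuration for scientific use.
Empirical p-values use the add-one rule `p = (1 + #{null >= obs}) /
(n_sims + 1)`, which never returns zero and counts ties against
significance. Recombination defaults to `rho = 0` because the original
pipeline's simulation settings are unstated; this is a flagged limitation
that mostly matters for the omega scan's null.

## CLR sweep scan

The scan follows the SweepFinder/SweeD model family. The background
spectrum `phi` defaults to the locus's own empirical SFS with a
pseudocount of 0.5 per bin — these are short single loci, not genome-wide
scans, so the locus is its own background. A sweep at position `x` with
intensity `alpha_s` lets each lineage at distance `d` escape with
probability `P_e = 1 - exp(-alpha_s d)`; the `n - k` non-escapers collapse
onto one pre-sweep lineage, the `k + 1` pre-sweep lineages receive derived
counts by hypergeometric projection of `phi`, and the collapsed lineage
expands its state to all its descendants. The resulting distribution over
observable segregating counts is renormalized on `1..n-1`; at `P_e = 0` no
segregating outcome exists and the model signals a degenerate-spectrum
error, which the scan treats as `-Inf` log-likelihood. The composite
likelihood ratio at `x` maximizes the summed per-site log-likelihood over
an intensity grid that always includes the infinite-intensity null, so
`CLR >= 0` by construction. Defaults: one grid point per 500 bp (ends
included), 12 log-spaced intensities spanning weak to strong distortion
over the locus, ties resolved to the smallest position then smallest
intensity; a folded mode symmetrizes the background for loci without
outgroup polarization. One caveat surfaced by exact enumeration: the
expected fraction of extreme frequency classes decreases with `P_e`
throughout the strong-distortion range but shows a shallow dip just below
the background value as `P_e` approaches 1 before returning to it —
the distortion is not perfectly monotone at the weak-sweep end.

## Omega (LD) scan

The omega statistic contrasts linkage disequilibrium within two flanking
site blocks against LD between them:
`omega = [(C(l,2)+C(S-l,2))^-1 (sum r2 within)] / [(l(S-l))^-1 (sum r2 between) + eps]`.
The denominator is regularized (`eps = 1e-12`, flagged when the
between-block sum is exactly zero) so statistics stay finite and sortable
for empirical p-values. `omega_max()` scans focal points (default: the
midpoints between adjacent sites) and maximizes over all left/right
window extents between `min_window = 2` and all sites, using a
summed-area table so the exhaustive window search stays quadratic;
the tests verify exact agreement with brute-force enumeration.
Singletons are excluded by default — LD on singletons is noise-dominated.
Unphased data are not supported: the intended inputs are sequenced
haploid-equivalent lines (inbred or chromosome-extracted), stated here
explicitly. The original survey's window bounds are unstated, so the
defaults above are design decisions; short loci limit the power of this
scan regardless.

## DFE and alpha

The adaptive proportion of nonsynonymous fixations is estimated from the
4-fold (neutral) and 0-fold (selected) spectra plus divergence counts,
after projection to a common sample size (nine or six alleles in the
motivating survey; the smallest per-species sample). The selected-class
expectation integrates the diffusion sojourn density
`tau(q; gamma) = (1 - e^{-gamma(1-q)}) / ((1 - e^{-gamma}) q (1-q))`
against the binomial sampling kernel; `gamma = 0` recovers `1/i` exactly.
Deleterious effects follow a gamma distribution over `-gamma` with shape
`beta` and mean `gmean`, discretized on a 48-node log grid spanning
`10^-3`–`10^4`; per-node expected spectra are precomputed once per sample
size, and the quadrature uses an adaptive integrator with a boundary-layer
split for `gamma < -50` (relative tolerance `1e-8`). Demographic
distortion enters through per-frequency-class multipliers `r_i`
(`r_1 = 1` for identifiability). The Poisson likelihood over both classes
is sampled by componentwise random-walk Metropolis on the log scale with
uniform priors on the natural scale (Jacobian-corrected), a deliberate
mirror of the credibility-interval phrasing of the DoFE-style approach
rather than ML plus bootstrap. Each retained draw implies
`alpha = 1 - D_s (L_nonsyn/L_syn) E_f[u(gamma)] / D_n` with
`u(gamma) = gamma/(1 - e^{-gamma})`; the point estimate is the posterior
median (always inside the 2.5–97.5% interval) and a split R-hat on the
alpha chain warns about non-mixing. Spectra from multiple loci are summed
per class before fitting (whether the original analysis concatenated or
summed is unstated; summing is the natural Poisson aggregation).
`simulate_dfe_data()` draws from the model's own expectations and adds
adaptive divergence so the generative alpha is exact; default study-like
magnitudes (`theta_s = 0.01` per site, `L_syn = 4000`,
`L_nonsyn = 12000`, `t_div = 10`, `beta = 0.4`, `gmean = 800`) give
divergence counts of the same order as the published gene tables.
Recovering the published point estimates themselves (0.814/0.790 overall)
would require the deposited sequence data, which this package does not
bundle.

## Multiple testing, bootstrap, pipeline

BH correction runs inside four families: the frequency-based tests (CLR
scan and MK) per species, and the LD-based omega scan per species —
frequency-based tests share information that LD does not. Each
(region, demographic scenario) scan p-value is its own record, matching a
row-per-scenario reporting layout. Significance is declared at adjusted
`p <= 0.05`. The bootstrap overlap test counts study loci whose interval
lies within `distance_bp` of an outlier interval (boundary distance,
closed threshold, overlap = 0) and resamples chromosome-matched locus
sets without replacement; its p-value is reported *without* the add-one
correction (`#{draws >= obs} / n_draws`), following the genome-wide
resampling convention, unlike the scan p-values — both conventions are
intentional and documented. `run_pipeline()` chains the stages, logs
every stage's seed, writes TSV/JSON reports, and is byte-identical across
reruns with the same config and seed; stage failures carry the stage
name.

## What the synthetic data do and do not show

The generators plant exact MK compositions at 4-fold/0-fold positions of
glycine codons, draw neutral haplotypes under the three demographies, and
sample sweep-distorted spectra — enough to exercise every code path and
to verify round trips, calibrations and type-I error exactly. They do not
emulate real coding sequence features: codon usage bias, CpG and context
effects, indel alignment error, selection on synonymous sites, population
structure or migration, or linked selection. Passing tests therefore
demonstrate internal correctness and calibration under the stated models,
not robustness of the biological conclusions to model misspecification.

## Problem sizes used by the released checks

The packaged tests and the acceptance script use 2000 simulator
calibration replicates (n = 10, `theta = 10`), 400 test against 1000–1500
null replicates for the scans' empirical size (n = 10, 2 kb loci, the
0.006–0.009 per-site prior), 30–50 DFE recovery replicates at reduced
chain length (1200 kept sweeps after 400 burn-in), and a 1500-codon
synthetic locus for the pipeline round trip; these sizes give
Monte-Carlo error comfortably inside the asserted tolerances.
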