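---
title: "Regional heterogeneity of mutation accumulation on the MSY: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heterogeneity of mutation accumulation on the MSY}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msymut)
```

# The scientific problem

The male-specific portion of the human Y chromosome (MSY) does not
recombine, so every extant Y chromosome carries a mutational record of a
single paternal genealogy. Deep resequencing of a targeted ~1.5 Mb of
X-degenerate MSY sequence in ~100 men yields a few thousand variable
positions; placed on a maximum-parsimony tree, each variant becomes a
dated-able mutational *event* on a specific branch. Two questions follow:

1. **Is the mutation supply even along the chromosome?** If 80 kb blocks
   ("bins") of effectively sequenced bases accumulate events in proportion
   to their size, a single substitution rate describes the whole region. If
   not, genetic dates computed from different subregions will disagree
   systematically.
2. **What is the region-specific substitution rate?** Ancient genomes of
   known age sampled inside the genealogy calibrate a strict molecular
   clock without transferring autosomal pedigree rates.

This package implements the full analysis: variant filtering, genotype
matrix construction, parsimony tree building, Fitch assignment of events to
branches, binning, CpG/substitution-type classification, proportionality
chi-square tests, genomic-feature correlations and regressions, and a
tip-calibrated least-squares clock — plus a coalescent simulator that
generates data with the same structure so every estimator is validated by
parameter recovery rather than by fiat.

# Data model and conventions

* **Coordinates.** External files use their native conventions (VCF and the
  published bin table are 1-based inclusive; fragment manifests are BED-like
  0-based half-open). Internally everything is 0-based half-open, with
  conversion only at the I/O boundary.
* **Absent call = reference.** The input datasets report variants only, so a
  sample without a record at a retained site carries the reference allele.
  Columns that end up monomorphic are dropped: retained sites are variable
  by construction.
* **Filters.** Modern (genotyping-platform) calls are dropped when flagged
  `VQLow` or when the alternative-allele depth is ≤ 2; ancient low-coverage
  calls are kept only when the alternative depth strictly exceeds the
  reference depth. A site blacklist (default: the three hyper-recurrent
  positions identified by phylogenetic cross-checking) removes positions
  regardless of quality; a whitelist protects validated positions from the
  quality filters. Filtering is idempotent, and `detect_hyper_recurrent()`
  closes the loop by flagging positions with more than 3 assigned events
  for feedback into the blacklist.

# Binning

Bins are blocks of consecutive baited fragments accumulating ~80,000
effectively sequenced bases. Two constructors exist, and which one is
authoritative depends on the purpose:

* `bins_from_boundaries()` reproduces an externally specified binning
  exactly (used to replicate the published 19 bins bit-for-bit);
* `partition_fragments()` bins new data: per region it forms
  `k = round(total/80000)` bins (at least one) and chooses, by dynamic
  programming over consecutive fragment partitions, the assignment that
  minimizes the maximum deviation of any bin from the region mean. The
  exact published algorithm is unstated, so the replication path never
  depends on ours. A region smaller than the target (such as the 8,275-base
  region B) forms a single small bin; a region slightly above it (91,454
  bases) stays one bin because `round(91454/80000) = 1`.

CpG positions are counted as positions residing in 5'-CG-3' dinucleotides
of the reference within sequenced fragments — both the C and the G count,
giving the fixed denominator (16,094 bp in the study) for CpG densities.
Because the context is read from the reference, the count is
strand-symmetric.

# Event classification

A substitution is a transition when ancestral and derived bases are both
purines or both pyrimidines, else a transversion. CpG status is a pure
function of position and reference context (flanking polymorphism and `N`
flanks are ignored), which matches the fixed CpG denominator above.
Double-hit sites are classified per event.

# Parsimony and branch assignment

The tree search is a neighbor-joining start on Hamming distances followed
by steepest-descent nearest-neighbor interchange under the Fitch score. On
all ≤ 7-taxon matrices we tested, the search attains the optimum of an
exhaustive scan over topologies scored by an independent parsimony
implementation (phangorn), and on simulated recurrence-free data it
recovers the generating topology up to branches carrying zero events
(which no method can resolve; the comparison collapses them first).

Event assignment is a per-site bottom-up/top-down Fitch pass. The
bottom-up pass intersects (or, when empty, unions) the children's state
sets; each union is one mutation, and the total provably equals the
minimum number of state changes over all ancestral labelings — we verify
this against exhaustive enumeration of all `4^internal` labelings on random
trees up to 8 tips. The top-down pass materializes one minimum labeling:

* at the root, the reference allele is preferred when compatible (ancestral
  context), otherwise a fixed alphabetical representative;
* below, a child keeps its parent's state whenever its down-pass set allows
  it, pushing changes rootward (accelerated-transformation style).

Ties therefore resolve deterministically; events at sites whose placement
had alternatives carry an `ambiguous` flag. The published toolchain's
tie-breaking is unknown, so recurrent sites may be placed differently —
counts, not placements, are the tested quantity. Missing tip states enter
the pass as the full base set, which reproduces assignment on the reduced
tree of observed tips.

Rooting defaults to the midpoint of the longest event-count path (from a
provisional assignment under an arbitrary rooting); an outgroup tip can be
given instead. The published tree is unrooted, so the root is an explicit,
configurable modelling choice here, needed by sectioning and dating.

# Time-window sectioning

Branches are classed as: `very_recent` (terminal, ≤ 10 events), `recent`
(subtending nodes with mean tip distance rho ≤ 20, excluding the former),
`deep` (below the configured deep-root clade, lower node at least 68 ky
old — this needs dated nodes), and `intermediate` otherwise; excluded
clades (a single-representative deep lineage, in the study) stay
unlabeled. "Branch between the deep root and a node older than the
threshold" is operationalized as *the branch's lower endpoint is at least
that old*: every such branch lies wholly on a path from the deep root to an
old node, which is the stated intent; the threshold node set is otherwise a
dating output, not an input.

# Heterogeneity statistics

Per-bin counts are tested for proportionality to per-bin weights by the
goodness-of-fit chi-square `sum((O-E)^2/E)` with `E = total * w/sum(w)` on
`bins - 1` degrees of freedom. Defaults follow the study: weights are
effectively sequenced bases; the small bin 2 (18 observations) is excluded
from every per-bin test, while the 5-region aggregation uses all 19 bins.
Expected counts are proportional to effective bases for *all* strata,
including the CpG and non-CpG subsets — this reproduces the published
non-CpG statistic (75.8); weighting CpG counts by CpG positions instead is
available as an option. Neither expected model reproduces the published
CpG chi-square of 76.3 (they give 75.9 and 80.6); we document this and do
not target that value. Similarly, the published per-bin CpG densities are
not consistent with the published per-bin CpG position counts (the totals
are), so only totals-based CpG quantities are asserted.

Coefficients of variation use the sample standard deviation of per-bin
densities over the 18 included bins; this basis reproduces the published
0.23 (non-CpG transversions) and 0.15 (transitions) exactly.

Correlations are Pearson with two-sided t tests on n − 2 df. Regression is
ordinary least squares; stepwise mode is bidirectional selection on
partial-coefficient p-values (enter 0.05, stay 0.10), the selection style
of the study's era, since the published criteria are unstated. Simulation
shows the per-predictor false-selection rate tracks the entry threshold
and that strong generating predictors are recovered in ≥ 90% of runs.

# Tip-calibrated strict clock

Under a strict clock, the expected root-to-tip event count of tip *i* is
`mu * L * (T_root - age_i)`. Ordinary least squares of counts on tip ages
gives `mu = -slope/L` and `T_root = intercept/(mu*L)`; with all tips
contemporary the slope — hence the rate — is unidentifiable and the fit
refuses to proceed. On noise-free expected counts the generating rate is
recovered to machine precision. The 95% interval is a nonparametric
bootstrap over events (each event's multiplicity resampled
multinomially, counts recomputed through the tip-by-event incidence,
1,000 replicates by default, seeded).

This estimator deliberately replaces the study's Bayesian machinery (GTR
substitution model, expansion coalescent prior, 10M-step MCMC): it is
desk-scale, dependency-free and testable by parameter recovery. The
published rate (0.716e-9/site/year) and node ages (291 ky root) are used
as *generating truth* in recovery experiments, never as reproduction
targets: at study scale (104 modern + 2 ancient tips, 1.5 Mb), 20
replicates put the mean estimate within a few percent of truth with ≥ 95%
bootstrap-interval coverage, and dated nodes older than 10 ky show a mean
absolute relative error around 10%.

Node ages convert rho through the fitted clock, averaging
`count/(mu*L) + tip_age` over descendant tips so ancient tips offset
correctly. Because a parent's tip-average need not exceed its child's, a
bottom-up pass then enforces age monotonicity (parent at least as old as
each child); intervals propagate the bootstrap rate draws. Mutation counts
are treated as substitution counts (strict neutrality), following the
study's conclusion that purifying selection did not materially bias the
regional representation of variants.

# The synthetic-data generator

`simulate_genealogy()` is a serial-sampling coalescent: lineages activate
at their sampling ages and coalesce backward in time with intensity
`k(k-1)/2 * exp(growth * t)/(n0 * gen_time)` per year. Defaults mirror the
study conditions: 104 modern tips, ancient tips at 45,000 and 7,205 years,
generation time 30 years, and `n0 = 4850` haploid — chosen once so the
expected root depth, `2 * n0 * (1 - 1/n)` generations, is about 291 ky at
this sample size; growth defaults to 0 since the root depth, not the
recent branch-length profile, is the condition the experiments rely on.

`simulate_mutations()` places per-branch Poisson event counts (branch
duration times the mean rate times the number of targeted sites) at
positions drawn with weight `multiplier(bin) * cpg_factor^[CpG]`,
normalized so the *mean* per-site rate equals `base_rate` — the fitted
overall rate is then directly comparable to the generating one. Derived
alleles are transitions with probability `r/(1+r)` for the context's Ts/Tv
ratio `r` (12.7 at CpGs, 1.5 elsewhere), drawn conditionally on the
lineage's *current* base in root-to-tip order: there is no infinite-sites
assumption, so recurrent and back mutations arise naturally and exercise
the multi-hit code paths. The emitted genotype matrix is exactly
consistent with the tree and event list, which the round-trip tests
(fixture VCFs → filters → matrix) verify byte-exactly.

The synthetic reference draws bases uniformly and then thins the G after
each C so that ~1.1% of positions reside in CpGs (the study's fraction);
replacement bases are A/T so no new CpGs form. Real CpG content is
*clustered* (CpG islands) and varies between bins — the published per-bin
CpG counts range 550–1,318 per ~80 kb — whereas the synthetic reference
spreads CpGs near-uniformly. This matters for one calibration: with
12-fold CpG hypermutability, per-bin expected counts are proportional to
`non-CpG bases + 12 * CpG bases`, so under the *real* CpG composition a
"homogeneous" per-base-rate simulation already rejects proportionality to
effective bases ~15% of the time. That is a genuine biological signal
(CpG content is one of the features the study regresses against), not an
artifact; the simulator's null-calibration experiment therefore uses its
own near-uniform reference, where the rejection rate is ~5% as a
correctly calibrated test should give. Passing tests validate the
estimators under the generator's assumptions — unstructured coalescent,
uniform CpG spread, context-only rate variation — not the full complexity
of real MSY data.

A miniature mode (10 tips, 5 bins, 50 kb) keeps unit tests fast; the
study-scale experiments state their sizes explicitly: 20 clock-recovery
replicates with 300 bootstrap draws, 500 null and 200 power replicates for
the chi-square, one million placements for the CpG-factor check.

# Numerical and degenerate-input choices

* Chi-square expecteds below 1 warn (small-expected caveat) but do not fail;
  bin exclusion happens before totals are formed.
* NJ distance ties are broken by an infinitesimal seeded jitter so the tree
  search is deterministic given its seed.
* All-identical samples yield a star tree with a warning; empty fragment
  files yield empty manifests with zero total bases; an all-contemporary
  tip set is an error in the clock, not a silent zero.
* Densities with zero denominators and Ts/Tv with zero transversions are
  errors/flagged `NA` rather than infinities.
* Every stochastic function takes or derives from a single seed; the
  pipeline writes byte-identical artifacts for identical config and seed.

# Known limitations

* The heuristic tree search is not guaranteed optimal beyond the scales we
  test exhaustively; the analysis is robust to this because event *counts*
  per bin, not exact placements, drive the statistics.
* Ambiguous Fitch placements are resolved rootward; a different convention
  reshuffles a handful of events between branches of recurrent sites.
* The least-squares clock ignores among-branch rate variation and
  phylogenetic correlation of root-to-tip counts; its bootstrap resamples
  events, not genealogies. The recovery experiments quantify the resulting
  calibration at study scale; they do not license extrapolation far from
  it.
* Feature aggregation assumes annotation tracks are given (retrieval from
  genome browsers is out of scope), and the regression's stepwise
  criteria, while era-appropriate, are one of several defensible choices
  (an AIC mode would be a natural alternative).
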