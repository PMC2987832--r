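---
title: "Models and methods: CpG evolution and imprint-dependent expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CpG evolution and imprint-dependent expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrevo)
```

This vignette documents the models implemented in `icrevo`, the numerical
choices behind them, and what the synthetic-data generators do and do not
emulate. It is the package's methodological reference; the README shows the
user-facing workflow.

## Scientific setting

Imprinting control regions (ICRs) acquire DNA methylation in one parental
germline — most in the oocyte ("maternal" ICRs, promoter-associated and
CpG-rich), a few in the male germline ("paternal" ICRs, intergenic, with
lower CpG content). Methylated cytosines deaminate to thymine at roughly an
order of magnitude above the ordinary transition rate, and the male
germline keeps its methylation through many more cell divisions than the
oocyte does. Two quantitative consequences are testable from sequence data:
present-day CpG depletion (observed/expected CpG ratio) and an elevated
historical rate of CpG→TpG/CpA substitution along a mammalian phylogeny.
On the functional side, comparing transcriptomes of fully imprinted (MP),
maternal-imprint-free (0P) and fully imprint-free (00) embryos attributes
expression changes to maternal or paternal imprints and, through gene-set
overrepresentation, to biological processes.

## CpG composition

`cpg_stats()` uses the Gardiner-Garden convention
$o/e = n_{CpG}\,L / (n_C\,n_G)$ with $L$ the ungapped, non-N length;
positions involving N contribute to no count. Category-level values pool
counts across regions before forming the ratio (`category_ratio()`); the
mean of per-region ratios is also reported because either convention can
appear in the literature, and on small, heterogeneous region sets the two
differ noticeably. Between-category comparison uses Fisher's exact test on
the 2×2 table of CpG versus non-CpG dinucleotide starts — the only table
that reduces to comparing the two categories' CpG frequencies without
modelling base composition. Promoter classes follow the standard
sliding-window scheme (500 bp windows, 5 bp step): HCP if any window has
$o/e > 0.75$ and GC $> 0.55$; LCP if no window exceeds $o/e\,0.48$; ICP
otherwise. The window step is not pinned by the original classification's
description; 5 bp is fine enough that the class assignment is insensitive
to halving it.

## The context-dependent substitution model

The evolutionary model is a continuous-time Markov process in which the
substitution rate of a site depends on its trinucleotide context:
$\rho(\ell, x{\to}y, r)$, tied under strand symmetry
$\rho(\ell, x{\to}y, r) = \rho(\bar r, \bar x{\to}\bar y, \bar\ell)$.
Two parameterizations are provided:

* **U3S** (`model_type = "u3s"`): one free rate per strand-symmetry orbit,
  96 parameters.
* **CpG-aware reduced model** (`model_type = "cpg"`, default): four
  parameters — baseline transition rate, transversion rate, a
  CpG-deamination rate for C→T with right-neighbour G (and its mirror),
  and a CpG-gain rate for the TpG→CpG / CpA→CpG transitions. This is the
  well-conditioned workhorse for recovery experiments and bootstrap work.

### Simulation

`simulate_branch()` runs the exact Gillespie algorithm: per-site exit
rates from the current trinucleotide context, exponential waiting times in
the summed rate, and after each event only the three affected sites are
refreshed. Region boundaries use phantom `A` flanks, a convention shared
with the estimators (it touches two sites per region). No indels are
introduced, so simulated alignments stay column-aligned.

### Composite likelihood and its context convention

The joint likelihood of a context-dependent process is intractable, so the
fit maximizes a composite likelihood: the product over gap-free columns of
the pruning-algorithm likelihood of the central site. A column is usable
when it and both flanking columns are gap-free in every species.

The flanking context of a column must be fixed to make the central-site
process Markovian. Fixing it at the column's present-day majority state is
tempting but measurably wrong at mammalian divergences: the flanking G of
a CpG is itself the G of that CpG and decays at the deamination rate, so a
large share of lineage time is spent in a context the majority state no
longer reflects. With the majority convention we measured ~18%
underestimation of the deamination multiplier on data simulated at the
packaged tree's depth. `icrevo` therefore fixes the context **per branch
half**: every branch is split at its midpoint, the upper half taking the
Fitch-parsimony-reconstructed flank states of the parent node and the
lower half those of the child node (flank changes, like focal changes, are
placed at branch midpoints — the same convention the counting estimator
uses). The two halves of a branch share one length parameter. This cuts
the bias to ~2% at the packaged tree's depth, and biases largely cancel in
between-category rate ratios. On trees of up to three tips every flank
difference is a reconstruction tie, so the subdivision adds convention
without information and contexts stay at the parent node.

### Estimation

Given the per-branch contexts, the model is fitted by
expectation-maximization with closed-form updates:

1. **E step.** For every (branch, context) pair, the joint posterior of
   parent and child states is accumulated over columns by an up-down
   pruning pass. Expected substitution counts and expected state-occupancy
   times are then obtained from the eigendecomposition integrals
   $\int_0^t e^{Qs} E_{ij}\, e^{Q(t-s)}\,ds$ (with a matrix-exponential
   fallback for near-defective generators, and the confluent limit
   $t\,e^{\lambda t}$ for close eigenvalues).
2. **M step.** Each tied rate class is updated to expected events over
   expected exposure; each branch length to expected events over
   rate-weighted exposure (a short inner alternation resolves their
   coupling); the rate/branch scale redundancy is fixed by rescaling so the
   exposure-weighted mean substitution rate is 1. Under that convention a
   rate is the frequency of its substitution relative to all substitutions,
   and branch lengths are substitutions per site.

Iteration stops when the log composite likelihood improves by less than
`tol` (default `1e-6`) or after `max_iter` (200) rounds; non-convergence
warns and flags the result. Starting values come from the parsimony counts,
which typically leaves only ~10–100 EM rounds. All-identical alignments
yield a flagged degenerate fit with near-zero branch lengths.

**Root handling.** The process is non-reversible and the data are not at
equilibrium (CpG-rich regions are decaying), so the root distribution
matters. On two-taxon (and generally very shallow) data the direction of a
substitution — C→T deamination versus T→C gain — is unidentifiable
jointly with a free root distribution: the likelihood has a ridge, and EM
wanders along it. The default therefore anchors the root: for trees of up
to three tips each column's root state is plugged in from the parsimony
reconstruction (`root = "fitch"`), and on deeper trees, where the data
determine the root posterior well, the per-context root prior is fixed at
the reconstructed-root frequencies (`root = "freq"`); a free
EM-estimated root (`root = "mle"`) remains available. Anchoring keeps the
direction convention identical between the likelihood and counting
estimators.

### The counting estimator

`count_events_parsimony()` is an independent estimator used as a
cross-check: Fitch ancestral states per column (ties broken alphabetically,
A<C<G<T), one event per state change on a branch, contexts taken at the
parent node, and exposures of branch length × context occurrences. On a
branch carrying an event the column's exposure is split half to the parent
and half to the child state, consistent with placing the event at the
branch midpoint; without the split the fast deamination class is
underestimated by O(ρt). At divergences ≤ 0.05 the two estimators agree to
a few percent per rate class; at two taxa both inherit the alphabetical
tie-break convention for direction, which is then a convention, not an
estimate — two-taxon data cannot direct substitutions.

### Rate summaries and cross-category comparison

`cpg_loss_rate()` reports the deamination component (exposure-weighted
rate of C→T|·G and its mirror), the total CpG-destroying rate, and the
deamination rate **relative to the category's own baseline (CpG-neutral)
transition rate** (`loss_vs_baseline`). `cpg_gain_rate()` mirrors this for
CpG-creating substitutions, with the TpG/CpA-only restriction reported
alongside the total. Cross-category ratios are formed on the
baseline-relative values: the mean-1 normalization is category-specific
(a category with more deamination mass has a larger normalizer), so the
ratio of mean-1 rates does not equal the ratio of the underlying
deamination intensities, whereas the baseline-relative contrast is exactly
invariant to each category's overall substitution intensity — the property
needed to compare fast-evolving intergenic paternal ICRs with constrained
promoter categories. Both scales are computed and reported.

### Bootstrap

`bootstrap_rates()` resamples columns in blocks of three consecutive
columns (the context window, respecting overlap dependence) with
replacement within each region — whole-region resampling is available via
`boot_unit` — refits by warm-started EM (three warm rounds reproduce the
intervals of much deeper refits to below 1e-4; deeper refits are a
parameter), and re-derives the root prior from each resample before
reporting percentile 2.5/97.5 intervals. Two categories are declared
significantly different when their 95% intervals do not overlap —
deliberately conservative. A caveat established by simulation: at full
tree depth the fitted deamination rate has a heavy-tailed, dataset-level
component of sampling variability (confirmed by independent replicate
datasets, split-half fits and a region jackknife) that neither block- nor
region-level within-dataset resampling reproduces, so the percentile
intervals for that rate are somewhat anticonservative there (empirical
coverage of a generating between-category ratio ≈85–90% at nominal 95%).
Interval widths for the shallower designs, and the non-overlap
significance calls throughout, are unaffected. Interval coverage was assessed on scaled-down
simulations (4-taxon tree of total length 0.12 substitutions/site). Two
regimes bound the design from either side: with very little data the
percentile interval itself carries a few percent of finite-sample error,
while with a lot of data the composite estimator's small fixed bias
(~1.5% of the deamination multiplier) comes to dominate the shrinking
sampling SE and coverage of the *generating* value necessarily degrades —
a property of every plug-in-context composite method, not of the bootstrap.
In the intermediate window (16 regions × 800 bp, B=100) the intervals
cover the generating deamination multiplier close to nominally
(92–94% over 200 datasets).

## Expression classification

`score_probes()` encodes the two imprint patterns as binary scores at a
threshold `alpha` (default 0.01, with 0.003 used only for the
imprinted-gene panel flags): maternal — significant change in the same
direction in 0P vs MP and 00 vs MP, no significant change in 00 vs 0P;
paternal — significant change in the same direction in 00 vs 0P and 00 vs
MP, no significant change in 0P vs MP. Direction consistency is required:
"misexpressed in both" comparisons with opposite signs would not be one
imprint effect. The two patterns are mutually exclusive by construction.
One caveat is worth stating: because the "unchanged" clause also uses
`alpha`, the scored sets are not perfectly nested across *all* thresholds
(lowering `alpha` loosens the no-change requirement); over the working
range (≤ 0.05) the sets are nested in practice. Filtering drops probe sets
undetected in all three conditions (detection p > 0.06), non-unique
mappings, chromosome-Y and Xist probes (sex effects of parthenogenetic
00 embryos), and array controls. Fold-change binning converts fractional
thresholds to log2 cutoffs (decrease to 80% ⇔ −0.322).

## Overrepresentation analysis

`ora()` computes upper-tail hypergeometric probabilities for each
annotation category with in-universe size in [5, 200] (configurable),
after collapsing probes to genes, and corrects with Benjamini–Hochberg
(Bonferroni available). The universe is the set of annotated, expressed,
filtered genes. Optional parent-map propagation annotates ancestors before
testing but is off by default. `pvalue_spectrum()` bins corrected p-values
(default edges 0.001, 0.01, 0.1, 1) and counts categories significant at
0.1 and 0.01.

## Synthetic data: what it does and does not emulate

The generators are pure functions of a scenario plus a seed.

* `gen_sequence_categories()` draws root sequences from a second-order
  Markov chain with controllable GC content and CpG observed/expected
  ratio, evolves them with the exact simulator under per-category
  CpG-aware models (defaults: deamination 15× vs 10× baseline —
  the classical tenfold elevation, with a 1.5-fold paternal:maternal
  contrast — CpG-gain 2×, transversions at 0.25× transitions), scaled to
  unit mean substitution rate at the root composition so branch lengths
  read as substitutions/site. The packaged 16-species tree carries branch
  lengths typical of conserved regulatory regions (total ≈ 0.4
  substitutions/site). Not emulated: indels and alignment error, rate
  variation beyond context, selection, GC-biased gene conversion, and
  non-equilibrium base composition drift beyond CpG decay.
* `gen_expression_dataset()` plants maternal-pattern and paternal-pattern
  shifts (defaults 1695 and 1582 probe sets of 45,101, matching the study
  scale) on log-normal probe-pair intensities with sd 0.12 and effect
  sizes 0.3 + Gamma(1.2, 0.4) log2 units, computes contrast p-values by
  the exact signed-rank distribution over 11 probe pairs and detection
  p-values from expression status, and embeds the classic imprinted-gene
  panel with its published directions, plus filter-exercising probes
  (chrY, Xist, controls, multi-mappers). A configurable fraction (0.3) of
  the maternal set is flagged as indirect (downstream) targets. Not
  emulated: probe-level summarization artifacts, cross-hybridization,
  batch effects, or real correlation structure between genes — so passing
  tests demonstrate the classifier's logic and calibration, not robustness
  to array pathologies.
* `gen_go_annotation()` assigns background categories uniformly and
  oversamples labelled genes in planted categories by a stated fold. Real
  GO's dependency structure (nested terms) is only reproduced if a parent
  map is supplied.

## Problem sizes used by the test suite

Statistical checks run at the scale their question requires: the headline
contrast-recovery experiment uses 20 replicates of two categories × 50
regions × 2 kb on the 16-species tree with B=200; interval coverage uses
200 scaled-down datasets as described above; oracle-equivalence uses ten
100k-column two-taxon datasets; unit tests use small trees and short
regions. These sizes are the package's chosen designs: large enough that
each property is sharply testable, small enough to run routinely.

## Known limitations

* The composite likelihood conditions on reconstructed flank contexts;
  residual bias of a few percent remains at deep divergence and large
  deamination elevation, and cancels to first order in between-category
  ratios.
* Substitution direction at two taxa is a convention (shared with the
  counting estimator), not an inference.
* No indel model: gapped columns and their neighbours are discarded.
* The expression arm consumes pre-summarized probe tables; it does not
  model the upstream array processing.
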