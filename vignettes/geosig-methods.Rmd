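---
title: "Mutational-signature extraction, attribution and geographic epidemiology with geosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational-signature extraction, attribution and geographic epidemiology with geosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`geosig` implements a complete pipeline for studying geographic variation of
somatic mutational processes in cancer genomes: mutation classification into
standard channel schemas, de novo signature extraction by non-negative
matrix factorization (NMF), decomposition of extracted signatures into a
reference catalogue, per-sample activity attribution with bootstrap
uncertainty, and the downstream epidemiological and clonal-timing
statistics. Because the cohorts that motivate this kind of analysis are
controlled-access, the package ships a synthetic multi-country cohort
generator with planted ground truth; every stage of the pipeline is
exercised and tested against that ground truth.

This vignette records the modelling choices, the tunable parameters and
their defaults, what the simulator does and does not emulate, and the
numerical conventions a maintainer needs to know.

# Mutation classification

Somatic variants are classified into four channel schemas:

* **SBS-96** — single-base substitutions in pyrimidine-centric
  trinucleotide context. Purine-reference records are reverse-complemented
  together with both flanks. Channel order is class-major (C>A, C>G, C>T,
  T>A, T>C, T>G), then 5' and 3' flank alphabetically.
* **SBS-288** — SBS-96 crossed with transcriptional strand. Unknown strand
  gets its own `N:` bucket rather than being silently merged, so strand-bias
  summaries cannot be biased by unannotated regions; collapsing over strand
  reproduces SBS-96 exactly.
* **DBS-78** — doublet substitutions mapped to the 78 canonical channels by
  reverse complementation; for palindromic reference doublets the alternate
  orientation is fixed by the canonical channel table itself (a label is
  canonical iff it appears in the table, and exactly one of the two
  orientations always does).
* **ID-83** — insertions/deletions by type, length (capped at 5+), repeat
  context and microhomology. The conventions, which the classification
  literature leaves partly implicit, are fixed here as: deletions are
  binned by the number of copies of the deleted unit present in the
  reference *including the deleted copy*, capped at 6 (encoded as field
  values 0–5); insertions by the copies already present, capped at 5;
  microhomology channels apply only to deletions of length ≥ 2 with no
  whole-unit repeat, with homology the longer of the 5'-suffix and
  3'-prefix matches, capped at `min(length - 1, 5)`. Indels arrive
  VCF-style (left-aligned, anchor base shared between REF and ALT); the
  anchor is stripped and re-attached to the 5' context before counting.

Classification consumes flanking context carried on the mutation record
itself. This removes any reference-genome download from the test path; an
in-memory FASTA-backed provider (`fasta_context_provider()`) exists for
real VCFs. Records that cannot be classified (N in context, complex
indels) are skipped and counted in the catalogue's log rather than
failing the build.

The classifiers are validated against exhaustive enumeration: all 192
stranded substitution contexts (a 2-to-1 map onto the 96 channels), all
144 stranded doublets (78 channels, 12 self-complementary), and an indel
construction grid over unit lengths 1–6, run counts 0–7 and homology 0–5.
The simulator's inverse classifier (`channel_record()`) is checked to be a
right inverse on every channel of every schema.

# De novo extraction

The catalogue `V` (channels × samples) is factorized as `V ≈ W H` with `W`
column-stochastic signatures and `H` non-negative exposures, minimizing the
generalized Kullback–Leibler divergence by multiplicative updates. Each
replicate run operates on an independently Poisson-resampled copy of the
catalogue (each entry replaced by a Poisson draw at its observed value), so
replicate scatter reflects counting noise. Initialization is non-negative
double SVD with zeros lifted to the smallest positive matrix entry
("nndsvd_min"), which is deterministic given the resampled matrix; the
randomness across replicates therefore comes from resampling alone.

Hypermutator samples are damped before factorization: any column whose
total exceeds `factor_cap` (default 10) times the median column total is
rescaled to that cap, and the scale factors are recorded so activities can
be reported on the original scale. This cap rule replaces an unspecified
mixture-model renormalization in the tools this design follows; it is
simple, testable, and achieves the same purpose of keeping extreme-burden
samples from dominating the objective.

Replicate solutions for a given `k` are pooled and partitioned into `k`
clusters under cosine distance with the constraint that each replicate
contributes exactly one signature per cluster. The constraint is enforced
by solving an exact one-to-one assignment (Hungarian algorithm) between
each replicate's signatures and the current centroids, iterating centroid
refresh to convergence, over multiple random restarts (default 100 in the
package, fewer in the scaled test runs). Per-signature stability is the
mean silhouette width of the cluster (cosine distance); for `k = 1`, where
the silhouette is undefined, the mean member-to-centroid cosine is used.
The selected `k` is the largest scanned value with mean stability ≥
`s_min` (default 0.8) and every per-signature stability ≥ `s_sig` (default
0.2); among equal candidates the lower reconstruction error wins. The
scan range defaults to 1–8 for desk use and is configurable up to the
1–20 range used on real cohorts, as is the replicate count (default 100;
500 is typical at full scale).

Numerical conventions: zero catalogue rows are lifted with a `1e-12`
pseudocount (multiplicative updates cannot move exact zeros); the stopping
rule is relative objective change below `tol` (default `1e-8`) or
`max_iter` (default 10,000); signature columns are normalized to sum 1
post hoc with the scale absorbed into `H`. The KL objective is asserted
non-increasing per iteration in the test suite.

# Reference decomposition

Each consensus signature is expressed as a non-negative combination of
reference signatures by greedy forward selection on reconstruction cosine
(add while the gain exceeds `add_thresh`, default 0.01), a backward pass
removing references whose loss is below `remove_thresh` (default 0.01),
and a final NNLS refit on the retained set. A profile whose final cosine
falls below `novelty_cosine` (default 0.8) is flagged novel. Forced
co-inclusion rules for biologically paired reference signatures are out of
scope. When a composite reference could be compared against several
decomposition components, both equal-weight and attribution-weighted
combinations are possible; the package takes a weights argument and
asserts nothing about either convention.

# Attribution

Per-sample activities are estimated by non-negative least squares (NNLS,
Lawson–Hanson, compiled) against a fixed panel, followed by backward
elimination: repeatedly refit without each retained signature and drop the
one whose absence costs the least L2 similarity, while that cost is at most
the penalty (0.008 for SBS, 0.014 for DBS, 0.03 for ID — thresholds
derived from simulations in the attribution literature). Ties break toward
the earlier panel column, deterministically. L2 similarity is defined on
raw counts as `1 − ‖v − v̂‖₂/‖v‖₂`.

Confidence intervals come from a parametric bootstrap: each replicate
Poisson-resamples the observed spectrum channel-wise and reruns the *full*
selection (pruning plus refit), not just the refit, so a signature pruned
in a replicate contributes zero. Per-signature bounds are the empirical
2.5% and 97.5% percentiles across replicates (percentile method; no bias
correction), with `n_boot` defaulting to 200. A signature is called
*present* when both bounds are positive and *absent* when the lower bound
is zero — making `ci_low = 0` a meaningful absence signal. Point-estimate
exposures are rescaled, when NNLS overshoots, so their sum never exceeds
the spectrum total; the remainder is reported as unassigned burden, which
keeps stacked-proportion summaries well formed.

Calibration is verified on cohorts generated from the same parametric
model the bootstrap assumes (channel counts Poisson around the planted
signature means): 95% intervals cover a planted activity of 2,000 at
burden 5,000 in 88–99% of 200 samples, and for signatures absent from the
generating mixture the lower bound is zero in ≥ 95% of samples. Note that
on cohorts generated with exact multinomial conditioning the intervals are
mildly conservative (the bootstrap adds total-count variance the
conditioned generator does not have); this is expected and documented
rather than corrected.

# Epidemiological layer

* **Dichotomization.** Signatures present (CI excluding zero) in at least
  75% of cases are split above/below the median attributed count across
  all cases; rarer signatures are coded present/absent by the CI rule.
* **Risk-factor regressions.** Logistic regression of the dichotomized
  outcome on the factor, adjusted for sex, age at diagnosis, country and
  tobacco status; Wald estimates with raw p-values, the Bonferroni family
  size carried alongside rather than multiplied in. Complete or
  quasi-complete separation (common when a signature is restricted to a
  few countries) triggers a Firth-type penalized-likelihood refit with
  aliased-column removal, ridge-stabilized information and step-halving;
  results from that path are flagged `firth_logistic`.
* **Incidence regressions.** Ordinary least squares of per-sample burden
  or exposure on the country-level age-standardized incidence rate (ASR
  per 100,000), adjusting for sex and age. A single-country cohort makes
  the ASR constant and is rejected.
* **Country burden comparison.** The burden test across countries is
  Kruskal–Wallis: the source analyses do not name their test, and rank
  tests are robust to the heavy-tailed burden distributions involved.
* **Driver-spectrum enrichment.** The T>A share among driver SNVs in
  exposed versus unexposed cases is compared with a two-sided Fisher exact
  test; exposure labels come from the CI presence rule of the attribution
  step.
* **Multiple testing.** Benjamini–Hochberg step-up, via `p.adjust`, with
  the closed form asserted in tests.
* **Wilcoxon signed-rank.** Two-sided, exact when at most 25 non-zero
  tie-free differences are present (the exact null with ties would require
  enumerating 2^n sign assignments); otherwise the normal approximation
  with tie and continuity correction. The exact path is verified against
  full enumeration for n ≤ 10.

# Clonal/subclonal timing

Cluster assignments (e.g. from a Dirichlet-process clustering of cancer
cell fractions) are an *input*. Before testing, samples and clusters pass
the exclusion rules, in order: tumour purity ≥ 40%; clusters centred at
CCF > 1.5 or dominated by chromosome X dropped as artifactual; at least
256 clonal and 256 subclonal mutations; no subclone centred above CCF
0.80 (poor clone/subclone separation); at least one clone and one
subclone remaining. Every rule is independently toggleable and excluded
samples are accounted to the first rule that fired, so exclusion counts
sum to input minus output.

For each retained sample the clonal and subclonal spectra are attributed
separately against the fixed panel, activities are normalized by the
clone's or subclone's own mutation total, and per-signature paired
differences are tested with the two-sided Wilcoxon signed-rank test,
BH-adjusted across signatures.

One estimator property worth knowing: attribution is slightly
depth-dependent (truncation at zero inflates small activities more at
lower counts), so clone-versus-subclone comparisons on *very* asymmetric
depths can show small systematic offsets for near-absent signatures even
under a null mixture. The planted-delta recovery and null-calibration
tests run at the simulator's default clone fractions (0.55–0.75) where
this effect is negligible for signatures of appreciable activity.

# The synthetic cohort generator

`default_scenario()` encodes an 11-country cohort whose structure mirrors
the international kidney-cancer setting that motivates the pipeline:
country sample sizes (96, 73, 259, 36, 16, 13, 64, 216, 69, 5, 115) and
incidence rates (ASR 1.8–14.5 per 100,000), a T>A-heavy signature at 70%,
23% and 60% prevalence in Romania, Serbia and Thailand and 2% elsewhere
with high burdens where present, a T>C-heavy signature at 72% prevalence
in Japan and 2% elsewhere, a flat ubiquitous signature whose mean burden
is linear in ASR (intercept 1,500, slope 180 per ASR unit), and a
clock-like C>T component — scales chosen so the cohort median burden lands
near 5,000 mutations. These are *inputs* to the simulation, never asserted
outputs; the tests assert only that the pipeline recovers what was
planted.

Per sample, signature presence is Bernoulli by country prevalence
(optionally modulated by a planted smoking odds ratio on the logit scale),
burdens are log-normal, and channel counts are drawn *multinomially
conditional on the burden*, so planted exposures sum exactly to the
per-sample total and any recovery error is attributable to the pipeline,
not the generator. Records are materialized through inverse
classification when needed, so rebuilding the catalogue from emitted
records reproduces the planted counts bit-exactly. Clone/subclone splits
assign 55–75% of mutations to the clone (CCF ≈ 1) and the rest to one or
two subclones (CCF 0.30–0.75), with the clonal mixture shifted by a
configurable delta for planted timing effects, and a configurable fraction
of samples receives filter-violating features (low purity, CCF 1.6
cluster, chrX-dominant cluster, small clone, subclone at CCF 0.85) whose
ground-truth flags must predict the timing filters' exclusions exactly.

What the simulator does **not** emulate: sequence-level realism (no reads,
alignment artifacts or germline contamination), genomic coordinates with
meaning, mutational-process interactions (signatures mix additively),
transcription-strand asymmetries, copy-number or structural variation, and
real inter-patient correlation structure. Passing tests therefore
demonstrate correctness of the pipeline's algorithms and calibration of
its statistics under the stated generative model — not robustness to every
artifact of real sequencing data.

# Problem sizes used in the checks

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the targeted properties are stable: extraction
recovery on 150 samples × 3 signatures with 50 replicates over k = 1–6
(NMF tolerance 1e-6, iteration cap 2,000 for these runs); pruning
specificity and bootstrap calibration on 200 samples with 200 bootstrap
replicates; regression power and calibration over 100–400 simulation
repeats; the end-to-end geographic scenario at the full 962-sample cohort
with 100 bootstrap replicates per sample. Package defaults remain at the
full-scale settings quoted above.

# Known limitations

* SBS-1536 (pentanucleotide context) is not implemented; analyses that
  would use it collapse to SBS-96 here.
* The NMF model selection rule (stability thresholds) and the hypermutator
  cap are documented replacements for unpublished criteria; both are
  configurable.
* Decomposition does not implement connected-signature co-inclusion rules.
* Exact Wilcoxon p-values are not available in the presence of ties.
* The attribution bootstrap is percentile-based; no bias correction.
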