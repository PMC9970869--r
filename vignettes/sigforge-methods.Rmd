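---
title: "Mutational signature analysis with sigforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational signature analysis with sigforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigforge)
```

# The problem

Somatic mutations in a tumor genome are the cumulative record of the
mutational processes that acted on its lineage: spontaneous deamination,
replication errors, defective repair pathways, exogenous mutagens,
treatment exposures. Each process leaves a characteristic distribution
over mutation-type *channels* — a **mutational signature** — and each
tumor's catalog is approximately a non-negative mixture of the signatures
active in it. sigforge implements the full analysis chain for single base
substitutions (SBS) and small insertions/deletions (indels): catalog
construction, de novo signature extraction, matching to a reference
catalog, per-sample activity attribution, and the downstream statistical
battery used to characterize signatures (clock-like behavior, covariate
associations, strand asymmetry, homologous-recombination-deficiency
features).

# Mutation channels

## SBS channels

An SBS is keyed by the pyrimidine representation of its substitution
(6 classes: C>A, C>G, C>T, T>A, T>C, T>G) and its flanking context.
When the mutated reference base is a purine, the substitution and context
are reverse-complemented, so `classify_sbs` is involutive under strand
flips. Supported schemes:

* **SBS96** — one flanking base on each side (6 × 16 = 96 channels);
* **SBS288** — SBS96 stratified by transcriptional strand class
  (transcribed / untranscribed / nontranscribed, prefix `T:`/`U:`/`N:`);
* **SBS1536** — two flanking bases on each side.

`collapse_channels()` maps SBS288 and SBS1536 onto SBS96 by exact
pre-image summation, conserving mass (and renormalizing probability
columns).

## ID83 channels

Indels use the 83-channel classification `L:Type:Class:N`:

* `L = min(length, 5)` with 5 meaning "5+".
* 1-bp events are classed `C`/`T` by the pyrimidine representation of the
  affected base; `N` counts the identical bases adjacent in the
  post-event sequence (deletions: copies remaining; insertions: copies
  already present), capped at 5.
* Longer events are classed `R` with `N` the number of *full* adjacent
  tandem copies of the indel sequence (partial copies never count),
  capped at 5.
* Deletions with zero remaining copies but flanking homology are classed
  `M` (microhomology): `N` is the maximum of the longest proper prefix of
  the deleted sequence matching the sequence immediately 3' of the
  deleted span and the longest proper suffix matching the sequence
  immediately 5' of it, capped per length class (2 bp: 1; 3 bp: 2;
  4 bp: 3; 5+ bp: 5). Repeat class takes precedence over microhomology —
  `M` requires exactly zero remaining copies — which is what makes the 83
  channels disjoint.

VCF anchor bases are stripped before classification; the indel sequence
is the inserted/deleted run only. The classifier demands six indel
lengths of reference context on each side (enough to saturate every
capped count); indels closer to a contig edge are skipped and counted in
the build log. Externally supplied indels are assumed left-aligned, as
produced by standard callers.

# De novo extraction

## Model

For a catalog $M$ (channels × samples) of counts, the factorization
$M \approx SA$ with $S \ge 0$ (channels × $k$, columns summing to 1) and
$A \ge 0$ ($k$ × samples, mutation-count units) is estimated by
minimizing the generalized Kullback–Leibler divergence

$$D(M \,\|\, SA) = \sum_{cs} \Big( M_{cs} \log \frac{M_{cs}}{(SA)_{cs}}
  - M_{cs} + (SA)_{cs} \Big),$$

the maximum-likelihood objective when counts are Poisson around the
signature mixture — exactly the noise model the synthetic cohort
generator uses. The multiplicative updates (implemented in C++ via
RcppArmadillo; the replicated protocol is infeasible in interpreted R)
are monotone: the objective never increases, which the test suite
asserts on sampled iterations. Both factors are initialized with
uniform(0,1] draws — strictly positive, so no entry is locked at zero —
and convergence is declared when the relative objective change over a
checkpoint interval falls below `tol` after `min_iter` iterations.
Function defaults follow the published protocol (minimum 10,000 and
maximum 1,000,000 iterations, tolerance 1e-14 at double precision);
the test suite and the bundled pipeline run at reduced settings
(hundreds to thousands of iterations, tolerance 1e-7 to 1e-9) at which
the small test catalogs are fully converged.

## Replicates, consensus, stability

`extract_consensus()` runs `n_replicates` factorizations from distinct
seeded initializations (the published protocol uses 500; the package
default is 100; tests use 4–50), pools all replicate signature columns
and partitions them into $k$ clusters. The partition is seeded by
matching each replicate one-to-one to the lowest-objective replicate
under cosine similarity, then refined by alternating centroid updates
with per-replicate optimal reassignment — a k-medoids-style procedure
under cosine distance that keeps the one-signature-per-replicate
constraint. The consensus signature is the normalized cluster centroid;
**per-signature stability** is the mean silhouette width of the cluster
under cosine distance (in $[-1, 1]$; 1 by convention at $k = 1$).
Consensus activities are NNLS refits of each sample against the
consensus signatures.

## Rank selection

`select_rank()` returns the largest $k$ whose solution has average
stability ≥ 0.80 with no individual signature below 0.2. If no rank
qualifies, the rank with maximal average stability is returned flagged
unstable. Ties resolve toward larger $k$. A manual ±1 override within
the evaluated range mirrors the visual-inspection adjustment of
published practice and is recorded in the result. On synthetic cohorts
the stability trace is diagnostic: below the true rank clusters merge
distinct processes (intermediate stability), at the true rank stability
is near 1, above it the surplus signature collects unrelated replicate
columns and its silhouette collapses (often negative).

# Decomposition and attribution

De novo signatures are expressed in a reference catalog by NNLS
(Lawson–Hanson, via `pracma::lsqnonneg`) with greedy **forward
addition** (add the reference signature that maximally improves the
reconstruction cosine, requiring a gain of at least `min_gain`,
default 0.01) and **backward removal** (drop any signature whose removal
costs less than the gain threshold), refitting after every change. A
decomposition is accepted when the final cosine reaches 0.85; otherwise
the signature is reported novel/unexplained. Equal gains break toward
the lexicographically smaller label for determinism.

Per-sample attribution (`refit_sample`, `refit_catalog`) fits the
probability-normalized sample profile by NNLS and rescales weights to
mutation counts. The **background rule** for homologous-recombination
analysis assumes the clock-like SBS1 and SBS5 in every sample and admits
SBS3 only when it improves the sample's reconstruction cosine by at
least 0.02; the rule is applied per sample (an aggregate mode can be
built by fitting entity-level mean profiles). With the gain set to zero
the tested signature is always admitted, since nested NNLS fits never
lose — a property the tests assert. `filter_min_activity()` zeroes
signatures below 5% of a sample's fitted total without redistributing
the removed mass, mirroring conservative attribution practice.

`deconstructSigs`-style iterative in-loop thresholding is approximated
by applying the activity filter once after the NNLS fit; for the
threshold and problem sizes used here the two orderings select the same
signatures, and the single-pass version is deterministic and cheaper.

# Downstream statistics

* `age_correlation` — Spearman and Pearson correlation of exposure with
  age per signature, BH-adjusted within each coefficient family.
* `covariate_association` — OLS of exposure on binary status, cancer-type
  contrasts and age; eligibility requires presence in ≥ 5 tumors and ≥ 3
  cancer types; significance requires a positive status coefficient and
  BH-adjusted p < 0.05. Rank-deficient designs are flagged and excluded
  from the adjustment family.
* `instability_correlation` — correlation of exposure with the per-tumor
  structural-variant total; significant iff p < 0.05 **and** r > 0.2.
  Spearman by default (robust to burden skew; the choice of coefficient
  is configurable).
* `strand_asymmetry_test` — per (signature × substitution class) cell,
  observed strand-label counts against pooled counts from `n_sim = 100`
  simulations that redraw each mutation's label from the genome-wide
  availability of its class; two-sided Fisher exact, BH across cells.
  The default null availability is 0.5 per class (both strands equally
  available); a per-class availability vector computed from an
  annotation track can be supplied, or `"pooled"` estimates it from the
  supplied mutations. Per-variant signature labels come from
  maximum-posterior attribution (`assign_mutations`).
* `mh_deletion_proportion` / `idn_features` — pure functions of the ID83
  histogram: the fraction of deletions in microhomology channels (the
  ID6/BRCAness feature) and counts of ≥ 2 bp insertions at nonrepeat
  sites (the leukemia-associated long-insertion feature), "nonrepeat"
  meaning adjacent repeat count exactly 0 by default (a flag widens it
  to ≤ 1).
* `exposure_cooccurrence` — Spearman correlation of every (SBS, ID)
  signature pair across shared samples, BH across pairs.

Elementary tests go through base R (`fisher.test`, `wilcox.test`,
`p.adjust`, `lm`, `cor.test`); the suite cross-checks them against
exhaustive enumeration oracles on small instances (BH m ≤ 8, Fisher
margins ≤ 12, Wilcoxon n + m ≤ 12). BH families are declared explicitly
per analysis battery.

# The synthetic cohort generator

Every stage is testable offline against planted ground truth:

* `make_reference_sequence` — i.i.d. bases at a requested GC content.
* `plant_variants` — realizes any channel label by *writing the
  required context into the sequence* (homopolymer runs, full tandem
  copies, microhomology flanks with explicit run-breaker bases) and
  emitting the corresponding variant; planted sites are spaced ≥ 20
  unedited bases apart so edits cannot interact. Classifying the
  emitted variants against the edited sequence reproduces the requested
  labels exactly — the oracle-identity property the acceptance suite
  checks on all 83 indel channels.
* `simulate_catalog_cohort` — exposures are log-normal (default
  sdlog 1) with a per-signature **presence probability** (default 0.6;
  absent means zero exposure); catalog counts are independent Poisson
  draws around $SA$.
* `simulate_covariates` — ages proportional to summed clock-signature
  exposure plus noise; a binary status multiplying a chosen signature's
  exposure (catalog redrawn from the updated means); SV counts tied to a
  chosen signature through a Gaussian copula at a configurable Spearman
  strength; cancer types uniform over a configurable number of levels.

The presence model deserves emphasis. If every signature is active in
every sample with exposures bounded away from zero, the exposure cone
sits strictly inside the positive orthant and the factorization is not
identifiable: alternative exact factorizations $S' = ST$, $A' = T^{-1}A$
exist, and KL-NMF converges to a reconstruction-perfect solution whose
signatures need not match the truth (we observed exactly this on
noiseless rank-5 data). Real cohorts are sparse — most signatures are
present in a fraction of tumors — and sparse exposures touch the orthant
boundary, which restores identifiability. The default presence of 0.6
encodes that structure; it is a property of the simulated *cohort*, not
a tuning knob of the estimator.

What the generator does **not** emulate: read-level sequencing noise and
caller error profiles, mutation rate variation along the genome,
signature profiles changing between cohorts, or correlated exposures
beyond the planted covariate effects. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to caller artifacts.

# Numerical choices and degenerate inputs

* All randomness flows from one integer seed through derived per-stage
  seeds (kept inside the 32-bit range R requires); identical
  configurations give bit-identical outputs, asserted by hashing.
* All-zero catalog rows/columns are removed before factorization and
  restored afterwards; zero-count samples get zero exposures.
* $0 \log 0 = 0$ in the KL objective; reconstructions are floored at
  1e-12 before logs and divisions.
* Zero vectors make cosine similarity undefined (an error), Fisher
  tables with a zero margin return p = 1 by convention, constant
  exposure or covariate vectors are reported as missing rather than
  propagating NaN.
* Variant sets are sorted and exact-deduplicated on construction;
  consensus intersection is idempotent.
* Sequence contexts containing N, and indels whose context window
  crosses a contig edge, are skipped and counted per sample.

# Problem sizes used by the test and acceptance suites

Chosen so the full chain exercises realistic structure at desk scale:
5 well-separated signatures (pairwise cosine ≤ 0.6), 100 samples,
~1,300–1,500 mutations per sample for recovery and rank selection (50
replicates at the true rank; scans k = 2–8 at 6 replicates and reduced
iteration ceilings, where the stability trace is already unambiguous);
10,043 planted indels covering all 83 channels for the classifier
oracle; 50 seeded samples of 1,000 mutations for the background rule;
10–20 seeded runs for power/calibration statements.

# Known limitations

* The consensus-clustering/stability procedure is a documented,
  fully-specified choice validated by recovery properties; it is not a
  re-implementation of any specific extraction tool's unpublished
  internals.
* Bayesian ARD-NMF, hierarchical Dirichlet processes, trained HRD
  classifiers and chromothripsis callers are out of scope; their outputs
  enter only as external annotations/covariates. The COMPOSITE
  (SBS1536 ⊕ ID83) scheme is supported as a catalog/factorization input,
  but no automatic-relevance rank selection is provided for it.
* The bundled reference catalog is synthetic (see
  `?synthetic_reference_catalog`): shaped to echo well-known processes
  for testing, not COSMIC estimates. Real COSMIC TSVs load with
  `read_catalog()` and drop in anywhere the synthetic one is used.
* `wilcoxon_rank_sum` switches from the exact distribution to the
  tie-corrected normal approximation above n + m = 20 or in the
  presence of ties.
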