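---
title: "Methods: paired differential-state cytometry analysis and twin variance decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential-state cytometry analysis and twin variance decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twincyto)
```

# Overview

`twincyto` implements an analysis chain for matched-pair (discordant-twin)
single-cell cytometry studies together with a twin variance-decomposition
model. The chain is: pooled-sample debarcoding, variance-stabilizing
transformation with batch alignment, percentile normalization,
self-organizing-map (SOM) clustering with consensus metaclustering,
paired empirical-Bayes moderated differential-state testing with a
treatment-robust dual filter, cross-platform mapping of external cluster
profiles onto the reference framework, and maximum-likelihood ACE
decomposition of trait variance over monozygotic (MZ) and dizygotic (DZ)
twin pairs. A seeded synthetic-cohort generator with planted effects makes
every stage testable without any external data.

The matched-pair design is the scientific core: comparing each affected
individual against their genetically identical, early-environment-matched
co-twin removes the variance attributable to genetics and shared early
environment, so surviving differences are candidate disease-associated
immune alterations. The ACE model quantifies exactly how much variance that
design removes for a given trait.

# The synthetic cohort generator

`generate_cytof_cohort()` emulates the study design at the data level, not
the instrument physics:

* **Emission model.** Each cell belongs to one of a set of populations;
  per population and marker, raw intensities are zero-inflated lognormal
  (`marker_means` is the lognormal median). Ion-count data are heavy-tailed
  and zero-inflated, which this captures; spillover, bead-drift and doublet
  physics are deliberately out of scope.
* **Pair effect.** Each (pair, marker) draws an additive shift on the log
  scale, shared by both twins — the data-level rendering of a shared early
  environment. It cancels exactly in within-pair differences, which is what
  gives the paired design its power.
* **Batches.** Two acquisition batches with one multiplicative lognormal
  factor per (marker, batch) (`batch_scale_sd`, default 0.15 on the log
  scale — a 10–40% scale wobble, the magnitude a run-to-run difference in
  labelling intensity plausibly produces). Both twins of a pair are always
  acquired in the same batch, and two normalization-control samples are
  present in both batches; because controls receive exactly the same batch
  factors as samples, cofactor-based alignment is identifiable.
* **Planted effects.** A `planted_effect(population, marker, log_fold_change,
  applies_to)` adds a shift on the log-intensity scale for the designated
  group only; `treatment_effects` apply only to the affected twin of treated
  pairs, emulating therapy-induced alterations that the dual filter must
  reject.
* **Determinism.** All randomness flows from one seed through named
  substreams (`batches`, `pairs`, `cells`, `controls`), so changing, say,
  the number of cells does not perturb the batch factors.

What passing tests on these cohorts do **not** show: robustness to
non-lognormal tails, instrument drift within a batch, spillover, or
population structure more subtle than discrete mixtures. The generator is a
calibration instrument, not a cytometer model.

`generate_twin_traits()` draws MZ/DZ pairs under the classical ACE
covariance structure: additive-genetic values fully shared within MZ pairs
and correlated 0.5 within DZ pairs, a shared-environment component common to
both twins of every pair, and independent unique-environment noise. The
implied moments are `cov_MZ = var_a + var_c`, `cov_DZ = var_a/2 + var_c`,
total variance `var_a + var_c + var_e`; tests verify these at large n.

# Debarcoding

The pooled sample carries a restricted combinatorial barcode: each sample is
one k-subset of n barcode channels (default 9-choose-3, 84 codes, assigned
in manifest order). `debarcode()` rescales each channel by its own 99.9th
percentile, calls a channel positive above 0.5 of that scaled range, and
then applies Boolean logic: more than k positive channels is a doublet;
exactly the k channels of a sample's code, with the k-th highest rescaled
signal exceeding the (k+1)-th by at least `margin` (default 0.1), is an
assignment; everything else is unassigned. The gate placement (0.5) and
margin are declared defaults, exposed in the API — the original gates in
such experiments are manual and unrecoverable.

# Normalization

* `arcsinh_transform()` applies `asinh(x / cofactor)` per marker (default
  cofactor 5, the conventional mass-cytometry choice; configurable per
  marker). Percentiles throughout the package use linear interpolation
  between order statistics (the type-7 convention) — the common default,
  chosen once.
* `align_batches()` removes residual batch effects by modifying the cofactor
  of each non-reference batch so the mean transformed intensity of the
  shared controls matches the reference batch. The equation
  `mean(asinh(x_b / c)) = target` is solved by bisection on `log c` over
  `[c_base/100, c_base*100]` to relative tolerance `1e-8`; since
  `asinh(f·x / f·c) = asinh(x/c)`, a purely multiplicative batch factor `f`
  is recovered exactly as a cofactor ratio. A marker whose reference target
  mean is zero keeps its base cofactor; a bracket without a sign change
  raises an error naming the marker.
* `percentile_normalize()` divides each marker by its 99.9th percentile and
  clips to `[0, 1]`. Clipping is a declared choice: it keeps downstream
  cluster medians on one bounded scale. Constant-zero markers map to zero.
* `call_cytokine_positive()` thresholds each cytokine at the 99th percentile
  of its transformed unstimulated-control distribution; stimulated cells
  strictly above the threshold are positive. By construction ~1% of
  background cells exceed the threshold, so a responder fraction r yields
  ~r + (1−r)/100 positives.

# Clustering and the reference framework

`train_som()` clusters cells on **type (lineage) markers only** — passing a
panel makes this a hard error for state markers — using online SOM updates:
cells are presented in a seeded random order for 10 epochs; the
best-matching unit (Euclidean) and its Gaussian grid neighborhood move
toward each cell with learning rate decaying 0.05 → 0.01 and neighborhood
radius decaying linearly from half the grid width to 1. The Gaussian kernel
uses σ = radius/3 so the neighborhood effectively ends at `radius` grid
units; with σ equal to the radius itself, a small grid never decouples its
nodes and cannot separate even well-separated populations. The default
10×10 grid gives the 100-node reference granularity. Mean quantization
error is recorded per epoch; it settles at the within-population noise
scale (online updates jitter, so tests assert stabilization rather than
strict monotone decrease).

`consensus_metacluster()` merges the 100 nodes: for each candidate k the
codebook is subsampled (80%, 100 times) and cut from an average-linkage
Euclidean dendrogram; the consensus matrix is the co-clustering frequency
among co-subsampled runs. k is chosen by the elbow of the area under the
consensus CDF: the largest k whose relative delta-area is at least 0.1.
The threshold is the one genuinely open numeric here. Unstable splits
beyond the true cluster number still add ~4% relative area per step, so a
very permissive threshold (e.g. 0.025) would always run to the top of the
scan range; 0.1 sits an order of magnitude above the post-elbow plateau and
an order below the at-elbow jump on separated data, and recovers the
planted population count on blob fixtures in ≥95% of seeds. Final labels
cut an average-linkage tree on `1 − consensus` at the chosen k.

Manual merging/annotation of metaclusters is represented as a replayable
label map (`annotate_metaclusters()`, YAML-friendly) rather than automated.
Iterative subclustering of a main population is expressed by re-invoking
the SOM/metaclustering pair on a label-restricted event table; tests confirm
the composition still partitions the cells.

`summarize_clusters()` produces the per-(sample, cluster) feature substrate:
cell count, frequency among the sample's cells, and per-marker medians.
Clusters with fewer than 10 cells in a sample yield missing medians (noisy
medians would otherwise dominate the paired differences); empty
combinations are emitted with count 0.

# Paired moderated differential-state testing

Features are the Cartesian product of clusters and state markers (100 × 14
= 1,400 at the reference granularity). For each feature, the paired linear
model (group effect + pair blocking) on cluster medians reduces exactly to a
one-sample analysis of within-pair differences: effect = mean difference,
`s²` its sample variance on `d = n_pairs − 1` degrees of freedom. Features
observed in fewer than 2 complete pairs are flagged `NOT_TESTED` rather than
erroring.

Variances are moderated with an empirical-Bayes prior: `(d0, s0²)` are
estimated by moment-matching a scaled-F distribution to the ensemble of
`log s²` values (Newton inversion of the trigamma function); with
`trend = TRUE`, `s0²` is a smooth function (lowess, span 0.5) of mean
cluster abundance. The moderated statistic `effect / (s̃ / √n)` with
`s̃² = (d0·s0² + d·s²)/(d0 + d)` is referred to a t distribution on `d + d0`
df. Setting `prior_df = 0` recovers the textbook paired t test exactly
(tested to 1e-10); `prior_df = Inf` shrinks every variance to the prior.
P-values are Benjamini–Hochberg adjusted (`bh_adjust()`, a validated wrapper
over the standard step-up procedure).

The **dual filter** operationalizes "disease-associated, not
therapy-elicited": a feature passes only if it is significant (adjusted
p < α, default 0.05) in the all-pairs analysis **and** in the
untreated-pairs-only re-analysis **and** the effect signs agree. The
stricter reading (significance, not mere non-reversal, in the untreated
subset) is implemented; sign concordance prevents sign-flip artifacts.
A configuration with the filter enabled but fewer than two untreated pairs
is rejected up front.

Supporting statistics mirror the package's conventions: exact
Wilcoxon signed-rank / Mann–Whitney tests for small untied samples with
normal-plus-continuity-correction fallbacks (zero differences dropped, ties
mid-ranked; effect size |Z|/√n), a per-gene logistic likelihood-ratio test
with twinship (pair) indicators as covariates against a pair-only null
(1 df, Bonferroni-corrected — the single-cell screen uses Bonferroni while
everything else uses BH), the strict clonal-expansion fraction (clones of
size > 2), and QC filters with strict thresholds (< 500 detected genes,
> 15% mitochondrial reads, > 2 TCR β-chains; genes expressed in < 3
retained cells dropped). Cells are filtered before genes; the order is a
declared choice.

# ACE variance decomposition

`ace_loglik()` is the two-group bivariate-normal likelihood with a single
common mean, total variance `a² + c² + e²` and within-pair covariance
`a² + c²` (MZ) or `a²/2 + c²` (DZ). `fit_ace()` maximizes it with path
coefficients constrained nonnegative (their sign is unidentified; boundary
estimates are legitimate), using bounded quasi-Newton iterations from five
seeded starts — the first moment-based via Falconer's formulas, the rest
random. Standardized shares are squared paths over implied total variance;
they sum to one by construction and are invariant to rescaling the trait.
Submodels (AE, CE, E) fix the corresponding paths at zero; the nesting
`logLik(ACE) ≥ logLik(AE) ≥ logLik(E)` is tested. `falconer_shares()`
(A = 2(r_MZ − r_DZ), C = 2r_DZ − r_MZ, E = 1 − r_MZ) serves as the
closed-form oracle: at n = 10,000 pairs per group, interior ML estimates
agree with it within 0.02. Whether traits are standardized before fitting
is immaterial here because only standardized shares are reported.

# Cross-platform mapping

`harmonize_profiles()` brings query node profiles (e.g. antibody-derived-tag
count medians) onto the reference's normalized scale: arcsinh transform,
percentile normalization, restriction to the shared markers (at least 3
required). Default cofactors are **data-adaptive** — each marker's 99.9th
percentile divided by 20 — which makes the harmonization exactly invariant
to a multiplicative rescaling of the query. That invariance is the reason
count-scale and ion-count-scale data can meet on one `[0, 1]` scale without
per-platform tuning; fixed cofactors can be supplied when a platform's
conventional value is preferred.

`build_node_graph()` scores query–reference pairs by cosine similarity over
the shared markers (clipped to `[0, 1]`), keeps each query's top 3 edges
with weight ≥ 0.5, and lays the graph out with seeded Fruchterman–Reingold
iterations. The layout is presentation only: `assign_to_reference()` depends
solely on edge weights (maximum weight; ties broken by larger reference
frequency, then lexicographic id), which tests verify by varying the layout
while holding assignments fixed. All-zero profiles have undefined cosine
similarity and are flagged unmapped. Mapping a reference onto itself is the
identity.

# Orchestration and provenance

`run_pipeline()` executes simulate/load → batch alignment on shared
controls → transform → percentile normalization → SOM + metaclustering →
summaries → moderated tests (all pairs, untreated pairs) → dual filter,
halting on the first stage error (classed as configuration, data or
numerical). The run report echoes every effective parameter, per-stage
summaries (cells in, batches aligned, chosen k, features tested/passed) and
warnings, and is written as JSON alongside CSV stage outputs when an output
directory is configured; identical configuration and seed reproduce every
table byte for byte. YAML configurations cover CSV-driven runs. Event
tables are read and written as CSV (one row per cell); FCS containers are
not parsed — exporting events to CSV upstream is assumed.

# Problem sizes used in the shipped checks

The package's own calibration runs use sizes chosen to make Monte-Carlo
error small relative to the tolerances they are checked against:

* ACE single-trait recovery: 5,000 MZ + 5,000 DZ pairs (share SE ≈ 1.5
  percentage points).
* Multi-trait mean shares: 24 traits × (2,000 + 2,000) pairs.
* Null false-discovery calibration: 500 replicate cohorts of 20 pairs,
  100 populations × 14 state markers, 1,000 cells per sample — roughly 10
  cells per population per sample, deliberately exercising the
  low-abundance missing-median rule.
* Planted-effect recovery: 10 end-to-end runs of 20 pairs (7 untreated),
  2,000 cells per sample, log fold change 1.0 planted in a naive
  helper-T-like population (CD25) with a treatment-only effect (CD69,
  memory-T-like) that the dual filter must reject. A planted effect counts
  as recovered when a passing feature pairs the planted marker with the
  planted population's home metacluster.

# Known limitations

* The emission model is a discrete mixture of zero-inflated lognormals;
  continuous differentiation trajectories, spillover and acquisition drift
  are not represented.
* Debarcoding is Boolean; probabilistic (e.g. Mahalanobis) debarcoding is
  out of scope.
* The ACE implementation is univariate (no cross-trait Cholesky, no
  dominance/ADE models, no ascertainment correction).
* The moderated test assumes cluster medians are approximately normal
  within pairs; very small clusters are excluded by the 10-cell rule rather
  than modelled.
* Mapping consumes externally produced profile tables as-is; no imputation
  model is fitted.
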