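# twincyto

Paired differential-state analysis for matched-pair (twin) single-cell
cytometry studies, with ACE twin variance decomposition.

## The problem

Cross-sectional immune-profiling studies of a disease such as multiple
sclerosis confound disease-associated immune alterations with genetics and
early shared environment. A discordant-twin design removes that confound:
each affected individual is compared with their own co-twin, so within-pair
differences are purged of heritable and early-environmental variance. This
package implements the full analysis chain such a design needs, end to end
and reproducibly:

- **Debarcoding** of pooled samples labelled with a restricted combinatorial
  barcode (k of n channels, default 9-choose-3): Boolean gating with doublet
  exclusion.
- **Normalization**: per-marker `asinh(x / cofactor)` transform; batch
  alignment by solving, per marker, for the cofactor that matches the mean
  transformed intensity of shared normalization controls across batches;
  percentile normalization to `[0, 1]` at the 99.9th percentile; cytokine
  positivity at the 99th percentile of an unstimulated control.
- **Reference-framework clustering**: online self-organizing map (10×10 =
  100 nodes) on lineage markers, consensus metaclustering with an
  elbow criterion on the consensus-CDF area, replayable manual annotation.
- **Differential-state testing**: for each of the (cluster × state-marker)
  features — 1,400 at the reference granularity — a paired moderated test on
  within-pair differences of cluster medians. Variances are shrunk with an
  empirical-Bayes prior, `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, with `(d₀, s₀²)`
  moment-matched to the `log s²` ensemble; moderated t on `d + d₀` df;
  Benjamini–Hochberg correction. A **dual filter** keeps only features that
  are significant across *all* pairs **and** among *untreated* pairs with
  concordant signs — screening out therapy-elicited alterations.
- **ACE twin model**: maximum-likelihood variance decomposition over MZ/DZ
  pairs (cov<sub>MZ</sub> = a² + c², cov<sub>DZ</sub> = a²/2 + c²), with
  standardized A/C/E shares, AE/CE/E submodels, and Falconer's closed form
  (A = 2(r<sub>MZ</sub> − r<sub>DZ</sub>), C = 2r<sub>DZ</sub> − r<sub>MZ</sub>,
  E = 1 − r<sub>MZ</sub>) as an oracle.
- **Cross-platform mapping**: external cluster profiles (e.g. CITE-seq ADT
  medians) harmonized onto the reference scale and assigned to reference
  nodes by cosine similarity over shared markers, with a seeded
  force-directed layout for display.
- **Synthetic cohorts**: a seeded generator for twin cohorts with planted
  disease/treatment effects, batch structure, shared controls,
  stimulated/unstimulated cytokine runs and MZ/DZ traits — every stage is
  testable with known ground truth.

## Worked example

Simulate a 10-pair cohort with a CD25 shift planted in a naive
helper-T-like population of the affected twins, run the whole pipeline, and
look at what survives the dual filter:

```r
library(twincyto)

cfg <- example_cohort_config(
  n_pairs = 10, n_untreated_pairs = 4, n_cells_per_sample = 1000,
  planted_effects = list(planted_effect("naive_Th", "CD25", 1.0, "affected")),
  seed = 31
)
run <- run_pipeline(pipeline_config(cohort = cfg, seed = 31))
run
#> twincyto pipeline run
#>   input: 24000 cells, 22 samples (simulated)
#>   clustering: 100 nodes -> 4 metaclusters
#>   differential state: 24/24 features tested, 1 significant (all pairs), 1 pass the dual filter

subset(run$results$filter_report, verdict)
#>   feature_id cluster_id marker sig_all sig_untreated sign_concordant tested verdict
#> 7     2:CD25          2   CD25    TRUE          TRUE            TRUE   TRUE    TRUE
```

The single surviving feature is CD25 in metacluster 2 — the metacluster
where the naive-helper-T-like cells land — i.e. exactly the planted effect:
elevated CD25 in the affected twins, present in all pairs and in the
untreated subset alike.

Decomposing a trait simulated with variance components 0.51/0.43/0.07
(additive-genetic / shared-environment / unique-environment):

```r
tt <- generate_twin_traits(twin_trait_config(5000, 5000, 0.51, 0.43, 0.07, seed = 1))
fit_ace(tt, seed = 1)
#> ACE twin model (ML), 5000 MZ / 5000 DZ pairs, logLik = -22016.07
#>   standardized shares: A = 49.4%, C = 43.5%, E = 7.1%
```

About 93% of this trait's variance is genetic or early-environmental — the
variance a discordant-twin comparison eliminates by design.

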