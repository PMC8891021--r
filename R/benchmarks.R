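#' Example PBMC-like cohort configuration
#'
#' Eight canonical leukocyte populations over 8 lineage (type) markers and 6
#' functional (state) markers, with a naive helper-T population in which
#' CD25-like disease effects can be planted. Used by the worked examples,
#' the end-to-end tests and the planted-effect benchmark.
#'
#' @param n_pairs,n_untreated_pairs,n_cells_per_sample Cohort layout.
#' @param planted_effects,treatment_effects Lists of [planted_effect()].
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
example_cohort_config <- function(n_pairs = 20L, n_untreated_pairs = 7L,
                                  n_cells_per_sample = 2000L,
                                  planted_effects = list(),
                                  treatment_effects = list(), seed = 1L) {
  type_hi <- 80
  lo <- 0.5
  mk <- function(...) {
    v <- c(...)
    state <- c(CD25 = 2, CD38 = 3, HLADR = 3, CD69 = 2, CXCR3 = 2, PD1 = 1.5)
    c(v, state)
  }
  pops <- list(
    population_spec("naive_Th", 0.20, mk(CD3 = type_hi, CD4 = type_hi, CD8 = lo, CD19 = lo, CD56 = lo, CD14 = lo, CD11c = lo, CD45RA = type_hi)),
    population_spec("memory_Th", 0.15, mk(CD3 = type_hi, CD4 = type_hi, CD8 = lo, CD19 = lo, CD56 = lo, CD14 = lo, CD11c = lo, CD45RA = lo)),
    population_spec("CD8_T", 0.15, mk(CD3 = type_hi, CD4 = lo, CD8 = type_hi, CD19 = lo, CD56 = lo, CD14 = lo, CD11c = lo, CD45RA = 30)),
    population_spec("B_cells", 0.12, mk(CD3 = lo, CD4 = lo, CD8 = lo, CD19 = type_hi, CD56 = lo, CD14 = lo, CD11c = lo, CD45RA = 40)),
    population_spec("NK", 0.10, mk(CD3 = lo, CD4 = lo, CD8 = 10, CD19 = lo, CD56 = type_hi, CD14 = lo, CD11c = lo, CD45RA = 30)),
    population_spec("monocytes", 0.18, mk(CD3 = lo, CD4 = 8, CD8 = lo, CD19 = lo, CD56 = lo, CD14 = type_hi, CD11c = 40, CD45RA = lo)),
    population_spec("dendritic", 0.05, mk(CD3 = lo, CD4 = 8, CD8 = lo, CD19 = lo, CD56 = lo, CD14 = lo, CD11c = type_hi, CD45RA = 20)),
    population_spec("other", 0.05, mk(CD3 = lo, CD4 = lo, CD8 = lo, CD19 = lo, CD56 = lo, CD14 = lo, CD11c = lo, CD45RA = lo))
  )
  cohort_config(
    n_pairs = n_pairs, n_untreated_pairs = n_untreated_pairs,
    n_cells_per_sample = n_cells_per_sample, populations = pops,
    planted_effects = planted_effects, treatment_effects = treatment_effects,
    batch_scale_sd = 0.15, pair_effect_sd = 0.1, seed = seed
  )
}

#' Panel definition for [example_cohort_config()]
#'
#' @return Data.frame (`marker`, `class` in `{"type","state"}`, `cofactor`).
#' @export
example_panel <- function() {
  type <- c("CD3", "CD4", "CD8", "CD19", "CD56", "CD14", "CD11c", "CD45RA")
  state <- c("CD25", "CD38", "HLADR", "CD69", "CXCR3", "PD1")
  data.frame(
    marker = c(type, state),
    class = c(rep("type", length(type)), rep("state", length(state))),
    cofactor = 5,
    stringsAsFactors = FALSE
  )
}

# A cohort config with `n_clusters` generic populations and `n_state`
# state-like markers, for null-calibration studies at the reference
# granularity (e.g. 100 clusters x 14 state markers = 1,400 features).
.null_grid_config <- function(n_pairs, n_clusters, n_state, n_cells, seed) {
  markers <- paste0("s", seq_len(n_state))
  means_base <- .with_seed(.substream(seed, "null_means"), {
    matrix(exp(runif(n_clusters * n_state, log(1), log(20))), n_clusters, n_state)
  })
  pops <- lapply(seq_len(n_clusters), function(i) {
    population_spec(
      name = sprintf("pop%03d", i), weight = 1 / n_clusters,
      marker_means = setNames(means_base[i, ], markers),
      marker_dispersions = 0.4, zero_inflation = 0.05
    )
  })
  cohort_config(
    n_pairs = n_pairs, n_untreated_pairs = n_pairs,
    n_cells_per_sample = n_cells, populations = pops,
    batch_scale_sd = 0.15, pair_effect_sd = 0.1, seed = seed
  )
}

# One replicate of the null/planted screen: generate a cohort, align batches
# on the shared controls, transform, percentile-normalize, summarize by the
# given labels and run the moderated paired screen.
.run_screen <- function(cohort, markers, labels, design, trend = FALSE,
                        min_cells = 10L) {
  ev <- cohort$events
  ctrl <- ev[startsWith(ev$sample_id, "control"), , drop = FALSE]
  ctrl_by_batch <- split(
    ctrl[, markers, drop = FALSE],
    ctrl$batch
  )
  cfs <- align_batches(ctrl_by_batch, base_cofactors = 5)
  y <- .arcsinh_by_batch(ev[, markers, drop = FALSE], ev$batch, cfs)
  norm <- percentile_normalize(y, q = 99.9)
  twin <- !startsWith(ev$sample_id, "control")
  events_n <- data.frame(
    sample_id = ev$sample_id[twin], norm[twin, , drop = FALSE],
    stringsAsFactors = FALSE, check.names = FALSE
  )
  features <- summarize_clusters(
    events_n, labels[twin],
    markers = markers, min_cells = min_cells
  )
  moderated_paired_test(features, design, state_markers = markers, trend = trend)
}

#' Empirical FDR of the paired screen on global-null cohorts
#'
#' Generates `n_reps` synthetic cohorts with no planted effects, runs the
#' full normalization + summary + moderated-test + BH chain on each (cluster
#' labels are the generator's true populations, matching the screen under
#' calibration), and records the false-discovery proportion per replicate
#' (all discoveries are false under the null; replicates without
#' discoveries contribute 0).
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_pairs,n_clusters,n_state_markers,n_cells Cohort geometry.
#' @param alpha BH threshold.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return List: `fdp` (per-replicate false-discovery proportion),
#'   `n_discoveries`, `mean_fdp`, `mc_se`.
#' @export
null_fdr_benchmark <- function(n_reps = 500L, n_pairs = 20L, n_clusters = 100L,
                               n_state_markers = 14L, n_cells = 1000L,
                               alpha = 0.05, seed = 1L) {
  fdp <- numeric(n_reps)
  ndisc <- integer(n_reps)
  markers <- paste0("s", seq_len(n_state_markers))
  for (r in seq_len(n_reps)) {
    cfg <- .null_grid_config(
      n_pairs, n_clusters, n_state_markers, n_cells,
      seed = (seed + 7919L * r) %% 2147483600L
    )
    cohort <- generate_cytof_cohort(cfg)
    design <- paired_design(cohort$manifest)
    labels <- cohort$truth$assignments$population
    res <- .run_screen(cohort, markers, labels, design)
    disc <- sum(res$p_adj < alpha, na.rm = TRUE)
    ndisc[r] <- disc
    fdp[r] <- if (disc > 0) 1 else 0 # every discovery is false under the null
  }
  list(
    fdp = fdp, n_discoveries = ndisc,
    mean_fdp = mean(fdp),
    mc_se = sd(fdp) / sqrt(n_reps)
  )
}

#' Planted-effect recovery of the dual filter, end to end
#'
#' Runs the full pipeline (simulate with planted disease and treatment-only
#' effects, align batches, transform, normalize, SOM + consensus
#' metaclustering, moderated tests on all pairs and on untreated pairs, dual
#' filter) over `n_runs` seeds. A planted disease effect counts as recovered
#' when a passing feature pairs the planted marker with the planted
#' population's home metacluster (the metacluster holding most of that
#' population's cells); a treatment-only effect counts as excluded when no
#' such passing feature exists.
#'
#' @param n_runs Number of seeded end-to-end runs.
#' @param n_pairs,n_untreated_pairs,n_cells Cohort layout.
#' @param lfc Planted log fold change.
#' @param alpha Dual-filter threshold.
#' @param seed Integer seed.
#' @return List: `recovered` / `excluded` (logical per run), `recovery_rate`,
#'   `exclusion_rate`.
#' @export
planted_recovery_benchmark <- function(n_runs = 10L, n_pairs = 20L,
                                       n_untreated_pairs = 7L, n_cells = 2000L,
                                       lfc = 1.0, alpha = 0.05, seed = 1L) {
  recovered <- logical(n_runs)
  excluded <- logical(n_runs)
  panel <- example_panel()
  type_markers <- panel$marker[panel$class == "type"]
  state_markers <- panel$marker[panel$class == "state"]
  for (r in seq_len(n_runs)) {
    cfg <- example_cohort_config(
      n_pairs = n_pairs, n_untreated_pairs = n_untreated_pairs,
      n_cells_per_sample = n_cells,
      planted_effects = list(planted_effect("naive_Th", "CD25", lfc, "affected")),
      treatment_effects = list(planted_effect("memory_Th", "CD69", lfc, "affected")),
      seed = (seed + 104729L * r) %% 2147483600L
    )
    run <- run_pipeline(pipeline_config(
      cohort = cfg, panel = panel,
      cluster = list(grid = c(10L, 10L), k_range = 2:20),
      diff = list(alpha = alpha)
    ))
    verdicts <- run$results$filter_report
    comp <- run$results$cluster_composition
    hit_feature <- function(pop, marker) {
      # the planted population's home metacluster: where most of its cells land
      sub <- comp[comp$population == pop, ]
      home <- sub$metacluster[which.max(sub$n_cells)]
      any(
        verdicts$verdict &
          verdicts$marker == marker &
          verdicts$cluster_id %in% as.character(home)
      )
    }
    recovered[r] <- hit_feature("naive_Th", "CD25")
    excluded[r] <- !hit_feature("memory_Th", "CD69")
  }
  list(
    recovered = recovered, excluded = excluded,
    recovery_rate = mean(recovered), exclusion_rate = mean(excluded)
  )
}
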