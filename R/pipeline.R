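#' Assemble a validated end-to-end run configuration
#'
#' Collects every stage parameter (with all defaults echoed explicitly into
#' the run report) for [run_pipeline()]. Input is either a
#' [cohort_config()] to simulate, or paths to an event-table CSV and a
#' manifest CSV.
#'
#' @param cohort A [cohort_config()] (simulated input), or `NULL`.
#' @param events_csv,manifest_csv CSV paths used when `cohort` is `NULL`.
#' @param panel Panel data.frame (`marker`, `class`, `cofactor`); defaults to
#'   [example_panel()].
#' @param normalize List: `q` (percentile, 99.9), `base_cofactors`.
#' @param cluster List: `grid`, `epochs`, `k_range`, `n_subsamples`,
#'   `subsample_fraction`, `elbow_threshold`.
#' @param diff List: `alpha`, `trend`, `min_cells`, `min_pairs`,
#'   `untreated_filter` (dual filter on the untreated subset, default TRUE).
#' @param out_dir Optional output directory for stage CSV/JSON artifacts.
#' @param seed Global seed for every seeded stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, events_csv = NULL, manifest_csv = NULL,
                            panel = example_panel(),
                            normalize = list(), cluster = list(), diff = list(),
                            out_dir = NULL, seed = 1L) {
  if (is.null(cohort) && (is.null(events_csv) || is.null(manifest_csv))) {
    .config_error("provide either a cohort_config or events_csv + manifest_csv")
  }
  if (!is.null(events_csv) && !file.exists(events_csv)) {
    .config_error(paste0("events_csv does not exist: ", events_csv))
  }
  if (!is.null(manifest_csv) && !file.exists(manifest_csv)) {
    .config_error(paste0("manifest_csv does not exist: ", manifest_csv))
  }
  need <- c("marker", "class", "cofactor")
  if (!all(need %in% colnames(panel))) {
    .config_error("panel must have columns marker, class, cofactor")
  }
  normalize <- modifyList(list(q = 99.9, base_cofactors = NULL), normalize)
  cluster <- modifyList(
    list(
      grid = c(10L, 10L), epochs = 10L, k_range = 2:20,
      n_subsamples = 100L, subsample_fraction = 0.8, elbow_threshold = 0.1
    ),
    cluster
  )
  diff <- modifyList(
    list(
      alpha = 0.05, trend = FALSE, min_cells = 10L, min_pairs = 2L,
      untreated_filter = TRUE
    ),
    diff
  )
  if (!is.null(cohort)) {
    if (!inherits(cohort, "cohort_config")) .config_error("cohort must be a cohort_config")
    if (diff$untreated_filter && cohort$n_untreated_pairs < 2L) {
      .config_error("the untreated filter needs at least 2 untreated pairs (disable it or add untreated pairs)")
    }
  }
  structure(
    list(
      cohort = cohort, events_csv = events_csv, manifest_csv = manifest_csv,
      panel = panel, normalize = normalize, cluster = cluster, diff = diff,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `cohort` block is
#' not supported from YAML (simulated runs are configured in R).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- if (!is.null(y$panel)) as.data.frame(do.call(rbind.data.frame, y$panel)) else example_panel()
  pipeline_config(
    events_csv = y$events_csv, manifest_csv = y$manifest_csv, panel = panel,
    normalize = if (is.null(y$normalize)) list() else y$normalize,
    cluster = if (is.null(y$cluster)) list() else y$cluster,
    diff = if (is.null(y$diff)) list() else y$diff,
    out_dir = y$out_dir,
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: simulate (or load) -> batch
#' alignment on shared controls -> arcsinh transform -> percentile
#' normalization -> SOM + consensus metaclustering on type markers ->
#' per-sample cluster summaries -> moderated paired tests (all pairs and,
#' when enabled, untreated pairs only) -> dual filter. Identical config and
#' seed give identical outputs; any stage failure halts with a stage-tagged
#' classed error.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run`: `report` (machine-readable provenance: config
#'   echo, per-stage summaries, warnings) and `results` (stage outputs:
#'   `manifest`, `som`, `metaclusters`, `features`, `test_all`,
#'   `test_untreated`, `filter_report`, `cluster_composition`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) .config_error("config must be a pipeline_config")
  panel <- config$panel
  type_markers <- panel$marker[panel$class == "type"]
  state_markers <- panel$marker[panel$class == "state"]
  warnings <- character()
  report <- list(
    package_version = as.character(utils::packageVersion("twincyto")),
    seed = config$seed,
    config = list(
      normalize = config$normalize, cluster = config$cluster, diff = config$diff,
      panel = panel
    ),
    stages = list()
  )

  # --- input stage -----------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- generate_cytof_cohort(config$cohort)
    events <- cohort$events
    manifest <- cohort$manifest
    truth <- cohort$truth
  } else {
    events <- utils::read.csv(config$events_csv, check.names = FALSE)
    manifest <- utils::read.csv(config$manifest_csv)
    truth <- NULL
  }
  markers <- intersect(panel$marker, colnames(events))
  miss <- setdiff(panel$marker, colnames(events))
  if (length(miss)) {
    .data_error(paste0("panel markers missing from events: ", paste(miss, collapse = ", ")))
  }
  report$stages$input <- list(
    n_cells = nrow(events), n_samples = length(unique(events$sample_id)),
    simulated = !is.null(config$cohort)
  )

  # --- normalization ---------------------------------------------------
  is_ctrl_cell <- if ("is_control" %in% colnames(manifest)) {
    events$sample_id %in% manifest$sample_id[manifest$is_control]
  } else {
    rep(FALSE, nrow(events))
  }
  base_cf <- config$normalize$base_cofactors
  if (is.null(base_cf)) base_cf <- setNames(panel$cofactor, panel$marker)
  n_batches <- length(unique(events$batch))
  if (any(is_ctrl_cell) && n_batches >= 2L) {
    ctrl <- events[is_ctrl_cell, , drop = FALSE]
    cfs <- align_batches(
      split(ctrl[, markers, drop = FALSE], ctrl$batch),
      base_cofactors = base_cf
    )
    y <- .arcsinh_by_batch(events[, markers, drop = FALSE], events$batch, cfs)
    solved <- cfs
  } else {
    y <- arcsinh_transform(events[, markers, drop = FALSE], base_cf)
    solved <- NULL
    if (n_batches >= 2L) {
      warnings <- c(warnings, "multiple batches but no shared controls; batch alignment skipped")
    }
  }
  norm <- percentile_normalize(y, q = config$normalize$q)
  report$stages$normalize <- list(
    q = config$normalize$q, batches = n_batches,
    aligned = !is.null(solved),
    cofactors = if (is.null(solved)) base_cf else solved
  )

  # --- clustering ------------------------------------------------------
  twin_rows <- !is_ctrl_cell
  som <- train_som(
    norm[twin_rows, , drop = FALSE],
    type_markers = type_markers,
    grid = config$cluster$grid, epochs = config$cluster$epochs,
    panel = panel, seed = config$seed
  )
  meta <- consensus_metacluster(
    som$codebook,
    k_range = config$cluster$k_range,
    n_subsamples = config$cluster$n_subsamples,
    subsample_fraction = config$cluster$subsample_fraction,
    elbow_threshold = config$cluster$elbow_threshold,
    seed = config$seed
  )
  cell_meta <- unname(meta$labels[som$mapping])
  report$stages$cluster <- list(
    grid = som$grid, n_nodes = nrow(som$codebook),
    chosen_k = meta$chosen_k, final_qe = som$qe[length(som$qe)]
  )

  # --- differential state ----------------------------------------------
  design <- paired_design(manifest)
  events_n <- data.frame(
    sample_id = events$sample_id[twin_rows],
    norm[twin_rows, , drop = FALSE],
    stringsAsFactors = FALSE, check.names = FALSE
  )
  features <- summarize_clusters(
    events_n, cell_meta,
    markers = state_markers, min_cells = config$diff$min_cells
  )
  test_all <- moderated_paired_test(
    features, design,
    state_markers = state_markers,
    trend = config$diff$trend, min_pairs = config$diff$min_pairs
  )
  test_untreated <- NULL
  filter_report <- NULL
  if (config$diff$untreated_filter) {
    untreated <- design[!design$treated, , drop = FALSE]
    if (length(unique(untreated$pair_id)) < 2L) {
      .config_error("untreated filter enabled but fewer than 2 untreated pairs present")
    }
    test_untreated <- moderated_paired_test(
      features, paired_design(untreated),
      state_markers = state_markers,
      trend = config$diff$trend, min_pairs = config$diff$min_pairs
    )
    filter_report <- dual_filter(test_all, test_untreated, alpha = config$diff$alpha)
  }
  report$stages$diff <- list(
    n_features = nrow(test_all), n_tested = sum(test_all$tested),
    alpha = config$diff$alpha,
    n_significant_all = sum(test_all$p_adj < config$diff$alpha, na.rm = TRUE),
    n_pass_dual_filter = if (is.null(filter_report)) NA_integer_ else sum(filter_report$verdict)
  )

  # --- truth-based composition (simulated runs only) -------------------
  composition <- NULL
  if (!is.null(truth)) {
    pop <- truth$assignments$population[twin_rows]
    tab <- table(metacluster = cell_meta, population = pop)
    composition <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
    colnames(composition) <- c("metacluster", "population", "n_cells")
    frac <- as.data.frame(as.table(tab / rowSums(tab)), stringsAsFactors = FALSE)
    composition$fraction <- frac[[3L]]
  }

  report$warnings <- warnings
  results <- list(
    manifest = manifest, design = design, som = som, metaclusters = meta,
    features = features, test_all = test_all, test_untreated = test_untreated,
    filter_report = filter_report, cluster_composition = composition
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(config$out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(test_all, file.path(config$out_dir, "test_all_pairs.csv"), row.names = FALSE)
    if (!is.null(test_untreated)) {
      utils::write.csv(test_untreated, file.path(config$out_dir, "test_untreated.csv"), row.names = FALSE)
    }
    if (!is.null(filter_report)) {
      utils::write.csv(filter_report, file.path(config$out_dir, "filter_report.csv"), row.names = FALSE)
    }
    jsonlite::write_json(
      report, file.path(config$out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
  }

  structure(list(report = report, results = results), class = "pipeline_run")
}

#' @exportS3Method base::print
print.pipeline_run <- function(x, ...) {
  s <- x$report$stages
  cat("twincyto pipeline run\n")
  cat(sprintf(
    "  input: %d cells, %d samples%s\n", s$input$n_cells, s$input$n_samples,
    if (isTRUE(s$input$simulated)) " (simulated)" else ""
  ))
  cat(sprintf(
    "  clustering: %d nodes -> %d metaclusters\n",
    s$cluster$n_nodes, s$cluster$chosen_k
  ))
  cat(sprintf(
    "  differential state: %d/%d features tested, %d significant (all pairs)%s\n",
    s$diff$n_tested, s$diff$n_features, s$diff$n_significant_all,
    if (!is.na(s$diff$n_pass_dual_filter)) {
      sprintf(", %d pass the dual filter", s$diff$n_pass_dual_filter)
    } else {
      ""
    }
  ))
  invisible(x)
}
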