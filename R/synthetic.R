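#' Describe one cell population of a synthetic cohort
#'
#' A population is a mixture component of the raw-intensity emission model:
#' per marker, intensities are zero-inflated lognormal with median
#' `marker_means[m]` and log-scale standard deviation `marker_dispersions[m]`.
#' A marker mean of 0 yields structural zeros for that marker.
#'
#' @param name Population label.
#' @param weight Mixing proportion in `[0, 1]`.
#' @param marker_means Named vector of nonnegative lognormal medians
#'   (raw-intensity scale).
#' @param marker_dispersions Named vector of positive log-scale SDs; a single
#'   value is recycled over markers.
#' @param zero_inflation Named vector of per-marker zero probabilities in
#'   `[0, 1]`; a single value is recycled. Default 0.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, weight, marker_means, marker_dispersions = 0.35,
                            zero_inflation = 0) {
  markers <- names(marker_means)
  if (is.null(markers) || anyDuplicated(markers)) {
    .config_error("marker_means must be a uniquely named vector")
  }
  if (any(marker_means < 0) || anyNA(marker_means)) {
    .config_error("marker means must be nonnegative")
  }
  if (length(marker_dispersions) == 1L) {
    marker_dispersions <- setNames(rep(marker_dispersions, length(markers)), markers)
  }
  if (length(zero_inflation) == 1L) {
    zero_inflation <- setNames(rep(zero_inflation, length(markers)), markers)
  }
  if (any(marker_dispersions[markers] <= 0)) .config_error("dispersions must be > 0")
  if (any(zero_inflation[markers] < 0 | zero_inflation[markers] > 1)) {
    .config_error("zero_inflation must lie in [0, 1]")
  }
  if (weight < 0 || weight > 1) .config_error("population weight must lie in [0, 1]")
  structure(
    list(
      name = as.character(name), weight = as.numeric(weight),
      marker_means = marker_means[markers],
      marker_dispersions = marker_dispersions[markers],
      zero_inflation = zero_inflation[markers]
    ),
    class = "population_spec"
  )
}

#' Plant a group-specific marker shift
#'
#' Adds `log_fold_change` to the log-intensity of `marker` for cells of
#' `population` in samples of the designated group.
#'
#' @param population Population label present in the cohort config.
#' @param marker Marker label present in the panel of the config.
#' @param log_fold_change Additive shift on the natural-log intensity scale.
#' @param applies_to `"affected"` or `"unaffected"`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(population, marker, log_fold_change,
                           applies_to = c("affected", "unaffected")) {
  applies_to <- match.arg(applies_to)
  structure(
    list(
      population = as.character(population), marker = as.character(marker),
      log_fold_change = as.numeric(log_fold_change), applies_to = applies_to
    ),
    class = "planted_effect"
  )
}

#' Configure a synthetic twin cohort
#'
#' The generated design mirrors a discordant-twin mass cytometry study:
#' `n_pairs` twin pairs, each contributing one affected and one unaffected
#' sample run in the same acquisition batch; two batches with multiplicative
#' per-marker scale shifts; and two normalization-control samples measured in
#' both batches so that batch alignment is identifiable. Treatment effects
#' (mimicking disease-modifying therapy) are applied only to the affected twin
#' of treated pairs.
#'
#' @param n_pairs Number of twin pairs.
#' @param n_untreated_pairs Number of pairs whose affected twin is untreated
#'   (these are the first pairs); must not exceed `n_pairs`.
#' @param n_cells_per_sample Cells generated per sample (>= 1).
#' @param populations List of [population_spec()] objects; weights must sum
#'   to 1 and all populations must share one marker panel.
#' @param planted_effects List of [planted_effect()] disease effects.
#' @param treatment_effects List of [planted_effect()] effects applied only to
#'   treated affected twins.
#' @param batch_scale_sd SD of the log multiplicative per-(marker, batch)
#'   scale factor.
#' @param pair_effect_sd SD of the additive log-intensity shift shared by both
#'   twins of a pair (per marker) — the data-level rendering of a shared early
#'   environment.
#' @param seed Integer seed; all randomness flows from it through named
#'   substreams.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_pairs, n_untreated_pairs, n_cells_per_sample,
                          populations, planted_effects = list(),
                          treatment_effects = list(),
                          batch_scale_sd = 0.1, pair_effect_sd = 0.1,
                          seed = 1L) {
  if (!.is_count(n_pairs) || n_pairs < 1) .config_error("n_pairs must be a positive count")
  if (!.is_count(n_untreated_pairs)) .config_error("n_untreated_pairs must be a count")
  if (n_untreated_pairs > n_pairs) .config_error("n_untreated_pairs must be <= n_pairs")
  if (!.is_count(n_cells_per_sample) || n_cells_per_sample < 1) {
    .config_error("n_cells_per_sample must be >= 1")
  }
  if (!length(populations)) .config_error("at least one population is required")
  populations <- lapply(populations, function(p) {
    if (!inherits(p, "population_spec")) .config_error("populations must be population_spec objects")
    p
  })
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) .config_error("population weights must sum to 1")
  markers <- names(populations[[1]]$marker_means)
  for (p in populations) {
    if (!identical(names(p$marker_means), markers)) {
      .config_error("all populations must define the same marker panel in the same order")
    }
  }
  pop_names <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(pop_names)) .config_error("population names must be unique")
  check_eff <- function(effs, what) {
    for (e in effs) {
      if (!inherits(e, "planted_effect")) .config_error(paste(what, "must be planted_effect objects"))
      if (!e$population %in% pop_names) {
        .config_error(paste0("unknown population in ", what, ": ", e$population))
      }
      if (!e$marker %in% markers) {
        .config_error(paste0("unknown marker in ", what, ": ", e$marker))
      }
    }
    effs
  }
  planted_effects <- check_eff(planted_effects, "planted_effects")
  treatment_effects <- check_eff(treatment_effects, "treatment_effects")
  if (batch_scale_sd < 0 || pair_effect_sd < 0) .config_error("effect SDs must be nonnegative")
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      n_untreated_pairs = as.integer(n_untreated_pairs),
      n_cells_per_sample = as.integer(n_cells_per_sample),
      populations = populations,
      planted_effects = planted_effects,
      treatment_effects = treatment_effects,
      batch_scale_sd = as.numeric(batch_scale_sd),
      pair_effect_sd = as.numeric(pair_effect_sd),
      seed = as.integer(seed),
      markers = markers,
      population_names = pop_names
    ),
    class = "cohort_config"
  )
}

# population-level parameter matrices (populations x markers)
.pop_matrices <- function(config) {
  M <- length(config$markers)
  P <- length(config$populations)
  mu <- matrix(NA_real_, P, M, dimnames = list(config$population_names, config$markers))
  disp <- mu
  zi <- mu
  for (i in seq_len(P)) {
    p <- config$populations[[i]]
    mu[i, ] <- log(p$marker_means) # -Inf encodes structural zero
    disp[i, ] <- p$marker_dispersions
    zi[i, ] <- p$zero_inflation
  }
  list(mu = mu, disp = disp, zi = zi)
}

#' Generate a synthetic twin-cohort cytometry run
#'
#' Emits an event table (one row per cell with raw marker intensities), a
#' sample manifest, and a truth log recording every latent quantity (cell
#' population assignments, realized batch factors, pair effects and planted
#' effects). Identical config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `events` (data.frame: `cell_id`, `sample_id`,
#'   `batch`, marker columns), `manifest` (data.frame: `sample_id`, `pair_id`,
#'   `group`, `treated`, `batch`, `is_control`; `2 * n_pairs` twin rows plus 4
#'   control entries — two control samples, each present in both batches), and
#'   `truth` (list).
#' @export
generate_cytof_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) .config_error("config must be a cohort_config")
  markers <- config$markers
  M <- length(markers)
  pm <- .pop_matrices(config)
  n_pairs <- config$n_pairs
  ncell <- config$n_cells_per_sample
  w <- vapply(config$populations, `[[`, numeric(1), "weight")

  pair_ids <- sprintf("pair%03d", seq_len(n_pairs))
  treated <- seq_len(n_pairs) > config$n_untreated_pairs
  pair_batch <- rep(c(1L, 2L), length.out = n_pairs) # both twins share a batch

  # twin sample table
  manifest <- data.frame(
    sample_id = as.vector(rbind(paste0(pair_ids, "_affected"), paste0(pair_ids, "_unaffected"))),
    pair_id = rep(pair_ids, each = 2L),
    group = rep(c("affected", "unaffected"), times = n_pairs),
    treated = rep(treated, each = 2L),
    batch = rep(pair_batch, each = 2L),
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
  ctrl <- data.frame(
    sample_id = rep(c("control_1", "control_2"), each = 2L),
    pair_id = NA_character_,
    group = "control",
    treated = FALSE,
    batch = rep(c(1L, 2L), times = 2L),
    is_control = TRUE,
    stringsAsFactors = FALSE
  )
  manifest <- rbind(manifest, ctrl)

  # named substreams: batch factors, pair effects, twin cells, control cells
  bf <- .with_seed(
    .substream(config$seed, "batches"),
    matrix(exp(rnorm(2L * M, 0, config$batch_scale_sd)), 2L, M,
      dimnames = list(c("1", "2"), markers)
    )
  )
  pe <- .with_seed(
    .substream(config$seed, "pairs"),
    matrix(rnorm(n_pairs * M, 0, config$pair_effect_sd), n_pairs, M,
      dimnames = list(pair_ids, markers)
    )
  )

  n_twin <- 2L * n_pairs * ncell
  twin <- manifest[!manifest$is_control, ]
  cell_sample <- rep(twin$sample_id, each = ncell)
  cell_pair <- rep(match(twin$pair_id, pair_ids), each = ncell)
  cell_group <- rep(twin$group, each = ncell)
  cell_treated <- rep(twin$treated, each = ncell)
  cell_batch <- rep(twin$batch, each = ncell)

  twin_dat <- .with_seed(.substream(config$seed, "cells"), {
    pop_idx <- sample.int(length(w), n_twin, replace = TRUE, prob = w)
    X <- matrix(0, n_twin, M, dimnames = list(NULL, markers))
    for (m in seq_len(M)) {
      mu_c <- pm$mu[pop_idx, m] + pe[cell_pair, m]
      for (e in config$planted_effects) {
        if (e$marker == markers[m]) {
          hit <- cell_group == e$applies_to &
            config$population_names[pop_idx] == e$population
          mu_c[hit] <- mu_c[hit] + e$log_fold_change
        }
      }
      for (e in config$treatment_effects) {
        if (e$marker == markers[m]) {
          hit <- cell_treated & cell_group == e$applies_to &
            config$population_names[pop_idx] == e$population
          mu_c[hit] <- mu_c[hit] + e$log_fold_change
        }
      }
      x <- exp(mu_c + rnorm(n_twin, 0, 1) * pm$disp[pop_idx, m]) * bf[cell_batch, m]
      zi_m <- pm$zi[pop_idx, m]
      if (any(zi_m > 0)) x[runif(n_twin) < zi_m] <- 0
      X[, m] <- x
    }
    list(pop_idx = pop_idx, X = X)
  })

  # controls: the same base material measured once per batch (batch factor is
  # the only difference between a control's two entries)
  ctrl_dat <- .with_seed(.substream(config$seed, "controls"), {
    n_ctrl <- 2L * ncell
    pop_idx <- sample.int(length(w), n_ctrl, replace = TRUE, prob = w)
    B <- matrix(0, n_ctrl, M, dimnames = list(NULL, markers))
    for (m in seq_len(M)) {
      x <- exp(pm$mu[pop_idx, m] + rnorm(n_ctrl, 0, 1) * pm$disp[pop_idx, m])
      zi_m <- pm$zi[pop_idx, m]
      if (any(zi_m > 0)) x[runif(n_ctrl) < zi_m] <- 0
      B[, m] <- x
    }
    list(pop_idx = pop_idx, B = B)
  })
  ctrl_sample_base <- rep(c("control_1", "control_2"), each = ncell)
  ctrl_X <- rbind(
    ctrl_dat$B * rep(bf[1L, ], each = 2L * ncell),
    ctrl_dat$B * rep(bf[2L, ], each = 2L * ncell)
  )
  ctrl_sample <- rep(ctrl_sample_base, times = 2L)
  ctrl_batch <- rep(c(1L, 2L), each = 2L * ncell)
  ctrl_pop <- rep(ctrl_dat$pop_idx, times = 2L)

  n_all <- n_twin + 4L * ncell
  cell_id <- sprintf("c%08d", seq_len(n_all))
  events <- data.frame(
    cell_id = cell_id,
    sample_id = c(cell_sample, ctrl_sample),
    batch = c(cell_batch, ctrl_batch),
    stringsAsFactors = FALSE
  )
  events <- cbind(events, as.data.frame(rbind(twin_dat$X, ctrl_X)))
  rownames(events) <- NULL

  truth <- list(
    assignments = data.frame(
      cell_id = cell_id,
      sample_id = events$sample_id,
      population = config$population_names[c(twin_dat$pop_idx, ctrl_pop)],
      stringsAsFactors = FALSE
    ),
    batch_factors = bf,
    pair_effects = pe,
    planted_effects = config$planted_effects,
    treatment_effects = config$treatment_effects
  )
  list(events = events, manifest = manifest, truth = truth)
}

#' Generate paired stimulated/unstimulated cytokine runs
#'
#' Emulates the data shape of an ex vivo activation experiment: the
#' unstimulated table carries background cytokine intensity only; the
#' stimulated table adds a responder subpopulation with an elevated cytokine
#' signal (shift on the log-intensity scale, shared across cytokines within a
#' responding cell).
#'
#' @param config A [cohort_config()]; its twin samples and cell count define
#'   the run layout.
#' @param cytokines Character vector of cytokine channel names, disjoint from
#'   the lineage panel.
#' @param responder_fraction Probability that a stimulated cell responds.
#' @param responder_shift Log-intensity shift added to responding cells.
#' @param background_median,background_sdlog Background lognormal parameters.
#' @return List with `stimulated` and `unstimulated` event tables (cell_id,
#'   sample_id, cytokine columns) and `truth` (responder indicator).
#' @export
generate_stimulation_run <- function(config, cytokines, responder_fraction = 0.2,
                                     responder_shift = 2,
                                     background_median = 1, background_sdlog = 0.5) {
  if (!inherits(config, "cohort_config")) .config_error("config must be a cohort_config")
  if (!length(cytokines)) .config_error("cytokine list must be nonempty")
  if (any(cytokines %in% config$markers)) {
    .config_error("cytokine labels must be disjoint from lineage markers")
  }
  if (responder_fraction < 0 || responder_fraction > 1) {
    .config_error("responder_fraction must lie in [0, 1]")
  }
  samples <- as.vector(rbind(
    sprintf("pair%03d_affected", seq_len(config$n_pairs)),
    sprintf("pair%03d_unaffected", seq_len(config$n_pairs))
  ))
  n <- length(samples) * config$n_cells_per_sample
  sample_col <- rep(samples, each = config$n_cells_per_sample)
  gen_tab <- function(seed_name, responders) {
    .with_seed(.substream(config$seed, seed_name), {
      X <- matrix(0, n, length(cytokines), dimnames = list(NULL, cytokines))
      is_resp <- if (responders && responder_fraction > 0) {
        runif(n) < responder_fraction
      } else {
        rep(FALSE, n)
      }
      for (j in seq_along(cytokines)) {
        mu <- log(background_median) + ifelse(is_resp, responder_shift, 0)
        X[, j] <- exp(rnorm(n, mu, background_sdlog))
      }
      list(X = X, is_resp = is_resp)
    })
  }
  un <- gen_tab("unstim", responders = FALSE)
  st <- gen_tab("stim", responders = TRUE)
  mk <- function(g, prefix) {
    data.frame(
      cell_id = sprintf("%s%08d", prefix, seq_len(n)),
      sample_id = sample_col,
      g$X,
      stringsAsFactors = FALSE,
      check.names = FALSE
    )
  }
  list(
    stimulated = mk(st, "s"),
    unstimulated = mk(un, "u"),
    truth = list(responders = st$is_resp)
  )
}

#' Configure a synthetic MZ/DZ twin-trait simulation
#'
#' Traits follow the classical ACE covariance structure: additive-genetic
#' values are fully shared within monozygotic pairs and correlated 0.5 within
#' dizygotic pairs; the shared-environment component is common to every pair;
#' the unique-environment component is independent. Hence
#' `cov_MZ = var_a + var_c`, `cov_DZ = var_a/2 + var_c`, and total variance
#' `var_a + var_c + var_e`.
#'
#' @param n_mz_pairs,n_dz_pairs Pair counts.
#' @param var_a,var_c Nonnegative additive-genetic and shared-environment
#'   variances.
#' @param var_e Positive unique-environment variance.
#' @param mean Trait mean.
#' @param seed Integer seed.
#' @return A `twin_trait_config` list.
#' @export
twin_trait_config <- function(n_mz_pairs, n_dz_pairs, var_a, var_c, var_e,
                              mean = 0, seed = 1L) {
  if (!.is_count(n_mz_pairs) || !.is_count(n_dz_pairs)) {
    .config_error("pair counts must be nonnegative integers")
  }
  if (var_a < 0 || var_c < 0) .config_error("var_a and var_c must be nonnegative")
  if (var_e <= 0) .config_error("var_e must be positive")
  structure(
    list(
      n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
      var_a = as.numeric(var_a), var_c = as.numeric(var_c), var_e = as.numeric(var_e),
      mean = as.numeric(mean), seed = as.integer(seed)
    ),
    class = "twin_trait_config"
  )
}

#' Simulate MZ/DZ twin traits under an ACE model
#'
#' @param config A [twin_trait_config()].
#' @return A data.frame (`pair_id`, `zygosity` in `{"MZ","DZ"}`, `y1`, `y2`).
#' @export
generate_twin_traits <- function(config) {
  if (!inherits(config, "twin_trait_config")) .config_error("config must be a twin_trait_config")
  .with_seed(.substream(config$seed, "traits"), {
    sim_group <- function(n, r_a) {
      if (n == 0L) {
        return(matrix(numeric(0), 0, 2))
      }
      a_shared <- rnorm(n, 0, sqrt(config$var_a * r_a))
      a1 <- a_shared + rnorm(n, 0, sqrt(config$var_a * (1 - r_a)))
      a2 <- a_shared + rnorm(n, 0, sqrt(config$var_a * (1 - r_a)))
      c_shared <- rnorm(n, 0, sqrt(config$var_c))
      y1 <- config$mean + a1 + c_shared + rnorm(n, 0, sqrt(config$var_e))
      y2 <- config$mean + a2 + c_shared + rnorm(n, 0, sqrt(config$var_e))
      cbind(y1, y2)
    }
    mz <- sim_group(config$n_mz_pairs, r_a = 1)
    dz <- sim_group(config$n_dz_pairs, r_a = 0.5)
    data.frame(
      pair_id = c(
        sprintf("mz%05d", seq_len(config$n_mz_pairs)),
        sprintf("dz%05d", seq_len(config$n_dz_pairs))
      ),
      zygosity = c(rep("MZ", config$n_mz_pairs), rep("DZ", config$n_dz_pairs)),
      y1 = c(mz[, 1], dz[, 1]),
      y2 = c(mz[, 2], dz[, 2]),
      stringsAsFactors = FALSE
    )
  })
}
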