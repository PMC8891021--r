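test_that("cohort bookkeeping matches the design layout", {
  cfg <- toy_cohort_config(n_pairs = 4L, n_cells = 500L)
  co <- generate_cytof_cohort(cfg)
  # 8 twin samples + 4 control entries (2 controls x 2 batches)
  expect_equal(nrow(co$manifest), 12L)
  expect_equal(sum(!co$manifest$is_control), 8L)
  expect_equal(sum(co$manifest$is_control), 4L)
  # 4 pairs x 2 twins x 500 cells + 2 controls x 2 batches x 500 cells
  expect_equal(nrow(co$events), 4L * 2L * 500L + 2L * 2L * 500L)
  expect_true(all(co$events[, cfg$markers] >= 0))
  # both twins of a pair share an acquisition batch
  twin <- co$manifest[!co$manifest$is_control, ]
  expect_true(all(tapply(twin$batch, twin$pair_id, function(b) length(unique(b))) == 1))
  # every cell appears exactly once in the truth log
  expect_identical(sort(co$truth$assignments$cell_id), sort(co$events$cell_id))
  expect_false(anyDuplicated(co$events$cell_id) > 0)
})

test_that("generation is deterministic and invalid configs are rejected", {
  cfg <- toy_cohort_config(n_pairs = 3L, n_cells = 200L, seed = 42L)
  expect_identical(generate_cytof_cohort(cfg), generate_cytof_cohort(cfg))

  pops <- list(population_spec("p1", 1, c(m1 = 5, m2 = 3)))
  expect_error(
    cohort_config(2, 1, 0, pops),
    "n_cells_per_sample"
  )
  expect_error(
    cohort_config(2, 1, 100, pops,
      planted_effects = list(planted_effect("nope", "m1", 1))
    ),
    "unknown population"
  )
  expect_error(
    cohort_config(2, 1, 100, pops,
      planted_effects = list(planted_effect("p1", "nope", 1))
    ),
    "unknown marker"
  )
  expect_error(
    cohort_config(2, 1, 100, list(population_spec("p1", 0.5, c(m1 = 5)))),
    "sum to 1"
  )
  expect_error(cohort_config(2, 3, 100, pops), "n_untreated_pairs")
})

test_that("planted effects shift the transformed group medians in the target population", {
  # Monte-Carlo over 200 seeds: the affected-vs-unaffected median difference
  # of the planted marker, within the planted population, is positive in at
  # least 95% of seeds.
  n_seeds <- 200L
  positive <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- example_cohort_config(
      n_pairs = 2L, n_untreated_pairs = 2L, n_cells_per_sample = 2000L,
      planted_effects = list(planted_effect("naive_Th", "CD25", 1.0, "affected")),
      seed = 1000L + s
    )
    co <- generate_cytof_cohort(cfg)
    ev <- co$events
    pop <- co$truth$assignments$population
    grp <- sub(".*_", "", ev$sample_id)
    y <- asinh(ev$CD25 / 5)
    in_pop <- pop == "naive_Th" & grp %in% c("affected", "unaffected")
    positive[s] <- median(y[in_pop & grp == "affected"]) >
      median(y[in_pop & grp == "unaffected"])
  }
  expect_gte(mean(positive), 0.95)
})

test_that("treatment effects are confined to treated affected twins", {
  cfg <- example_cohort_config(
    n_pairs = 6L, n_untreated_pairs = 3L, n_cells_per_sample = 3000L,
    treatment_effects = list(planted_effect("memory_Th", "CD69", 2.0, "affected")),
    seed = 7L
  )
  co <- generate_cytof_cohort(cfg)
  ev <- co$events
  pop <- co$truth$assignments$population
  man <- co$manifest
  treated_aff <- man$sample_id[man$treated & man$group == "affected"]
  untreated_aff <- man$sample_id[!man$treated & !man$is_control & man$group == "affected"]
  in_pop <- pop == "memory_Th"
  y <- asinh(ev$CD69 / 5)
  m_treated <- median(y[in_pop & ev$sample_id %in% treated_aff])
  m_untreated <- median(y[in_pop & ev$sample_id %in% untreated_aff])
  expect_gt(m_treated, m_untreated + 0.2)
})

test_that("stimulation runs carry responders only in the stimulated table", {
  cfg <- toy_cohort_config(n_pairs = 2L, n_cells = 500L)
  expect_error(generate_stimulation_run(cfg, character()), "nonempty")
  expect_error(generate_stimulation_run(cfg, "CD25"), "disjoint")

  # responder fraction 0: stimulated and unstimulated identical in law
  ks_ok <- logical(100L)
  for (s in seq_len(100L)) {
    # tables small enough for the exact two-sample KS distribution
    cfg_s <- toy_cohort_config(n_pairs = 2L, n_cells = 20L, seed = 2000L + s)
    run <- generate_stimulation_run(cfg_s, "IFNg", responder_fraction = 0)
    ks <- suppressWarnings(stats::ks.test(run$stimulated$IFNg, run$unstimulated$IFNg))
    ks_ok[s] <- ks$p.value > 0.05
  }
  expect_gte(mean(ks_ok), 0.94)

  # responder fraction 0.2 with a strong shift: fraction above the
  # unstimulated 99th percentile ~ 0.2 responders + 1% background
  run <- generate_stimulation_run(
    toy_cohort_config(n_pairs = 10L, n_cells = 1000L, seed = 5L),
    "IFNg",
    responder_fraction = 0.2, responder_shift = 4
  )
  thr <- quantile(asinh(run$unstimulated$IFNg / 5), 0.99, names = FALSE)
  frac <- mean(asinh(run$stimulated$IFNg / 5) > thr)
  expect_equal(frac, 0.2 * 1 + 0.8 * 0.01, tolerance = 0.15)
})

test_that("twin-trait covariance matches the ACE closed forms", {
  # independence: no A, no C
  tt0 <- generate_twin_traits(twin_trait_config(10000L, 0L, 0, 0, 1, seed = 3L))
  expect_lt(abs(cor(tt0$y1, tt0$y2)), 0.05)

  tt <- generate_twin_traits(twin_trait_config(50000L, 50000L, 0.5, 0.3, 0.2, seed = 4L))
  mz <- tt[tt$zygosity == "MZ", ]
  dz <- tt[tt$zygosity == "DZ", ]
  expect_equal(cov(mz$y1, mz$y2), 0.8, tolerance = 0.01 / 0.8)
  expect_equal(cov(dz$y1, dz$y2), 0.55, tolerance = 0.01 / 0.55)
  expect_equal(var(c(tt$y1, tt$y2)), 1.0, tolerance = 0.02)
  expect_identical(tt, generate_twin_traits(twin_trait_config(50000L, 50000L, 0.5, 0.3, 0.2, seed = 4L)))
  expect_error(twin_trait_config(10, 10, -0.1, 0, 1), "nonnegative")
  expect_error(twin_trait_config(10, 10, 0.5, 0, 0), "positive")
})
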