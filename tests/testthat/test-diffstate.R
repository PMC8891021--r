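test_that("feature enumeration is the cluster-major Cartesian product", {
  f <- enumerate_features(sprintf("c%03d", 1:100), paste0("s", 1:14))
  expect_equal(nrow(f), 1400L)
  f23 <- enumerate_features(c("c1", "c2"), c("x", "y", "z"))
  expect_equal(f23$cluster_id, rep(c("c1", "c2"), each = 3))
  expect_equal(f23$marker, rep(c("x", "y", "z"), 2))
  expect_equal(nrow(enumerate_features("c", "m")), 1L)
  expect_error(enumerate_features(c("a", "a"), "m"), "duplicate")
})

test_that("moderated test with zero prior df equals the textbook paired t", {
  gm <- make_gaussian_features(8, 10, c("m1", "m2"), seed = 2)
  res <- moderated_paired_test(gm$features, gm$design, c("m1", "m2"), prior_df = 0)
  for (i in seq_len(nrow(res))) {
    cl <- res$cluster_id[i]
    mk <- res$marker[i]
    ft <- gm$features
    aff <- ft[[mk]][ft$cluster_id == cl & grepl("_a$", ft$sample_id)]
    una <- ft[[mk]][ft$cluster_id == cl & grepl("_u$", ft$sample_id)]
    tt <- t.test(aff, una, paired = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("infinite prior df shrinks every variance to the common prior", {
  gm <- make_gaussian_features(10, 20, "m1", seed = 3)
  res <- moderated_paired_test(gm$features, gm$design, "m1", prior_df = Inf)
  expect_equal(length(unique(round(res$s2_post, 12))), 1L)
  expect_equal(res$s2_post, res$s2_prior)
})

test_that("empirical-Bayes moment matching agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(4)
  df <- 15
  s2 <- 0.5 * rchisq(400, df) / df * rf(400, 40, 40)
  sq <- twincyto:::.squeeze_var(s2, rep(df, 400))
  lref <- limma::squeezeVar(s2, df = df)
  expect_equal(sq$df_prior, lref$df.prior, tolerance = 0.05)
  expect_equal(mean(sq$var_prior), mean(lref$var.prior), tolerance = 0.02)
  # posterior variances from the two routes agree feature-wise
  post_own <- (sq$df_prior * sq$var_prior + df * s2) / (sq$df_prior + df)
  expect_equal(post_own, lref$var.post, tolerance = 0.02)
})

test_that("global-null moderated p-values are approximately uniform", {
  gm <- make_gaussian_features(20, 500, paste0("m", 1:10), seed = 5)
  res <- moderated_paired_test(gm$features, gm$design, paste0("m", 1:10))
  expect_equal(nrow(res), 5000L)
  ks <- max(abs(sort(res$p) - (seq_along(res$p) - 0.5) / length(res$p)))
  expect_lt(ks, 0.02)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
})

test_that("features observed in too few pairs are flagged, not tested", {
  gm <- make_gaussian_features(4, 3, "m1", seed = 6)
  ft <- gm$features
  # remove one cluster's rows from all but one pair
  drop <- ft$cluster_id == "c001" & !grepl("^p01", ft$sample_id)
  ft$m1[drop] <- NA_real_
  res <- moderated_paired_test(ft, gm$design, "m1")
  expect_false(res$tested[res$cluster_id == "c001"])
  expect_true(is.na(res$p[res$cluster_id == "c001"]))
  expect_true(all(res$tested[res$cluster_id != "c001"]))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # random vectors against a literal p * m / rank + cummin implementation
  set.seed(7)
  for (i in 1:5) {
    p <- runif(20)
    o <- order(p, decreasing = TRUE)
    manual <- pmin(1, cummin(p[o] * length(p) / rank(p)[o]))[order(o)]
    expect_equal(bh_adjust(p), manual)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the dual filter demands concordant significance in both screens", {
  base <- data.frame(
    feature_id = c("f1", "f2", "f3", "f4", "f5"),
    cluster_id = "c", marker = c("a", "b", "c", "d", "e"),
    stringsAsFactors = FALSE
  )
  all_res <- cbind(base,
    effect = c(1, 1, 1, -1, 1),
    p_adj = c(0.01, 0.01, 0.20, 0.01, 0.01),
    tested = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  untr_res <- cbind(base,
    effect = c(1, -1, 1, -1, 1),
    p_adj = c(0.01, 0.01, 0.01, 0.01, 0.01),
    tested = TRUE
  )
  fr <- dual_filter(all_res, untr_res, alpha = 0.05)
  expect_equal(fr$verdict, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # f2: discordant signs; f3: significant in untreated only; f5: untested
  expect_false(fr$tested[5])
  expect_equal(fr$verdict, fr$sig_all & fr$sig_untreated & fr$sign_concordant)
  expect_error(dual_filter(all_res, untr_res[c(2:5, 1), ]), "share")
})

test_that("signed-rank test matches enumeration and permutation oracles", {
  # identical pairs: degenerate
  r0 <- paired_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(r0$degenerate)
  expect_equal(r0$p.value, 1)
  expect_equal(r0$effect_size, 0)

  # differences {+1, +2, +3}: exact two-sided p = 2/8
  r <- paired_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$p.value, 0.25)

  # exact route equals full sign enumeration for n <= 8
  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r <- paired_signed_rank(x, y)
    expect_equal(r$p.value, signed_rank_perm_p(x - y), tolerance = 1e-12)
  }

  # large-sample approximation close to the permutation law
  set.seed(9)
  x <- rnorm(40) + 0.5
  y <- rnorm(40)
  r <- paired_signed_rank(x, y)
  d <- x - y
  set.seed(10)
  perm <- replicate(20000, {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    abs(sum(rank(abs(d))[(s * abs(d)) > 0]) - length(d) * (length(d) + 1) / 4)
  })
  obs <- abs(sum(rank(abs(d))[d > 0]) - length(d) * (length(d) + 1) / 4)
  expect_lt(abs(r$p.value - mean(perm >= obs - 1e-12)), 1e-2)
})

test_that("rank-sum test matches the enumeration oracle", {
  # complete separation 3 vs 3: exact two-sided p = 2 / choose(6, 3)
  r <- unpaired_rank_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$p.value, 0.1)
  # permuted copies of one set: p = 1 by symmetry
  r1 <- unpaired_rank_test(c(5, 1, 9), c(9, 5, 1))
  expect_equal(r1$p.value, 1)
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:5, 1))
    b <- rnorm(sample(3:4, 1))
    expect_equal(
      unpaired_rank_test(a, b)$p.value,
      rank_sum_perm_p(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("latent-pair logistic LRT is calibrated and finds planted genes", {
  set.seed(12)
  n_cells <- 80
  pairs <- rep(sprintf("p%02d", 1:8), each = 10)
  group <- rep(rep(c("MS", "HC"), each = 5), 8)
  # constant gene is not tested
  expr0 <- matrix(0, 1, n_cells, dimnames = list("flat", NULL))
  r0 <- lr_latent_test(expr0, group, pairs)
  expect_false(r0$tested)

  # null genes: uniform-ish p, Bonferroni >= raw
  expr <- matrix(rnorm(150 * n_cells), 150, n_cells,
    dimnames = list(paste0("g", 1:150), NULL)
  )
  rn <- lr_latent_test(expr, group, pairs)
  expect_true(all(rn$p_bonf >= rn$p, na.rm = TRUE))
  ks <- suppressWarnings(stats::ks.test(rn$p, "punif"))
  expect_gt(ks$p.value, 0.001)

  # a strongly separating gene attains the minimum adjusted p
  hits <- vapply(1:50, function(s) {
    set.seed(100 + s)
    e <- matrix(rnorm(100 * n_cells), 100, n_cells,
      dimnames = list(paste0("g", 1:100), NULL)
    )
    e[1, ] <- e[1, ] + ifelse(group == "MS", 2.5, 0)
    rr <- lr_latent_test(e, group, pairs)
    which.min(rr$p_bonf) == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("clonal expansion fraction uses the strict n > 2 rule", {
  t1 <- data.frame(cell_id = 1:7, clonotype_id = c(rep("a", 5), "b", "c"))
  expect_equal(clonal_expansion_fraction(t1), 5 / 7)
  t2 <- data.frame(cell_id = 1:4, clonotype_id = letters[1:4])
  expect_equal(clonal_expansion_fraction(t2), 0)
  t3 <- data.frame(
    cell_id = 1:8,
    clonotype_id = c(rep("a", 3), rep("b", 3), rep("c", 2))
  )
  expect_equal(clonal_expansion_fraction(t3), 0.75) # the 2-cell clone is not expanded
  expect_warning(
    out <- clonal_expansion_fraction(data.frame(cell_id = 1, clonotype_id = NA)),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("QC filters apply strict thresholds on genes, mito and beta chains", {
  n_genes <- 600
  genes <- c(paste0("MT-", 1:10), paste0("g", 1:(n_genes - 10)))
  counts <- matrix(1L, n_genes, 4, dimnames = list(genes, paste0("cell", 1:4)))
  counts[501:n_genes, 2] <- 0L # cell2: 500 detected genes exactly
  counts[500:n_genes, 3] <- 0L # cell3: 499 detected genes
  # cell4: high mito fraction (> 15%)
  counts[1:10, 4] <- 40L
  res <- qc_filter_cells(counts, mito_genes = paste0("MT-", 1:10))
  expect_true("cell2" %in% res$cells) # exactly 500 genes retained
  expect_false("cell3" %in% res$cells) # strict < 500 removed
  expect_false("cell4" %in% res$cells) # mito 40*10/(590+400) > 0.15
  # mito boundary: 0.150 retained, 0.151 removed
  m <- matrix(0L, 1000, 2, dimnames = list(
    c("MT-1", paste0("g", 1:999)), c("lo", "hi")
  ))
  m[2:1000, ] <- 1L
  m["MT-1", "lo"] <- round(0.150 / 0.850 * 999)
  m["MT-1", "hi"] <- ceiling(0.152 / 0.848 * 999)
  resm <- qc_filter_cells(m, mito_genes = "MT-1", min_cells_per_gene = 1)
  expect_true("lo" %in% resm$cells)
  expect_false("hi" %in% resm$cells)
  # beta-chain rule and the <3-cells gene filter
  cl <- data.frame(cell_id = c("cell1", "cell2"), n_beta_chains = c(3L, 2L))
  res2 <- qc_filter_cells(counts, mito_genes = character(), clonotypes = cl)
  expect_false("cell1" %in% res2$cells)
  rare <- rbind(
    rare = c(1, 1, 0, 0), # expressed in 2 cells: below the 3-cell rule
    ok = c(1, 1, 1, 0), # expressed in exactly 3 cells: retained
    matrix(1, 600, 4, dimnames = list(paste0("f", 1:600), NULL))
  )
  colnames(rare) <- paste0("c", 1:4)
  res3 <- qc_filter_cells(rare, min_genes = 100)
  expect_false("rare" %in% res3$genes)
  expect_true("ok" %in% res3$genes)
})
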