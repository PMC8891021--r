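#' Build and validate a paired twin design
#'
#' @param manifest Data.frame with `sample_id`, `pair_id`, `group`
#'   (`"affected"`/`"unaffected"`), `treated` (logical); control rows
#'   (`is_control`) are dropped if present.
#' @return A validated `paired_design` data.frame.
#' @export
paired_design <- function(manifest) {
  d <- as.data.frame(manifest)
  if ("is_control" %in% colnames(d)) d <- d[!d$is_control, , drop = FALSE]
  need <- c("sample_id", "pair_id", "group", "treated")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) .data_error(paste0("design lacks columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$sample_id)) .data_error("sample ids must be unique")
  sp <- split(d, d$pair_id)
  for (p in sp) {
    if (nrow(p) != 2L || !setequal(p$group, c("affected", "unaffected"))) {
      .data_error(paste0("pair '", p$pair_id[1L], "' must have exactly one affected and one unaffected sample"))
    }
    if (length(unique(p$treated)) != 1L) {
      .data_error(paste0("treated flag differs within pair '", p$pair_id[1L], "'"))
    }
  }
  d <- d[, need]
  class(d) <- c("paired_design", "data.frame")
  d
}

#' Enumerate differential-state features
#'
#' The Cartesian product of clusters and cell-state markers in cluster-major
#' order; 100 clusters x 14 state markers give the canonical 1,400 features.
#'
#' @param cluster_ids Character/integer vector of cluster ids (unique).
#' @param state_markers Character vector of state markers (unique).
#' @return Data.frame (`feature_id`, `cluster_id`, `marker`).
#' @export
#' @examples
#' nrow(enumerate_features(1:100, paste0("s", 1:14))) # 1400
enumerate_features <- function(cluster_ids, state_markers) {
  if (!length(cluster_ids) || !length(state_markers)) {
    .data_error("cluster and marker lists must be nonempty")
  }
  if (anyDuplicated(cluster_ids)) .data_error("duplicate cluster ids")
  if (anyDuplicated(state_markers)) .data_error("duplicate state markers")
  cluster_ids <- as.character(cluster_ids)
  out <- data.frame(
    cluster_id = rep(cluster_ids, each = length(state_markers)),
    marker = rep(state_markers, times = length(cluster_ids)),
    stringsAsFactors = FALSE
  )
  out <- cbind(feature_id = paste(out$cluster_id, out$marker, sep = ":"), out)
  out$feature_id <- as.character(out$feature_id)
  out
}

# Newton inversion of the trigamma function (Smyth-style), vectorized.
.trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  todo <- is.na(out)
  x <- 0.5 + 1 / y[todo]
  if (any(todo)) {
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[todo] <- x
  }
  out
}

# Empirical-Bayes moment matching of a scaled-F prior to an ensemble of
# sample variances: returns prior df d0 and prior variance s0^2 (a fitted
# function of `covariate` when trend = TRUE).
.squeeze_var <- function(s2, df, covariate = NULL, span = 0.5) {
  ok <- is.finite(s2) & is.finite(df) & df > 0 & s2 > 0
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  if (!is.null(covariate)) {
    cv <- covariate[ok]
    fit <- lowess(cv, e, f = span)
    emean <- stats::approx(fit$x, fit$y, xout = cv, rule = 2)$y
  } else {
    emean <- rep(mean(e), length(e))
  }
  n <- length(e)
  evar <- sum((e - emean)^2) / max(n - 1, 1) - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    var_prior_ok <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior_ok <- exp(emean)
  }
  var_prior <- rep(NA_real_, length(s2))
  var_prior[ok] <- var_prior_ok
  if (any(!ok)) var_prior[!ok] <- mean(var_prior_ok)
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Paired empirical-Bayes moderated differential-state test
#'
#' For every (cluster, state-marker) feature, the paired linear model with a
#' group effect and pair blocking reduces to a one-sample analysis of the
#' within-pair differences of cluster medians (affected minus unaffected):
#' effect = mean difference, `s^2` its sample variance on `d = n_pairs - 1`
#' df. The variances are shrunk toward an empirical-Bayes prior,
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, with `(d0, s0^2)` estimated by
#' moment-matching a scaled-F distribution to the `log s^2` ensemble (with
#' `s0^2` a smooth function of mean cluster abundance when `trend = TRUE`).
#' The moderated t statistic `effect / (s_tilde / sqrt(n))` is referred to a
#' t distribution on `d + d0` df, and p-values are BH-adjusted.
#'
#' @param features Feature table from [summarize_clusters()] (normalized
#'   medians).
#' @param design A [paired_design()] (or manifest coercible to one).
#' @param state_markers Cell-state markers to test.
#' @param trend Model the prior variance as a function of mean cluster
#'   abundance (limma-trend style).
#' @param prior_df Override the estimated prior df `d0` (0 disables
#'   shrinkage; `Inf` forces full shrinkage to the prior).
#' @param min_pairs Minimum complete pairs for a feature to be tested.
#' @return A `moderated_test` data.frame: `feature_id`, `cluster_id`,
#'   `marker`, `n_pairs`, `effect`, `s2`, `df`, `df_prior`, `s2_prior`,
#'   `s2_post`, `t`, `p`, `p_adj`, `tested`.
#' @export
moderated_paired_test <- function(features, design, state_markers,
                                  trend = FALSE, prior_df = NULL,
                                  min_pairs = 2L) {
  if (!inherits(design, "paired_design")) design <- paired_design(design)
  ft <- as.data.frame(features)
  .assert_markers(ft, state_markers)
  ft <- ft[ft$sample_id %in% design$sample_id, , drop = FALSE]
  if (!nrow(ft)) .data_error("no feature rows match the design samples")
  clusters <- sort(unique(as.character(ft$cluster_id)))
  feat <- enumerate_features(clusters, state_markers)

  pairs <- unique(design$pair_id)
  aff <- design$sample_id[match(paste0(pairs, ".affected"), paste(design$pair_id, design$group, sep = "."))]
  una <- design$sample_id[match(paste0(pairs, ".unaffected"), paste(design$pair_id, design$group, sep = "."))]

  # medians as feature x sample matrices, one per marker
  key <- paste(ft$sample_id, ft$cluster_id, sep = "\r")
  D <- matrix(NA_real_, nrow(feat), length(pairs))
  freq_mat <- matrix(NA_real_, length(clusters), nrow(design),
    dimnames = list(clusters, design$sample_id)
  )
  freq_mat[cbind(as.character(ft$cluster_id), ft$sample_id)] <- ft$freq
  for (m in state_markers) {
    med <- setNames(ft[[m]], key)
    rows <- which(feat$marker == m)
    for (j in seq_along(pairs)) {
      da <- med[paste(aff[j], feat$cluster_id[rows], sep = "\r")]
      du <- med[paste(una[j], feat$cluster_id[rows], sep = "\r")]
      D[rows, j] <- da - du
    }
  }

  n_complete <- rowSums(is.finite(D))
  effect <- rowMeans(D, na.rm = TRUE)
  s2 <- apply(D, 1L, function(r) stats::var(r[is.finite(r)]))
  df <- n_complete - 1
  tested <- n_complete >= max(2L, min_pairs) & is.finite(s2) & s2 >= 0

  # abundance covariate for the trend: mean cluster frequency across samples
  mean_abund <- rowMeans(freq_mat, na.rm = TRUE)
  covariate <- if (trend) log(mean_abund[feat$cluster_id] + 1e-8) else NULL

  if (is.null(prior_df)) {
    sq <- .squeeze_var(
      ifelse(tested, s2, NA_real_), ifelse(tested, df, NA_real_),
      covariate = covariate
    )
    df_prior <- sq$df_prior
    s2_prior <- sq$var_prior
  } else {
    df_prior <- as.numeric(prior_df)
    s2_prior <- if (df_prior > 0) {
      sq <- .squeeze_var(
        ifelse(tested, s2, NA_real_), ifelse(tested, df, NA_real_),
        covariate = covariate
      )
      sq$var_prior
    } else {
      rep(NA_real_, length(s2))
    }
  }

  s2_post <- if (is.infinite(df_prior)) {
    s2_prior
  } else if (df_prior == 0) {
    s2
  } else {
    (df_prior * s2_prior + df * s2) / (df_prior + df)
  }
  tstat <- effect / sqrt(s2_post / n_complete)
  df_total <- df + df_prior
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[!tested] <- NA_real_
  tstat[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- bh_adjust(p[tested])

  out <- data.frame(
    feature_id = feat$feature_id, cluster_id = feat$cluster_id,
    marker = feat$marker, n_pairs = n_complete,
    effect = effect, s2 = s2, df = df,
    df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post,
    t = tstat, p = p, p_adj = p_adj, tested = tested,
    stringsAsFactors = FALSE
  )
  class(out) <- c("moderated_test", "data.frame")
  out
}

#' @exportS3Method base::print
print.moderated_test <- function(x, alpha = 0.05, ...) {
  cat(sprintf(
    "Moderated paired differential-state test: %d features (%d tested), prior df = %.2f\n",
    nrow(x), sum(x$tested), x$df_prior[1L]
  ))
  cat(sprintf(
    "  %d features at BH-adjusted p < %.2f\n",
    sum(x$p_adj < alpha, na.rm = TRUE), alpha
  ))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper around the standard step-up adjustment
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) .data_error("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Treatment-robust dual filter
#'
#' A feature passes when it is significant (BH-adjusted p below `alpha`) in
#' BOTH the all-pairs and the untreated-pairs analyses AND its effect signs
#' agree — i.e. it distinguishes affected from unaffected twins and is not
#' elicited by disease-modifying therapy. Features untested in either run
#' are excluded.
#'
#' @param results_all,results_untreated `moderated_test` results sharing one
#'   feature list.
#' @param alpha Significance threshold (default 0.05).
#' @return A `filter_report` data.frame: `feature_id`, `cluster_id`,
#'   `marker`, `sig_all`, `sig_untreated`, `sign_concordant`, `tested`,
#'   `verdict`.
#' @export
dual_filter <- function(results_all, results_untreated, alpha = 0.05) {
  if (!identical(results_all$feature_id, results_untreated$feature_id)) {
    .data_error("the two result sets must share one feature list")
  }
  tested <- results_all$tested & results_untreated$tested
  sig_all <- tested & results_all$p_adj < alpha
  sig_un <- tested & results_untreated$p_adj < alpha
  conc <- tested & sign(results_all$effect) == sign(results_untreated$effect)
  out <- data.frame(
    feature_id = results_all$feature_id,
    cluster_id = results_all$cluster_id,
    marker = results_all$marker,
    sig_all = sig_all, sig_untreated = sig_un, sign_concordant = conc,
    tested = tested,
    verdict = sig_all & sig_un & conc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("filter_report", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank test with effect size
#'
#' Exact null distribution for up to 25 non-zero untied differences, normal
#' approximation with tie/continuity correction otherwise (zero differences
#' dropped, classic convention). The effect size is the rank correlation
#' |Z| / sqrt(n), with Z from the normal approximation and n the number of
#' pairs.
#'
#' @param affected,unaffected Paired numeric vectors (matched by position).
#' @return List: `statistic` (V), `p.value`, `effect_size`, `n_pairs`,
#'   `n_nonzero`, `degenerate` (all differences zero).
#' @export
paired_signed_rank <- function(affected, unaffected) {
  if (length(affected) != length(unaffected)) .data_error("groups must be paired")
  d <- affected - unaffected
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  n_pairs <- length(d)
  if (!length(nz)) {
    return(list(
      statistic = NA_real_, p.value = 1, effect_size = 0,
      n_pairs = n_pairs, n_nonzero = 0L, degenerate = TRUE
    ))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, exact = exact, correct = TRUE)
  )
  # Z from the normal approximation (tie-corrected), for the effect size
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  n <- length(nz)
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu) / sqrt(sig2)
  list(
    statistic = unname(wt$statistic), p.value = wt$p.value,
    effect_size = abs(z) / sqrt(n_pairs),
    n_pairs = n_pairs, n_nonzero = n, degenerate = FALSE
  )
}

#' Unpaired Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact p for small untied samples, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List: `statistic` (U for group_a), `p.value`.
#' @export
unpaired_rank_test <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) .data_error("both groups must be nonempty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 25 && length(group_b) <= 25 && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Latent-pair logistic likelihood-ratio test per gene
#'
#' For each gene, disease status is regressed on expression with twinship
#' (pair) indicator covariates; the model is compared against the pair-only
#' null with a 1-df likelihood ratio test, and p-values are
#' Bonferroni-corrected over tested genes. Constant genes are not tested;
#' fits are iteration-bounded and flagged when they approach complete
#' separation.
#'
#' @param expression Genes x cells numeric matrix (rownames = genes).
#' @param group Factor/character with two levels, per cell.
#' @param pairs Pair label per cell.
#' @param maxit Maximum IRLS iterations per fit.
#' @return Data.frame: `gene`, `lrt`, `p`, `p_bonf`, `tested`, `flagged`.
#' @export
lr_latent_test <- function(expression, group, pairs, maxit = 25L) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) rownames(expression) <- paste0("g", seq_len(nrow(expression)))
  group <- factor(group)
  if (nlevels(group) != 2L) .data_error("group must have exactly two levels")
  if (length(group) != ncol(expression) || length(pairs) != ncol(expression)) {
    .data_error("one group and pair label per cell is required")
  }
  y <- as.integer(group) - 1L
  X0 <- stats::model.matrix(~ factor(pairs))
  fit0 <- suppressWarnings(
    glm.fit(X0, y, family = binomial(), control = list(maxit = maxit))
  )
  dev0 <- fit0$deviance

  genes <- rownames(expression)
  lrt <- rep(NA_real_, length(genes))
  p <- rep(NA_real_, length(genes))
  flagged <- rep(FALSE, length(genes))
  tested <- rep(FALSE, length(genes))
  for (i in seq_along(genes)) {
    g <- expression[i, ]
    if (length(unique(g)) < 2L) next
    X1 <- cbind(X0, expr = g)
    fit1 <- suppressWarnings(
      glm.fit(X1, y, family = binomial(), control = list(maxit = maxit))
    )
    stat <- max(dev0 - fit1$deviance, 0)
    lrt[i] <- stat
    p[i] <- pchisq(stat, df = 1L, lower.tail = FALSE)
    flagged[i] <- !fit1$converged || abs(fit1$coefficients[["expr"]]) > 15
    tested[i] <- TRUE
  }
  n_tested <- sum(tested)
  p_bonf <- pmin(p * n_tested, 1)
  data.frame(
    gene = genes, lrt = lrt, p = p, p_bonf = p_bonf,
    tested = tested, flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Fraction of cells in expanded T-cell clones
#'
#' A clone is expanded when strictly more than two cells share its
#' clonotype; the statistic is the fraction of clonotype-bearing cells that
#' belong to an expanded clone.
#'
#' @param clonotypes Data.frame with columns `cell_id` and `clonotype_id`
#'   (NA = no clonotype detected).
#' @param expanded_min Strict lower bound on clone size (default 2, i.e.
#'   clones of size > 2 are expanded).
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) for an empty table.
#' @export
#' @examples
#' tab <- data.frame(cell_id = 1:7, clonotype_id = c("a", "a", "a", "a", "a", "b", "c"))
#' clonal_expansion_fraction(tab) # 5/7
clonal_expansion_fraction <- function(clonotypes, expanded_min = 2L) {
  ct <- clonotypes$clonotype_id[!is.na(clonotypes$clonotype_id)]
  if (!length(ct)) {
    warning("no clonotype-bearing cells; expansion fraction undefined")
    return(NA_real_)
  }
  sizes <- table(ct)
  mean(sizes[as.character(ct)] > expanded_min)
}

#' Quality-control filtering of a single-cell count matrix
#'
#' Drops cells with fewer than `min_genes` detected genes, cells with a
#' mitochondrial read fraction strictly above `max_mito`, and cells bearing
#' more than `max_beta` TCR beta chains; then drops genes expressed in fewer
#' than `min_cells_per_gene` retained cells.
#'
#' @param counts Genes x cells nonnegative integer matrix (dense or sparse).
#' @param mito_genes Character vector of mitochondrial gene names.
#' @param clonotypes Optional data.frame with `cell_id` and `n_beta_chains`.
#' @param min_genes,max_mito,max_beta,min_cells_per_gene Thresholds.
#' @return List: `cells` (retained cell names), `genes` (retained gene
#'   names), `counts` (filtered matrix).
#' @export
qc_filter_cells <- function(counts, mito_genes = character(), clonotypes = NULL,
                            min_genes = 500L, max_mito = 0.15, max_beta = 2L,
                            min_cells_per_gene = 3L) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    .data_error("counts must have gene rownames and cell colnames")
  }
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- intersect(mito_genes, rownames(counts))
  mito_frac <- if (length(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, ncol(counts))
  }
  keep <- detected >= min_genes & mito_frac <= max_mito
  if (!is.null(clonotypes)) {
    nb <- setNames(clonotypes$n_beta_chains, clonotypes$cell_id)[colnames(counts)]
    nb[is.na(nb)] <- 0L
    keep <- keep & nb <= max_beta
  }
  sub <- counts[, keep, drop = FALSE]
  gene_keep <- Matrix::rowSums(sub > 0) >= min_cells_per_gene
  list(
    cells = colnames(sub),
    genes = rownames(sub)[gene_keep],
    counts = sub[gene_keep, , drop = FALSE]
  )
}
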