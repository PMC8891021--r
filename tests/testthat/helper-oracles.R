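# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exact two-sided signed-rank p-value by enumeration of all sign patterns.
signed_rank_perm_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  ev <- sum(r) / 2
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}

# Exact two-sided Mann-Whitney p-value by enumeration of group assignments.
rank_sum_perm_p <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(na)])
  idx <- utils::combn(length(x), na)
  w_all <- apply(idx, 2L, function(i) sum(r[i]))
  ev <- na * (length(x) + 1) / 2
  mean(abs(w_all - ev) >= abs(w_obs - ev) - 1e-12)
}

# A feature table + paired design with gaussian medians, one row per
# (sample, cluster), for direct tests of the moderated-test machinery.
make_gaussian_features <- function(n_pairs, n_clusters, markers, sd_feature = 1,
                                   effect = 0, seed = 1) {
  set.seed(seed)
  samples <- as.vector(rbind(
    sprintf("p%02d_a", 1:n_pairs), sprintf("p%02d_u", 1:n_pairs)
  ))
  design <- paired_design(data.frame(
    sample_id = samples,
    pair_id = rep(sprintf("p%02d", 1:n_pairs), each = 2),
    group = rep(c("affected", "unaffected"), n_pairs),
    treated = FALSE
  ))
  ft <- expand.grid(
    sample_id = samples, cluster_id = sprintf("c%03d", 1:n_clusters),
    stringsAsFactors = FALSE
  )
  ft$n_cells <- 100L
  ft$freq <- 1 / n_clusters
  for (m in markers) {
    ft[[m]] <- rnorm(nrow(ft), sd = sd_feature) +
      ifelse(grepl("_a$", ft$sample_id), effect, 0)
  }
  list(features = ft, design = design)
}

# Small toy cohort used by several pipeline-level tests.
toy_cohort_config <- function(n_pairs = 4L, n_cells = 300L, seed = 1L, ...) {
  example_cohort_config(
    n_pairs = n_pairs, n_untreated_pairs = max(2L, n_pairs %/% 2L),
    n_cells_per_sample = n_cells, seed = seed, ...
  )
}
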