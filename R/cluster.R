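#' Consensus metaclustering of SOM codebook vectors
#'
#' For each candidate `k`, the codebook nodes are repeatedly subsampled and
#' cut from an average-linkage Euclidean dendrogram; the consensus matrix is
#' the fraction of co-subsampled runs in which two nodes co-cluster. The
#' number of metaclusters is chosen by the elbow criterion on the area under
#' the consensus CDF: the largest `k` whose relative delta-area is at least
#' `elbow_threshold`. Final labels cut an average-linkage tree on
#' `1 - consensus` at the chosen `k`.
#'
#' @param codebook Nodes x markers matrix (e.g. `som_model$codebook`).
#' @param k_range Candidate metacluster counts, within `[2, n_nodes]`.
#' @param n_subsamples Number of subsampled clusterings (>= 2).
#' @param subsample_fraction Fraction of nodes drawn per subsample.
#' @param elbow_threshold Minimum relative delta-area to accept a larger `k`.
#' @param seed Integer seed.
#' @return A `metacluster_tree`: `labels` (metacluster per node), `chosen_k`,
#'   `k_range`, `consensus` (list of matrices), `auc`, `delta_area`,
#'   `merge_map` (identity until annotated).
#' @export
consensus_metacluster <- function(codebook, k_range = 2:20, n_subsamples = 100L,
                                  subsample_fraction = 0.8,
                                  elbow_threshold = 0.1, seed = 1L) {
  codebook <- as.matrix(codebook)
  n <- nrow(codebook)
  if (!length(k_range)) .config_error("k_range must be nonempty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n) {
    .config_error("k_range must lie within [2, number of nodes]")
  }
  if (n_subsamples < 2L) .config_error("n_subsamples must be >= 2")
  m <- max(2L, ceiling(subsample_fraction * n))

  conn <- array(0, c(n, n, length(k_range)))
  together <- matrix(0, n, n)
  .with_seed(.substream(seed, "consensus"), {
    for (s in seq_len(n_subsamples)) {
      idx <- sort(sample.int(n, m))
      hc <- hclust(dist(codebook[idx, , drop = FALSE]), method = "average")
      together[idx, idx] <- together[idx, idx] + 1
      ks <- k_range[k_range <= m]
      ct <- cutree(hc, k = ks)
      if (is.null(dim(ct))) ct <- matrix(ct, ncol = 1L)
      for (j in seq_along(ks)) {
        lab <- ct[, j]
        co <- outer(lab, lab, "==")
        ki <- match(ks[j], k_range)
        conn[idx, idx, ki] <- conn[idx, idx, ki] + co
      }
    }
  })
  consensus <- lapply(seq_along(k_range), function(ki) {
    cm <- conn[, , ki] / pmax(together, 1)
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(codebook), rownames(codebook))
    cm
  })
  names(consensus) <- as.character(k_range)

  # area under the consensus CDF per k (ConsensusClusterPlus-style)
  auc <- vapply(consensus, function(cm) {
    v <- sort(cm[upper.tri(cm)])
    if (!length(v)) return(0)
    x <- c(0, v, 1)
    cdf <- stats::ecdf(v)
    sum(diff(x) * cdf(x[-length(x)]))
  }, numeric(1))
  delta <- numeric(length(k_range))
  delta[1L] <- auc[1L]
  if (length(k_range) > 1L) {
    for (j in 2L:length(k_range)) {
      delta[j] <- if (auc[j - 1L] > 0) (auc[j] - auc[j - 1L]) / auc[j - 1L] else 0
    }
  }
  keep <- which(delta >= elbow_threshold)
  chosen_k <- if (length(keep)) k_range[max(keep)] else k_range[1L]

  cm <- consensus[[as.character(chosen_k)]]
  hc_final <- hclust(stats::as.dist(1 - cm), method = "average")
  labels <- cutree(hc_final, k = chosen_k)
  names(labels) <- rownames(codebook)

  structure(
    list(
      labels = labels, chosen_k = as.integer(chosen_k), k_range = k_range,
      consensus = consensus, auc = auc, delta_area = delta,
      merge_map = setNames(
        as.character(seq_len(chosen_k)),
        as.character(seq_len(chosen_k))
      ),
      seed = as.integer(seed)
    ),
    class = "metacluster_tree"
  )
}

#' Apply a manual annotation / merge map to metaclusters
#'
#' The manual merging-and-annotation step of reference-framework building is
#' represented as a replayable label map (e.g. read from YAML with
#' [yaml::read_yaml()]): metacluster id -> canonical population name. Two
#' metaclusters mapped to the same name are merged.
#'
#' @param tree A `metacluster_tree`.
#' @param label_map Named character vector or list: metacluster id -> name.
#' @return The tree with updated `merge_map` and `annotated_labels`.
#' @export
annotate_metaclusters <- function(tree, label_map) {
  if (!inherits(tree, "metacluster_tree")) .config_error("tree must be a metacluster_tree")
  label_map <- unlist(label_map)
  unknown <- setdiff(names(label_map), as.character(unique(tree$labels)))
  if (length(unknown)) {
    .config_error(paste0("label map names unknown metaclusters: ", paste(unknown, collapse = ", ")))
  }
  mm <- tree$merge_map
  mm[names(label_map)] <- label_map
  tree$merge_map <- mm
  tree$annotated_labels <- setNames(mm[as.character(tree$labels)], names(tree$labels))
  tree
}

#' @exportS3Method base::print
print.metacluster_tree <- function(x, ...) {
  cat(sprintf(
    "Consensus metaclustering of %d nodes: chosen k = %d (scanned %d..%d)\n",
    length(x$labels), x$chosen_k, min(x$k_range), max(x$k_range)
  ))
  print(table(x$labels))
  invisible(x)
}

#' Per-sample cluster summaries (counts, frequencies, marker medians)
#'
#' Builds the feature substrate of differential-state analysis: for every
#' (sample, cluster) combination, the cell count, the frequency among all of
#' the sample's cells, and the median of each requested marker. Combinations
#' with fewer than `min_cells` cells get missing medians (low-abundance
#' rule); empty combinations are emitted with count 0.
#'
#' @param events Data.frame with a `sample_id` column and marker columns
#'   (values on the normalized scale for downstream testing).
#' @param labels Cluster label per cell (vector, same length as rows of
#'   `events`).
#' @param markers Marker columns to summarize (default: all numeric marker
#'   columns except bookkeeping ones).
#' @param min_cells Minimum cells for a median to be reported; default 10.
#' @return A `data.table` feature table: `sample_id`, `cluster_id`,
#'   `n_cells`, `freq`, one median column per marker.
#' @export
summarize_clusters <- function(events, labels, markers = NULL, min_cells = 10L) {
  if (length(labels) != nrow(events)) .data_error("one label per cell is required")
  if (anyNA(labels)) .data_error("labels must be complete")
  if (is.null(markers)) {
    markers <- setdiff(colnames(events), c("cell_id", "sample_id", "batch"))
  }
  .assert_markers(events, markers)
  dt <- data.table::as.data.table(events[, c("sample_id", markers), drop = FALSE])
  dt[, cluster_id := as.character(labels)]
  # grouped medians in a GForce-optimizable form, counts separately
  agg <- dt[, lapply(.SD, median), by = .(sample_id, cluster_id), .SDcols = markers]
  cnt <- dt[, list(n_cells = .N), by = .(sample_id, cluster_id)]
  agg <- cnt[agg, on = c("sample_id", "cluster_id")]
  # complete grid: emit empty combinations with count 0
  grid <- data.table::CJ(
    sample_id = unique(dt$sample_id),
    cluster_id = unique(dt$cluster_id)
  )
  agg <- agg[grid, on = c("sample_id", "cluster_id")]
  agg[is.na(n_cells), n_cells := 0L]
  agg[, freq := n_cells / sum(n_cells), by = sample_id]
  for (m in markers) {
    data.table::set(agg, i = which(agg$n_cells < min_cells), j = m, value = NA_real_)
  }
  data.table::setcolorder(agg, c("sample_id", "cluster_id", "n_cells", "freq", markers))
  data.table::setorder(agg, sample_id, cluster_id)
  agg[]
}
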