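#' Harmonize query node profiles onto a reference panel
#'
#' Query node medians on a raw or count scale (e.g. CITE-seq ADT counts, an
#' external surface-proteome table) are arcsinh-transformed and
#' percentile-normalized, then restricted to the markers shared with the
#' reference and ordered identically. By default cofactors are data-adaptive
#' (each marker's q-th percentile divided by 20), which makes the
#' harmonization exactly invariant to a multiplicative rescaling of the
#' query — the property that lets count-scale and ion-count-scale data meet
#' on one `[0, 1]` scale. Fixed cofactors can be supplied instead.
#'
#' @param query Nodes x markers numeric matrix of raw medians (rownames =
#'   node ids).
#' @param reference Nodes x markers matrix of reference profiles on the
#'   normalized `[0, 1]` scale.
#' @param cofactors `"adaptive"` (default), a single number, or a named
#'   vector per marker.
#' @param q Percentile for normalization (and adaptive cofactors).
#' @param transform Set `FALSE` when the query is already on the normalized
#'   scale (values are then only restricted/ordered).
#' @param min_shared Minimum number of shared markers (default 3).
#' @return Matrix of harmonized query profiles over the shared markers, in
#'   reference order; attribute `"shared_markers"`.
#' @export
harmonize_profiles <- function(query, reference, cofactors = "adaptive",
                               q = 99.9, transform = TRUE, min_shared = 3L) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  shared <- intersect(colnames(reference), colnames(query))
  if (!length(shared)) .data_error("query and reference marker sets are disjoint")
  if (length(shared) < min_shared) {
    .data_error(sprintf(
      "only %d shared marker(s); at least %d required", length(shared), min_shared
    ))
  }
  x <- query[, shared, drop = FALSE]
  if (transform) {
    if (identical(cofactors, "adaptive")) {
      cf <- apply(x, 2L, .pctl, q = q) / 20
      cf[cf <= 0] <- 1
    } else if (length(cofactors) == 1L) {
      cf <- setNames(rep(as.numeric(cofactors), length(shared)), shared)
    } else {
      cf <- cofactors[shared]
      if (anyNA(cf)) .config_error("cofactors must cover all shared markers")
    }
    y <- arcsinh_transform(x, setNames(as.numeric(cf), shared))
    x <- percentile_normalize(y, q = q)
  }
  out <- x[, shared, drop = FALSE]
  attr(out, "shared_markers") <- shared
  out
}

#' Build a reference/query node similarity graph with a seeded layout
#'
#' Edge weights are cosine similarities over the shared markers (clipped to
#' `[0, 1]`); each query node keeps its `top_k` strongest edges with weight
#' at least `min_similarity`. Coordinates come from seeded
#' Fruchterman-Reingold iterations (layout is presentation only — the
#' query-to-reference assignment depends solely on edge weights). All-zero
#' profiles have undefined similarity and are flagged unmapped.
#'
#' @param reference Reference profiles (nodes x markers, normalized scale).
#' @param query Query profiles over the same (shared) markers, e.g. from
#'   [harmonize_profiles()].
#' @param frequency Optional named node-frequency vector (reference and/or
#'   query ids) used as a node-size attribute and for assignment
#'   tie-breaking.
#' @param top_k Maximum edges kept per query node.
#' @param min_similarity Minimum retained edge weight.
#' @param fr_iter Fruchterman-Reingold iterations.
#' @param seed Integer layout seed.
#' @return A `node_graph`: `nodes` (data.frame id, role, frequency, x, y),
#'   `edges` (data.frame query, reference, weight), parameters.
#' @export
build_node_graph <- function(reference, query, frequency = NULL, top_k = 3L,
                             min_similarity = 0.5, fr_iter = 500L, seed = 1L) {
  reference <- as.matrix(reference)
  query <- as.matrix(query)
  shared <- intersect(colnames(reference), colnames(query))
  if (length(shared) < 1L) .data_error("no shared markers between reference and query")
  R <- reference[, shared, drop = FALSE]
  Q <- query[, shared, drop = FALSE]
  if (is.null(rownames(R))) rownames(R) <- paste0("ref", seq_len(nrow(R)))
  if (is.null(rownames(Q))) rownames(Q) <- paste0("query", seq_len(nrow(Q)))

  rn <- sqrt(rowSums(R^2))
  qn <- sqrt(rowSums(Q^2))
  zero_q <- qn == 0
  sim <- (Q %*% t(R)) / (pmax(qn, 1e-300) %o% pmax(rn, 1e-300))
  sim[zero_q, ] <- NA_real_
  sim[, rn == 0] <- NA_real_
  sim <- pmin(pmax(sim, 0), 1)

  edges <- do.call(rbind, lapply(seq_len(nrow(Q)), function(i) {
    w <- sim[i, ]
    ok <- which(!is.na(w) & w >= min_similarity)
    if (!length(ok)) return(NULL)
    ok <- ok[order(w[ok], decreasing = TRUE)]
    ok <- ok[seq_len(min(top_k, length(ok)))]
    data.frame(
      query = rownames(Q)[i], reference = rownames(R)[ok],
      weight = unname(w[ok]), stringsAsFactors = FALSE
    )
  }))
  if (is.null(edges)) {
    edges <- data.frame(
      query = character(), reference = character(), weight = numeric(),
      stringsAsFactors = FALSE
    )
  }

  ids <- c(rownames(R), rownames(Q))
  nodes <- data.frame(
    id = ids,
    role = c(rep("reference", nrow(R)), rep("query", nrow(Q))),
    frequency = if (is.null(frequency)) NA_real_ else unname(frequency[ids]),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("query", "reference", "weight")],
    directed = FALSE,
    vertices = nodes$id
  )
  coords <- .with_seed(.substream(seed, "layout"), {
    if (igraph::ecount(g) > 0) {
      igraph::layout_with_fr(
        g,
        niter = fr_iter,
        weights = igraph::E(g)$weight
      )
    } else {
      matrix(0, nrow(nodes), 2)
    }
  })
  nodes$x <- coords[match(nodes$id, igraph::V(g)$name), 1L]
  nodes$y <- coords[match(nodes$id, igraph::V(g)$name), 2L]

  structure(
    list(
      nodes = nodes, edges = edges, similarity = sim,
      unmapped_queries = rownames(Q)[zero_q],
      top_k = as.integer(top_k), min_similarity = min_similarity,
      seed = as.integer(seed)
    ),
    class = "node_graph"
  )
}

#' Assign query nodes to reference nodes
#'
#' Each query node is assigned the reference node of its maximum-weight
#' surviving edge; ties are broken by larger reference frequency, then
#' lexicographic reference id. Queries with no surviving edge are unmapped
#' (`NA`).
#'
#' @param graph A `node_graph` from [build_node_graph()].
#' @return Data.frame (`query`, `reference` or `NA`, `weight`).
#' @export
assign_to_reference <- function(graph) {
  if (!inherits(graph, "node_graph")) .data_error("graph must be a node_graph")
  queries <- graph$nodes$id[graph$nodes$role == "query"]
  freq <- setNames(graph$nodes$frequency, graph$nodes$id)
  out <- data.frame(
    query = queries, reference = NA_character_, weight = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(queries)) {
    e <- graph$edges[graph$edges$query == queries[i], , drop = FALSE]
    if (!nrow(e)) next
    f <- freq[e$reference]
    f[is.na(f)] <- -Inf
    ord <- order(-e$weight, -f, e$reference)
    out$reference[i] <- e$reference[ord[1L]]
    out$weight[i] <- e$weight[ord[1L]]
  }
  out
}

#' @exportS3Method base::print
print.node_graph <- function(x, ...) {
  cat(sprintf(
    "Node graph: %d reference + %d query nodes, %d edges (top_k = %d, min similarity = %.2f)\n",
    sum(x$nodes$role == "reference"), sum(x$nodes$role == "query"),
    nrow(x$edges), x$top_k, x$min_similarity
  ))
  invisible(x)
}
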