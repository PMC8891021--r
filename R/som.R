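#' Train a self-organizing map on cell-type markers
#'
#' Online SOM training: cells are presented in a seeded random order over
#' `epochs` passes; the best-matching unit (Euclidean) and its Gaussian grid
#' neighborhood are pulled toward each presented cell with a linearly
#' decaying learning rate and neighborhood radius. A 10x10 grid yields the
#' 100-node reference granularity used for differential-state feature
#' enumeration. Clustering must use cell-type (lineage) markers only; pass a
#' panel to enforce this.
#'
#' @param x Normalized matrix (cells x markers); only `type_markers` columns
#'   are used.
#' @param type_markers Character vector of markers to cluster on; defaults to
#'   all columns of `x`.
#' @param grid `c(rows, cols)` of the SOM grid.
#' @param epochs Training passes over the data.
#' @param alpha Learning rate, decaying linearly `alpha[1] -> alpha[2]`.
#' @param radius Start radius in grid units (default `max(grid)/2`), decaying
#'   linearly to 1.
#' @param panel Optional panel data.frame (`marker`, `class` in
#'   `{"type","state"}`); passing any state marker is a configuration error.
#' @param seed Integer seed (initialization and presentation order).
#' @return A `som_model`: `codebook` (nodes x markers), `grid`, `mapping`
#'   (best-matching node per training cell), `qe` (mean quantization error
#'   per epoch), hyperparameters and seed.
#' @export
train_som <- function(x, type_markers = colnames(x), grid = c(10L, 10L),
                      epochs = 10L, alpha = c(0.05, 0.01), radius = NULL,
                      panel = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) .data_error("x must have marker column names")
  .assert_markers(x, type_markers)
  if (!is.null(panel)) {
    cls <- setNames(panel$class, panel$marker)[type_markers]
    if (any(is.na(cls))) .config_error("panel does not cover all clustering markers")
    if (any(cls != "type")) {
      .config_error(paste0(
        "state markers passed to train_som: ",
        paste(type_markers[cls != "type"], collapse = ", ")
      ))
    }
  }
  if (length(grid) != 2L || any(grid < 1)) .config_error("grid must be c(rows, cols) >= 1")
  if (!length(type_markers)) .config_error("at least one type marker is required")
  X <- x[, type_markers, drop = FALSE]
  if (anyNA(X)) .data_error("clustering input must be complete")
  n <- nrow(X)
  nnodes <- as.integer(grid[1L] * grid[2L])
  if (is.null(radius)) radius <- max(grid) / 2

  res <- .with_seed(.substream(seed, "som"), {
    init_idx <- sample.int(n, nnodes, replace = n < nnodes)
    codes0 <- X[init_idx, , drop = FALSE]
    ord <- as.integer(unlist(lapply(seq_len(epochs), function(e) sample.int(n) - 1L)))
    som_train_cpp(
      X, codes0,
      xdim = as.integer(grid[2L]), ydim = as.integer(grid[1L]),
      order = ord, n_epochs = as.integer(epochs),
      alpha0 = alpha[1L], alpha1 = alpha[2L],
      radius0 = radius, radius1 = 1
    )
  })
  colnames(res$codebook) <- type_markers
  rownames(res$codebook) <- sprintf("node%03d", seq_len(nnodes))
  structure(
    list(
      codebook = res$codebook, grid = as.integer(grid),
      mapping = as.integer(res$bmu), qe = as.numeric(res$qe),
      type_markers = type_markers, epochs = as.integer(epochs),
      alpha = alpha, radius = c(radius, 1), seed = as.integer(seed)
    ),
    class = "som_model"
  )
}

#' Map cells to their best-matching SOM node
#'
#' @param object A `som_model`.
#' @param newdata Matrix/data.frame containing the model's type markers.
#' @param ... Unused.
#' @return Integer vector of node indices (1-based).
#' @export
predict.som_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  .assert_markers(newdata, object$type_markers)
  as.integer(som_map_cpp(
    newdata[, object$type_markers, drop = FALSE],
    object$codebook
  ))
}

#' @exportS3Method base::print
print.som_model <- function(x, ...) {
  cat(sprintf(
    "Self-organizing map: %d x %d grid (%d nodes), %d markers, %d epochs\n",
    x$grid[1L], x$grid[2L], nrow(x$codebook), ncol(x$codebook), x$epochs
  ))
  cat(sprintf(
    "  final mean quantization error: %.4f\n", x$qe[length(x$qe)]
  ))
  invisible(x)
}
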