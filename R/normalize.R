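#' Inverse hyperbolic sine transform with per-marker cofactors
#'
#' `y = asinh(x / cofactor)`, the variance-stabilizing transform standard for
#' cytometry ion counts. Monotone per marker; `asinh(0) = 0`.
#'
#' @param x Nonnegative numeric matrix (cells x markers) or data.frame with
#'   marker columns.
#' @param cofactors Named positive vector (one entry per marker) or a single
#'   value recycled over markers. Default 5.
#' @return Numeric matrix of transformed values, same shape and order.
#' @export
#' @examples
#' arcsinh_transform(matrix(5, 1, 1, dimnames = list(NULL, "CD25")), 5) # asinh(1)
arcsinh_transform <- function(x, cofactors = 5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (length(cofactors) == 1L && is.null(names(cofactors))) {
    cofactors <- setNames(rep(as.numeric(cofactors), ncol(x)), colnames(x))
  }
  miss <- setdiff(colnames(x), names(cofactors))
  if (length(miss)) {
    .config_error(paste0("no cofactor for marker(s): ", paste(miss, collapse = ", ")))
  }
  cf <- cofactors[colnames(x)]
  if (any(cf <= 0)) .config_error("cofactors must be positive")
  if (anyNA(x) || any(x < 0)) .data_error("intensities must be nonnegative and complete")
  asinh(sweep(x, 2L, cf, "/"))
}

#' Align batches by solving per-marker cofactors on shared controls
#'
#' The reference batch (first element) keeps the base cofactors. For every
#' other batch and marker, the cofactor `c` solving
#' `mean(asinh(x_batch / c)) = mean(asinh(x_ref / c_ref))` over control cells
#' is found by monotone 1-D root search (bisection on `log c`, bracket
#' `[c_base/100, c_base*100]`, relative tolerance `tol`). For a purely
#' multiplicative batch effect `x_batch = f * x_ref` the solution is exactly
#' `f * c_base`. A zero target mean returns the base cofactor.
#'
#' @param control_events_by_batch Named list (one element per batch) of
#'   control-cell matrices/data.frames sharing marker columns.
#' @param base_cofactors Named positive vector or single value.
#' @param tol Relative root tolerance.
#' @return Data.frame (`marker`, `batch`, `cofactor`) covering every
#'   (marker, batch) combination, plus attribute `"base_batch"`.
#' @export
align_batches <- function(control_events_by_batch, base_cofactors = 5, tol = 1e-8) {
  if (length(control_events_by_batch) < 2L) {
    .config_error("at least two batches of control events are required")
  }
  if (is.null(names(control_events_by_batch))) {
    names(control_events_by_batch) <- as.character(seq_along(control_events_by_batch))
  }
  mats <- lapply(control_events_by_batch, function(x) {
    x <- as.matrix(x)
    if (anyNA(x) || any(x < 0)) .data_error("control intensities must be nonnegative")
    x
  })
  markers <- colnames(mats[[1L]])
  for (m in mats) {
    if (!setequal(colnames(m), markers)) .data_error("batches must share marker columns")
  }
  if (length(base_cofactors) == 1L && is.null(names(base_cofactors))) {
    base_cofactors <- setNames(rep(as.numeric(base_cofactors), length(markers)), markers)
  }
  miss <- setdiff(markers, names(base_cofactors))
  if (length(miss)) .config_error(paste0("no base cofactor for: ", paste(miss, collapse = ", ")))

  batches <- names(mats)
  ref <- batches[1L]
  out <- expand.grid(
    marker = markers, batch = batches,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  out$cofactor <- NA_real_
  for (m in markers) {
    c_base <- base_cofactors[[m]]
    target <- mean(asinh(mats[[ref]][, m] / c_base))
    out$cofactor[out$marker == m & out$batch == ref] <- c_base
    for (b in batches[-1L]) {
      x <- mats[[b]][, m]
      cf <- if (target == 0) {
        c_base
      } else {
        f <- function(lc) mean(asinh(x / exp(lc))) - target
        lo <- log(c_base / 100)
        hi <- log(c_base * 100)
        if (f(lo) * f(hi) > 0) {
          .numeric_error(paste0(
            "batch alignment: no cofactor bracket for marker '", m,
            "' in batch '", b, "'"
          ))
        }
        exp(uniroot(f, c(lo, hi), tol = tol)$root)
      }
      out$cofactor[out$marker == m & out$batch == b] <- cf
    }
  }
  attr(out, "base_batch") <- ref
  out
}

# apply batch-specific cofactors to an event table with a batch column
.arcsinh_by_batch <- function(x, batch, cofactor_table) {
  x <- as.matrix(x)
  y <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (b in unique(batch)) {
    rows <- batch == b
    cf <- cofactor_table$cofactor[cofactor_table$batch == as.character(b)]
    names(cf) <- cofactor_table$marker[cofactor_table$batch == as.character(b)]
    y[rows, ] <- arcsinh_transform(x[rows, , drop = FALSE], cf)
  }
  y
}

#' Marker-wise percentile normalization
#'
#' Each marker is divided by its own q-th percentile over all cells (type-7,
#' linear interpolation) and clipped to `[0, 1]`. A constant-zero marker maps
#' to all zeros.
#'
#' @param y Transformed matrix (cells x markers).
#' @param q Percentile in `(0, 100)`; default 99.9.
#' @return Matrix of values in `[0, 1]` with attribute `"norm_percentiles"`
#'   (the divisors applied).
#' @export
percentile_normalize <- function(y, q = 99.9) {
  y <- as.matrix(y)
  if (!nrow(y)) .data_error("matrix must be nonempty")
  if (q <= 0 || q >= 100) .config_error("q must lie in (0, 100)")
  div <- apply(y, 2L, .pctl, q = q)
  zero <- div <= 0
  div[zero] <- 1
  out <- sweep(y, 2L, div, "/")
  out[out > 1] <- 1
  out[out < 0] <- 0
  out[, zero] <- 0
  attr(out, "norm_percentiles") <- div
  attr(out, "q") <- q
  out
}

#' Call cytokine positivity against an unstimulated control
#'
#' The positivity threshold for each cytokine is the q-th percentile of its
#' transformed unstimulated intensities (residual signal); a stimulated cell
#' is positive when its transformed intensity strictly exceeds that
#' threshold.
#'
#' @param stimulated,unstimulated Event tables (data.frames) containing the
#'   cytokine columns.
#' @param cytokines Character vector of cytokine channels.
#' @param q Threshold percentile; default 99.
#' @param cofactors Cofactors for the arcsinh transform (single value or
#'   named vector).
#' @return List: `positive` (logical cells x cytokines matrix for the
#'   stimulated table), `thresholds` (named vector, transformed scale).
#' @export
call_cytokine_positive <- function(stimulated, unstimulated, cytokines, q = 99,
                                   cofactors = 5) {
  if (!nrow(unstimulated)) .data_error("unstimulated table is empty")
  .assert_markers(stimulated, cytokines)
  .assert_markers(unstimulated, cytokines)
  y_un <- arcsinh_transform(unstimulated[, cytokines, drop = FALSE], cofactors)
  y_st <- arcsinh_transform(stimulated[, cytokines, drop = FALSE], cofactors)
  thr <- apply(y_un, 2L, .pctl, q = q)
  positive <- sweep(y_st, 2L, thr, ">")
  list(positive = positive, thresholds = setNames(thr, cytokines))
}
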