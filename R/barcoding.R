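#' Enumerate combinatorial barcode codes
#'
#' All k-subsets of `n_channels` barcode channels in lexicographic order;
#' the default 9-choose-3 scheme yields 84 codes. Channels are 1-based.
#'
#' @param n_channels Number of barcode channels.
#' @param k Channels per code.
#' @return Integer matrix with `choose(n_channels, k)` rows and `k` columns.
#' @export
#' @examples
#' nrow(enumerate_codes(9, 3)) # 84
enumerate_codes <- function(n_channels = 9L, k = 3L) {
  if (!.is_count(n_channels) || !.is_count(k) || k < 1) {
    .config_error("n_channels and k must be positive counts")
  }
  if (k > n_channels) .config_error("k must not exceed n_channels")
  codes <- t(combn(seq_len(n_channels), k))
  colnames(codes) <- paste0("ch", seq_len(k))
  codes
}

#' Build a barcode scheme for a set of samples
#'
#' Codes are assigned to samples deterministically in manifest order.
#'
#' @param sample_ids Character vector of sample ids (unique).
#' @param n_channels,k Scheme geometry (defaults 9-choose-3).
#' @return A `barcode_scheme` list with `codes`, `sample_to_code` (row index
#'   into `codes` per sample), `n_channels`, `k`.
#' @export
barcode_scheme <- function(sample_ids, n_channels = 9L, k = 3L) {
  if (anyDuplicated(sample_ids)) .config_error("sample ids must be unique")
  codes <- enumerate_codes(n_channels, k)
  if (length(sample_ids) > nrow(codes)) {
    .config_error(sprintf(
      "%d samples exceed the %d available codes", length(sample_ids), nrow(codes)
    ))
  }
  structure(
    list(
      n_channels = as.integer(n_channels), k = as.integer(k), codes = codes,
      sample_to_code = setNames(seq_along(sample_ids), sample_ids)
    ),
    class = "barcode_scheme"
  )
}

#' Simulate barcode-channel intensities for labelled cells
#'
#' Test/benchmark helper: each cell receives high signal on the channels of
#' its sample's code and background elsewhere; an optional fraction of
#' doublets carries the union of two random codes.
#'
#' @param sample_of_cell Character vector giving each cell's true sample.
#' @param scheme A [barcode_scheme()].
#' @param signal,background Lognormal medians of positive/negative channels.
#' @param sdlog Log-scale noise SD.
#' @param doublet_rate Fraction of cells replaced by two-code doublets.
#' @param seed Integer seed.
#' @return List with `intensities` (cells x channels matrix) and `truth`
#'   (data.frame: true sample, doublet flag).
#' @export
simulate_barcode_channels <- function(sample_of_cell, scheme, signal = 100,
                                      background = 1, sdlog = 0.1,
                                      doublet_rate = 0, seed = 1L) {
  if (!inherits(scheme, "barcode_scheme")) .config_error("scheme must be a barcode_scheme")
  unknown <- setdiff(unique(sample_of_cell), names(scheme$sample_to_code))
  if (length(unknown)) {
    .config_error(paste0("samples without a code: ", paste(unknown, collapse = ", ")))
  }
  n <- length(sample_of_cell)
  .with_seed(.substream(seed, "barcode"), {
    X <- matrix(
      exp(rnorm(n * scheme$n_channels, log(background), sdlog)),
      n, scheme$n_channels,
      dimnames = list(NULL, paste0("bc", seq_len(scheme$n_channels)))
    )
    is_doublet <- runif(n) < doublet_rate
    for (i in seq_len(n)) {
      chans <- scheme$codes[scheme$sample_to_code[[sample_of_cell[i]]], ]
      if (is_doublet[i]) {
        other <- sample.int(nrow(scheme$codes), 1L)
        chans <- union(chans, scheme$codes[other, ])
      }
      X[i, chans] <- exp(rnorm(length(chans), log(signal), sdlog))
    }
    list(
      intensities = X,
      truth = data.frame(
        sample_id = sample_of_cell, doublet = is_doublet,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Boolean debarcoding with doublet exclusion
#'
#' Channels are rescaled by their own high percentile, then called positive
#' above `positive_threshold`. A cell is assigned to sample `s` when exactly
#' the `k` channels of `s`'s code are positive and the k-th highest rescaled
#' signal exceeds the (k+1)-th by at least `margin`; cells with more than `k`
#' positive channels are doublets; every other pattern is unassigned.
#'
#' @param intensities Cells x barcode-channels numeric matrix (raw scale).
#' @param scheme A [barcode_scheme()].
#' @param margin Minimum rescaled-signal gap between the k-th and (k+1)-th
#'   channel for an assignment.
#' @param positive_threshold Rescaled intensity above which a channel is
#'   called positive.
#' @param rescale_q Percentile used for per-channel rescaling.
#' @return A `debarcode_result` list: `assignments` (data.frame `cell`,
#'   `call` in `{sample id, "DOUBLET", "UNASSIGNED"}`), `thresholds`
#'   (per-channel rescaling divisors), `margin`.
#' @export
debarcode <- function(intensities, scheme, margin = 0.1,
                      positive_threshold = 0.5, rescale_q = 99.9) {
  if (!inherits(scheme, "barcode_scheme")) .config_error("scheme must be a barcode_scheme")
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != scheme$n_channels) {
    .data_error("intensity matrix must have one column per barcode channel")
  }
  if (anyNA(intensities)) .data_error("barcode intensities must be complete")
  n <- nrow(intensities)
  k <- scheme$k

  div <- apply(intensities, 2L, .pctl, q = rescale_q)
  div[div <= 0] <- 1 # all-background channel: leave unscaled
  R <- sweep(intensities, 2L, div, "/")

  pos <- R > positive_threshold
  npos <- rowSums(pos)

  # gap between the k-th and (k+1)-th highest rescaled signals
  gap <- apply(R, 1L, function(z) {
    s <- sort(z, decreasing = TRUE)
    s[k] - s[k + 1L]
  })

  # map exact-k positivity patterns to codes assigned to samples
  code_key <- apply(scheme$codes, 1L, paste, collapse = "-")
  assigned_codes <- scheme$sample_to_code
  key_to_sample <- setNames(names(assigned_codes), code_key[assigned_codes])

  call <- rep("UNASSIGNED", n)
  call[npos > k] <- "DOUBLET"
  exact <- which(npos == k & gap >= margin)
  if (length(exact)) {
    keys <- vapply(
      exact,
      function(i) paste(which(pos[i, ]), collapse = "-"),
      character(1)
    )
    hit <- key_to_sample[keys]
    call[exact[!is.na(hit)]] <- hit[!is.na(hit)]
  }
  structure(
    list(
      assignments = data.frame(
        cell = if (is.null(rownames(intensities))) seq_len(n) else rownames(intensities),
        call = call, stringsAsFactors = FALSE
      ),
      thresholds = setNames(div, colnames(intensities)),
      margin = margin,
      positive_threshold = positive_threshold
    ),
    class = "debarcode_result"
  )
}

#' @exportS3Method base::print
print.debarcode_result <- function(x, ...) {
  tab <- table(ifelse(
    x$assignments$call %in% c("DOUBLET", "UNASSIGNED"),
    x$assignments$call, "assigned"
  ))
  cat("Debarcoding of", nrow(x$assignments), "cells\n")
  print(tab)
  invisible(x)
}
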