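#' Coerce twin-pair trait data to zygosity form
#'
#' @param data Either a data.frame with columns `zygosity` (`"MZ"`/`"DZ"`),
#'   `y1`, `y2` (as produced by [generate_twin_traits()]) or a list with
#'   two-column matrices `mz` and `dz`.
#' @return List with numeric matrices `mz` and `dz` (pairs x 2).
#' @export
zygosity_data <- function(data) {
  if (is.data.frame(data)) {
    need <- c("zygosity", "y1", "y2")
    miss <- setdiff(need, colnames(data))
    if (length(miss)) .data_error(paste0("missing columns: ", paste(miss, collapse = ", ")))
    out <- list(
      mz = as.matrix(data[data$zygosity == "MZ", c("y1", "y2")]),
      dz = as.matrix(data[data$zygosity == "DZ", c("y1", "y2")])
    )
  } else if (is.list(data) && all(c("mz", "dz") %in% names(data))) {
    out <- list(mz = as.matrix(data$mz), dz = as.matrix(data$dz))
  } else {
    .data_error("data must be a trait data.frame or a list with mz/dz matrices")
  }
  if (anyNA(out$mz) || anyNA(out$dz) ||
    any(!is.finite(out$mz)) || any(!is.finite(out$dz))) {
    .data_error("trait values must be finite")
  }
  out
}

# Sum of bivariate-normal log densities with common mean, common variance v
# and covariance cv.
.bvn_loglik <- function(Y, mu, v, cv) {
  if (!nrow(Y)) return(0)
  det_s <- v^2 - cv^2
  if (det_s <= 0 || v <= 0) return(-Inf)
  z1 <- Y[, 1] - mu
  z2 <- Y[, 2] - mu
  q <- (v * z1^2 - 2 * cv * z1 * z2 + v * z2^2) / det_s
  sum(-log(2 * pi) - 0.5 * log(det_s) - 0.5 * q)
}

#' ACE model log-likelihood
#'
#' Two-group bivariate-normal likelihood with common mean, total variance
#' `a^2 + c^2 + e^2`, within-pair covariance `a^2 + c^2` for MZ pairs and
#' `a^2/2 + c^2` for DZ pairs. A non-positive-definite implied covariance
#' returns `-Inf`.
#'
#' @param params Named vector or list with `a`, `c`, `e`, `mean` (path
#'   coefficients; variances are their squares).
#' @param data Twin data accepted by [zygosity_data()].
#' @return Log-likelihood (scalar).
#' @export
ace_loglik <- function(params, data) {
  data <- zygosity_data(data)
  a <- params[["a"]]
  cc <- params[["c"]]
  e <- params[["e"]]
  mu <- params[["mean"]]
  v <- a^2 + cc^2 + e^2
  .bvn_loglik(data$mz, mu, v, a^2 + cc^2) +
    .bvn_loglik(data$dz, mu, v, 0.5 * a^2 + cc^2)
}

#' Maximum-likelihood ACE twin variance decomposition
#'
#' Fits the classical twin variance-components model (and its AE, CE, E
#' submodels) by maximum likelihood over MZ and DZ pairs, with path
#' coefficients constrained nonnegative (their sign is unidentified) and a
#' single common mean. Optimization uses bounded quasi-Newton iterations
#' from multiple seeded starts; standardized shares are the squared paths
#' over the implied total variance.
#'
#' @param data Twin data accepted by [zygosity_data()].
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param n_starts Number of optimization starts (first is moment-based).
#' @param seed Integer seed for the random restarts.
#' @return An `ace_fit`: `estimates` (a, c, e, mean), `shares` (A, C, E,
#'   summing to 1), `loglik`, `model`, `n_pairs`, `convergence`.
#' @export
fit_ace <- function(data, model = c("ACE", "AE", "CE", "E"), n_starts = 5L,
                    seed = 1L) {
  model <- match.arg(model)
  data <- zygosity_data(data)
  if (model == "ACE" && (nrow(data$mz) < 3L || nrow(data$dz) < 3L)) {
    .data_error("a full ACE fit needs at least 3 pairs per zygosity group")
  }
  y <- c(data$mz, data$dz)
  sd_y <- sd(y)
  mu0 <- mean(y)
  r_mz <- if (nrow(data$mz) > 2L) cor(data$mz[, 1], data$mz[, 2]) else 0
  r_dz <- if (nrow(data$dz) > 2L) cor(data$dz[, 1], data$dz[, 2]) else 0
  fal <- falconer_shares(r_mz, r_dz)$clipped

  free <- switch(model,
    ACE = c("a", "c", "e"),
    AE = c("a", "e"),
    CE = c("c", "e"),
    E = "e"
  )
  build <- function(theta) {
    p <- c(a = 0, c = 0, e = 0)
    p[free] <- theta[seq_along(free)]
    c(as.list(p), mean = theta[length(theta)])
  }
  negll <- function(theta) {
    ll <- ace_loglik(build(theta), data)
    if (!is.finite(ll)) 1e10 else -ll
  }

  start0 <- c(
    sqrt(pmax(fal[c("A", "C", "E")], 0.02)) * sd_y,
    0
  )[c(match(free, c("a", "c", "e")), 4L)]
  start0[length(start0)] <- mu0
  starts <- list(start0)
  extra <- .with_seed(.substream(seed, "ace_starts"), {
    lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
      th <- c(runif(length(free), 0.1, 1) * sd_y, mu0 + rnorm(1, 0, 0.1 * max(sd_y, 1e-6)))
      th
    })
  })
  starts <- c(starts, extra)

  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      nlminb(
        start = th, objective = negll,
        lower = c(rep(0, length(free)), -Inf),
        upper = rep(Inf, length(free) + 1L),
        control = list(iter.max = 500L, rel.tol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || !is.finite(best$objective)) {
    .numeric_error("ACE fit did not converge from any start")
  }
  p <- build(best$par)
  paths <- c(a = p$a, c = p$c, e = p$e)
  v <- sum(paths^2)
  shares <- setNames(paths^2 / v, c("A", "C", "E"))
  structure(
    list(
      estimates = c(paths, mean = p$mean),
      shares = shares,
      loglik = -best$objective,
      model = model,
      n_pairs = c(mz = nrow(data$mz), dz = nrow(data$dz)),
      convergence = list(code = best$convergence, message = best$message,
                         iterations = best$iterations)
    ),
    class = "ace_fit"
  )
}

#' @exportS3Method base::print
print.ace_fit <- function(x, ...) {
  cat(sprintf(
    "%s twin model (ML), %d MZ / %d DZ pairs, logLik = %.2f\n",
    x$model, x$n_pairs[["mz"]], x$n_pairs[["dz"]], x$loglik
  ))
  cat(sprintf(
    "  standardized shares: A = %.1f%%, C = %.1f%%, E = %.1f%%\n",
    100 * x$shares[["A"]], 100 * x$shares[["C"]], 100 * x$shares[["E"]]
  ))
  invisible(x)
}

#' @exportS3Method base::summary
summary.ace_fit <- function(object, ...) {
  cat("Path coefficients:\n")
  print(round(object$estimates, 4))
  cat("Standardized variance shares:\n")
  print(round(object$shares, 4))
  cat(sprintf("logLik: %.4f (%s model)\n", object$loglik, object$model))
  invisible(object)
}

#' @export
coef.ace_fit <- function(object, ...) object$estimates

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(object$loglik,
    df = switch(object$model, ACE = 4L, AE = 3L, CE = 3L, E = 2L),
    class = "logLik"
  )
}

#' Falconer closed-form variance shares
#'
#' The classical oracle for the ML fit: `A = 2 (r_MZ - r_DZ)`,
#' `C = 2 r_DZ - r_MZ`, `E = 1 - r_MZ`.
#'
#' @param r_mz,r_dz Twin correlations in `[-1, 1]`.
#' @return List with `raw` (unclipped, sums to 1) and `clipped` (components
#'   clipped to `[0, 1]` and renormalized).
#' @export
#' @examples
#' falconer_shares(0.93, 0.68)$raw # A = 0.50, C = 0.43, E = 0.07
falconer_shares <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) .data_error("correlations must lie in [-1, 1]")
  raw <- c(A = 2 * (r_mz - r_dz), C = 2 * r_dz - r_mz, E = 1 - r_mz)
  cl <- pmin(pmax(raw, 0), 1)
  if (sum(cl) > 0) cl <- cl / sum(cl)
  list(raw = raw, clipped = cl)
}

#' Variance decomposition across multiple traits
#'
#' Fits the ACE model to every trait and reports per-trait standardized
#' shares plus their unweighted means (the "mean variance components across
#' all immune subsets" summary). Per-trait failures are reported and do not
#' abort the remaining traits.
#'
#' @param traits Named list of twin datasets (each accepted by
#'   [zygosity_data()]).
#' @param ... Passed to [fit_ace()].
#' @return List: `per_trait` (data.frame trait, A, C, E, loglik, error),
#'   `mean_shares` (named vector over successful fits).
#' @export
variance_report <- function(traits, ...) {
  if (is.null(names(traits))) names(traits) <- paste0("trait", seq_along(traits))
  rows <- lapply(names(traits), function(nm) {
    fit <- tryCatch(fit_ace(traits[[nm]], ...), error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(
        trait = nm, A = NA_real_, C = NA_real_, E = NA_real_,
        loglik = NA_real_, error = conditionMessage(fit),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        trait = nm, A = fit$shares[["A"]], C = fit$shares[["C"]],
        E = fit$shares[["E"]], loglik = fit$loglik, error = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  })
  per_trait <- do.call(rbind, rows)
  ok <- is.na(per_trait$error)
  mean_shares <- c(
    A = mean(per_trait$A[ok]), C = mean(per_trait$C[ok]), E = mean(per_trait$E[ok])
  )
  list(per_trait = per_trait, mean_shares = mean_shares)
}
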