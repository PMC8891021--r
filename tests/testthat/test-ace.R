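test_that("ACE log-likelihood has the stated closed forms and invariances", {
  set.seed(1)
  dat <- list(
    mz = matrix(rnorm(40), 20, 2),
    dz = matrix(rnorm(30), 15, 2)
  )
  # a = c = 0: pairs independent, likelihood is a product of univariate normals
  ll <- ace_loglik(list(a = 0, c = 0, e = 1.3, mean = 0.2), dat)
  ll_uni <- sum(stats::dnorm(c(dat$mz, dat$dz), 0.2, 1.3, log = TRUE))
  expect_equal(ll, ll_uni, tolerance = 1e-10)

  # scaling parameters and data by k shifts the log-likelihood by the exact
  # Jacobian term only
  p <- list(a = 0.7, c = 0.4, e = 0.9, mean = 0.1)
  p2 <- list(a = 1.4, c = 0.8, e = 1.8, mean = 0.2)
  dat2 <- list(mz = dat$mz * 2, dz = dat$dz * 2)
  n_pairs <- nrow(dat$mz) + nrow(dat$dz)
  expect_equal(
    ace_loglik(p2, dat2),
    ace_loglik(p, dat) - n_pairs * 2 * log(2),
    tolerance = 1e-10
  )

  # non-positive-definite implied covariance is rejected
  expect_equal(ace_loglik(list(a = 0, c = 0, e = 0, mean = 0), dat), -Inf)
})

test_that("the likelihood peaks near the simulated truth", {
  hits <- vapply(1:40, function(s) {
    tt <- generate_twin_traits(twin_trait_config(800, 800, 0.5, 0.3, 0.2, seed = s))
    truth <- list(a = sqrt(0.5), c = sqrt(0.3), e = sqrt(0.2), mean = 0)
    pert <- list(a = sqrt(0.5) * 1.3, c = sqrt(0.3) * 0.7, e = sqrt(0.2), mean = 0)
    ace_loglik(truth, tt) >= ace_loglik(pert, tt)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Falconer shares follow the closed forms", {
  f <- falconer_shares(0.93, 0.68)
  expect_equal(unname(f$raw), c(0.50, 0.43, 0.07), tolerance = 1e-12)
  r <- 0.4
  f2 <- falconer_shares(r, r)
  expect_equal(unname(f2$raw), c(0, r, 1 - r))
  f3 <- falconer_shares(1, 0.5)
  expect_equal(unname(f3$raw), c(1, 0, 0))
  expect_error(falconer_shares(1.2, 0), "-1, 1")
})

test_that("ML fit recovers interior truths and boundary nulls", {
  # interior truth with standardized shares (0.5, 0.3, 0.2)
  tt <- generate_twin_traits(twin_trait_config(5000, 5000, 0.5, 0.3, 0.2, seed = 21))
  fit <- fit_ace(tt)
  expect_equal(unname(fit$shares), c(0.5, 0.3, 0.2), tolerance = 0.03 / 0.2)
  expect_equal(sum(fit$shares), 1, tolerance = 1e-8)
  expect_true(all(fit$shares >= 0))

  # null A and C recovered at the boundary
  tt0 <- generate_twin_traits(twin_trait_config(5000, 5000, 0, 0, 1, seed = 22))
  fit0 <- fit_ace(tt0)
  expect_lt(fit0$shares[["A"]], 0.05)
  expect_lt(fit0$shares[["C"]], 0.05)

  # interior estimates agree with the Falconer closed form at n = 10,000
  tt10 <- generate_twin_traits(twin_trait_config(10000, 10000, 0.4, 0.35, 0.25, seed = 23))
  fit10 <- fit_ace(tt10)
  mz <- tt10[tt10$zygosity == "MZ", ]
  dz <- tt10[tt10$zygosity == "DZ", ]
  fal <- falconer_shares(cor(mz$y1, mz$y2), cor(dz$y1, dz$y2))$raw
  expect_equal(unname(fit10$shares), unname(fal), tolerance = 0.02 / 0.25)

  expect_error(
    fit_ace(list(mz = matrix(rnorm(4), 2, 2), dz = matrix(rnorm(20), 10, 2))),
    "3 pairs"
  )
})

test_that("nested submodels never beat the full model and scaling is equivariant", {
  tt <- generate_twin_traits(twin_trait_config(400, 400, 0.5, 0.2, 0.3, seed = 31))
  f_ace <- fit_ace(tt, "ACE")
  f_ae <- fit_ace(tt, "AE")
  f_ce <- fit_ace(tt, "CE")
  f_e <- fit_ace(tt, "E")
  expect_gte(f_ace$loglik, f_ae$loglik - 1e-6)
  expect_gte(f_ae$loglik, f_e$loglik - 1e-6)
  expect_gte(f_ace$loglik, f_ce$loglik - 1e-6)
  expect_equal(attr(logLik(f_ace), "df"), 4L)

  tt_k <- tt
  tt_k$y1 <- tt$y1 * 3
  tt_k$y2 <- tt$y2 * 3
  f_k <- fit_ace(tt_k, "ACE")
  expect_equal(unname(f_k$estimates[c("a", "c", "e")]),
    unname(3 * f_ace$estimates[c("a", "c", "e")]),
    tolerance = 1e-3
  )
  expect_equal(f_k$shares, f_ace$shares, tolerance = 1e-4)
})

test_that("variance reports aggregate per-trait shares and survive failures", {
  tt <- generate_twin_traits(twin_trait_config(2000, 2000, 0.5, 0.1, 0.4, seed = 41))
  single <- variance_report(list(cd25 = tt))
  expect_equal(single$mean_shares[["A"]], single$per_trait$A[1])

  traits <- lapply(1:6, function(s) {
    generate_twin_traits(twin_trait_config(1500, 1500, 0.5, 0.1, 0.4, seed = 50 + s))
  })
  rep6 <- variance_report(traits)
  expect_equal(unname(rep6$mean_shares), c(0.5, 0.1, 0.4), tolerance = 0.05 / 0.1)

  # a failing trait is reported, the others continue
  bad <- list(mz = matrix(rnorm(4), 2, 2), dz = matrix(rnorm(4), 2, 2))
  mixed <- variance_report(list(good = tt, bad = bad))
  expect_true(is.na(mixed$per_trait$A[2]))
  expect_false(is.na(mixed$per_trait$error[2]))
  expect_equal(mixed$mean_shares[["A"]], mixed$per_trait$A[1])
})
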