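test_that("centred batch dummies deliver the global-mean intercept contract", {
  rec <- quick_records(seed = 2, n_lines = 6, n_batches = 4, n_flies = 4)
  g <- hemivar:::.group_data(rec, "lifespan", TRUE)
  des <- build_design(g, weights = g$n)
  # every centred dummy column sums to zero under the design weights
  dummy_cols <- grep("batch", colnames(des$X))
  for (j in dummy_cols) {
    expect_lt(abs(sum(des$X[, j] * g$n)), 1e-8)
  }
  # balanced zero-noise data: GLS intercept equals the grand mean per sex
  be <- rbind(F = c(-2, 1, 0.5, 0.5), M = c(1, -1, 0, 0))
  p0 <- genetic_params(grand_mean = c(F = 60, M = 50), G = diag(c(0, 0)),
                       V_V = c(F = 0, M = 0), V_R = c(F = 0, M = 0),
                       batch_effects = be)
  rec0 <- simulate_lifespans(small_design(n_lines = 5, n_batches = 4,
                                          n_flies = 3), p0, seed = 1)
  g0 <- hemivar:::.group_data(rec0, "lifespan", TRUE)
  d0 <- build_design(g0, weights = g0$n)
  fit <- lm.fit(d0$X * sqrt(g0$n), g0$ybar * sqrt(g0$n))
  expect_equal(unname(fit$coefficients["trait_F"]), 60, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["trait_M"]), 50, tolerance = 1e-8)

  # single batch: dummies dropped with a warning
  rec1 <- quick_records(seed = 3, n_batches = 1)
  g1 <- hemivar:::.group_data(rec1, "lifespan", TRUE)
  expect_warning(build_design(g1), "single batch")

  # batches nested in sex leave an all-zero column: rejected by name
  bad <- data.frame(sex = rep(c("F", "M"), each = 4),
                    batch = rep(c(1, 2), each = 4))
  expect_error(build_design(bad), "rank deficient.*batch")
})

test_that("with plain priors and pinned effects the sampler matches the conjugate posterior", {
  # observed line effects (residual noise ~ 0, fixed effects pinned at
  # zero): the line covariance posterior is inverse-Wishart in closed form
  L <- 40
  G0 <- matrix(c(4, 1.5, 1.5, 3), 2, 2)
  u <- simulate_line_effects(L, G0, seed = 2)
  dat <- rbind(
    data.frame(line_id = u$line_id, sex = "F", batch = rep(1:2, each = L),
               value = rep(u$effect_F, 2) + rnorm(2 * L, 0, 0.005)),
    data.frame(line_id = u$line_id, sex = "M", batch = rep(1:2, each = L),
               value = rep(u$effect_M, 2) + rnorm(2 * L, 0, 0.005))
  )
  nu <- 4
  ch <- run_gibbs(dat, "aging",
                  prior = prior_spec(nu_random = nu, px = FALSE,
                                     beta_prior_var = 1e-12),
                  config = chain_config(20000, 2000, 10, seed = 3))
  U <- cbind(u$effect_F, u$effect_M)
  post <- (nu * diag(2) + crossprod(U)) / (nu + L - 3)  # IW posterior mean
  est <- colMeans(ch$samples[, c("V_L_F", "Cov_MF", "V_L_M")])
  mcse <- apply(ch$samples[, c("V_L_F", "Cov_MF", "V_L_M")], 2, sd) /
    sqrt(nrow(ch$samples) / 2)   # conservative ESS guess
  expect_lt(abs(est[["V_L_F"]] - post[1, 1]), 3 * mcse[["V_L_F"]])
  expect_lt(abs(est[["Cov_MF"]] - post[1, 2]), 3 * mcse[["Cov_MF"]])
  expect_lt(abs(est[["V_L_M"]] - post[2, 2]), 3 * mcse[["V_L_M"]])
})

test_that("posterior chains keep their structural invariants", {
  rec <- quick_records(seed = 4, n_lines = 15, n_batches = 4, n_flies = 10)
  ch <- run_gibbs(rec, "lifespan", config = quick_chain_config(seed = 5))
  S <- ch$samples
  expect_equal(nrow(S), (6000 - 1000) / 5)
  # every retained line G sample positive semidefinite
  expect_true(all(S[, "V_L_F"] >= 0 & S[, "V_L_M"] >= 0))
  expect_true(all(S[, "V_L_F"] * S[, "V_L_M"] - S[, "Cov_MF"]^2 >= -1e-10))
  # r_MF within [-1, 1] for every PSD sample
  r <- rmf(S[, "Cov_MF"], S[, "V_L_F"], S[, "V_L_M"])
  expect_true(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  # V_P identity per sample, exact arithmetic
  ds <- derive_stats(ch)
  expect_identical(ds$samples$VP_F,
                   ds$samples$V_L_F + ds$samples$V_V_F + ds$samples$V_R_F)
  # reproducibility under identical seed, and under record permutation
  ch2 <- run_gibbs(rec, "lifespan", config = quick_chain_config(seed = 5))
  expect_identical(ch$samples, ch2$samples)
  perm <- sample(nrow(rec))
  ch3 <- run_gibbs(rec[perm, ], "lifespan",
                   config = quick_chain_config(seed = 5))
  expect_identical(ch$samples, ch3$samples)
})

test_that("one observation per vial makes the vial term non-identifiable", {
  rec <- quick_records(seed = 6, n_lines = 6, n_flies = 1)
  expect_error(run_gibbs(rec, "lifespan"), "not identifiable")
  # mixed chromosome types must be fitted separately
  cfg <- small_design(n_lines = 4, n_flies = 5, types = c("autosome", "X"))
  rec2 <- simulate_lifespans(cfg, list(
    autosome = fly_lifespan_params("autosome", 2),
    X = fly_lifespan_params("X", 2)), seed = 1)
  expect_error(run_gibbs(rec2, "lifespan"), "more than one chromosome type")
})

test_that("the aging response reuses the lifespan machinery without the vial term", {
  # vial-level aging rates: same sampler, vial flag flipped off
  L <- 25
  u <- simulate_line_effects(L, matrix(c(6, 2, 2, 3), 2, 2), seed = 14)
  set.seed(16)
  grid <- expand.grid(line = seq_len(L), sex = c("F", "M"), batch = 1:4)
  dat <- data.frame(
    line_id = sprintf("L%02d", grid$line), sex = grid$sex,
    batch = grid$batch,
    beta_x100 = ifelse(grid$sex == "F", 17.3, 12.4) +
      ifelse(grid$sex == "F", u$effect_F[grid$line],
             u$effect_M[grid$line]) +
      rnorm(nrow(grid), 0, sqrt(ifelse(grid$sex == "F", 25, 7)))
  )
  ch <- run_gibbs(dat, "aging", config = quick_chain_config(seed = 18))
  expect_false(ch$include_vial)
  expect_false(any(grepl("V_V", colnames(ch$samples))))
  # components are recovered within the 95% credible intervals
  ci <- apply(ch$samples[, c("V_L_F", "V_L_M", "V_R_F", "V_R_M")], 2,
              quantile, c(0.025, 0.975))
  truth <- c(V_L_F = 6, V_L_M = 3, V_R_F = 25, V_R_M = 7)
  for (p in names(truth)) {
    expect_true(truth[p] >= ci[1, p] && truth[p] <= ci[2, p],
                label = paste("CI covers", p))
  }
})

test_that("line-variance posteriors are robust to the prior belief parameter", {
  rec <- quick_records(seed = 10, n_lines = 30, n_batches = 4, n_flies = 15)
  means <- sds <- numeric(3)
  for (i in seq_along(c(0.002, 2, 3))) {
    nu <- c(0.002, 2, 3)[i]
    ch <- run_gibbs(rec, "lifespan", prior = prior_spec(nu_random = nu),
                    config = quick_chain_config(seed = 11))
    means[i] <- mean(ch$samples[, "V_L_F"])
    sds[i] <- sd(ch$samples[, "V_L_F"])
  }
  # posterior means differ by less than one posterior SD across nu choices
  expect_lt(max(means) - min(means), min(sds))
})

test_that("Gelman-Rubin separates converged from divergent chains", {
  set.seed(12)
  null_chains <- list(matrix(rnorm(2000), 1000, 2,
                             dimnames = list(NULL, c("a", "b"))),
                      matrix(rnorm(2000), 1000, 2,
                             dimnames = list(NULL, c("a", "b"))))
  gr <- gelman_rubin(null_chains)
  expect_true(all(gr$psrf < 1.05))
  expect_true(all(!gr$flagged))

  div <- list(matrix(rnorm(1000, 0), 1000, 1, dimnames = list(NULL, "a")),
              matrix(rnorm(1000, 10), 1000, 1, dimnames = list(NULL, "a")))
  gr2 <- gelman_rubin(div)
  expect_gt(gr2$psrf, 5)
  expect_true(all(gr2$flagged))

  # duplicated chain: degenerate, warn, PSRF about 1
  ch <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "a"))
  expect_warning(gr3 <- gelman_rubin(list(ch, ch)), "identical chain means")
  expect_lt(abs(gr3$psrf - 1), 0.01)

  expect_error(gelman_rubin(list(ch)), "at least two")
  expect_error(gelman_rubin(list(ch, ch[1:100, , drop = FALSE])),
               "equal retained length")
})
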