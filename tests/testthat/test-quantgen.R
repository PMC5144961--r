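test_that("conversion rules reproduce the published arithmetic", {
  ref <- reference_estimates()
  pick <- function(trait, q, ty, s) {
    ref$estimate[ref$trait == trait & ref$quantity == q &
                   ref$chromosome_type == ty & ref$sex == s]
  }
  # hemiclone doubling rule against the published V_A entries
  expect_equal(additive_variance(pick("lifespan", "V_L", "autosome", "F"),
                                 "autosome", "F"), 30.00)
  expect_equal(additive_variance(pick("aging", "V_L", "autosome", "F"),
                                 "autosome", "F"), 13.94)
  # hemizygous male X: V_A = V_L unchanged
  expect_equal(additive_variance(pick("lifespan", "V_L", "X", "M"),
                                 "X", "M"), 8.95)
  expect_equal(additive_variance(0, "X", "F"), 0)
  expect_error(additive_variance(1, "Y", "M"))
  expect_error(additive_variance(-1, "X", "M"), "V_L")

  # phenotypic variance sums match the published V_P entries
  expect_equal(phenotypic_variance(17.36, 4.82, 89.92), 112.10)
  expect_equal(phenotypic_variance(2.28, 5.96, 60.95), 69.19)
  expect_equal(phenotypic_variance(6.97, NULL, 25.86), 32.83)
  expect_equal(phenotypic_variance(0, 0, 0), 0)

  # plug-in evolvability coefficients round to the published two decimals
  expect_equal(round(cv_a(30.00, 64.75), 2), 0.08)
  expect_equal(round(cv_a(8.95, 51.36), 2), 0.06)
  expect_equal(cv_a(0, 10), 0)
  expect_error(cv_a(4, 0), "mean")
})

test_that("r_MF handles degenerate denominators per sample", {
  expect_equal(as.numeric(rmf(0, 4, 9)), 0)
  expect_equal(as.numeric(rmf(6, 4, 9)), 1)
  r <- rmf(c(1, 1), c(2, 0), c(2, 2))
  expect_true(is.na(r[2]))
  expect_equal(attr(r, "n_dropped"), 1L)
  expect_error(rmf(c(1), c(0), c(1)), "every sample")
})

test_that("posterior summaries are location-correct and skew-robust", {
  s <- posterior_summary(rep(3.5, 100))
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, 0)
  expect_equal(s$ci, c(3.5, 3.5))

  # lognormal median recovered within 3 MC SE of the analytic median
  set.seed(51)
  x <- rlnorm(2000)
  mc_se <- 1 / (2 * stats::dlnorm(1) * sqrt(2000))
  expect_lt(abs(posterior_summary(x)$median - 1), 3 * mc_se)

  # adversarial ratio samples: a handful of near-zero denominators inflate
  # the mean while the median stays put
  set.seed(52)
  den <- c(abs(rnorm(1990, 1, 0.1)), rep(1e-7, 10))
  ratio <- 1 / den
  sk <- posterior_summary(ratio, skewed = TRUE)
  expect_true(is.finite(sk$median))
  expect_gt(sk$mean, 100 * sk$median)
  expect_lt(abs(sk$median - 1), 0.05)
  expect_true(sk$skewed)

  expect_error(posterior_summary(numeric(0)), "at least 2")
})

test_that("chain differences give calibrated posterior contrasts", {
  # constant chains difference to exactly zero
  d0 <- chain_difference(rep(2, 100), rep(2, 100), seed = 1)
  expect_true(all(d0$differences == 0))

  set.seed(53)
  a <- rnorm(2000, 1); b <- rnorm(2000, 0)
  d <- chain_difference(a, b, seed = 2)
  expect_lt(abs(d$summary$mean - 1), 3 * sqrt(2 / 2000))

  # same distribution: fraction >= 0 near one half
  d2 <- chain_difference(rnorm(2000), rnorm(2000), seed = 3)
  expect_lt(abs(d2$frac_ge0 - 0.5), 3 * sqrt(0.25 / 2000))

  # unequal lengths resampled and flagged
  d3 <- chain_difference(rnorm(500), rnorm(2000), seed = 4)
  expect_true(d3$resampled)
  expect_length(d3$differences, 2000)
})

test_that("X-linkage proportions recover the generative share", {
  # constants
  expect_equal(x_linkage_proportion(rep(2, 10), rep(2, 10))$summary$mean, 50)
  expect_equal(x_linkage_proportion(rep(0, 10), rep(2, 10))$summary$mean, 0)
  # near-noise-free posterior-style samples around a 15.6% generative share
  set.seed(54)
  vx <- 15.6 * rchisq(4000, 2000) / 2000
  va <- 84.4 * rchisq(4000, 2000) / 2000
  xl <- x_linkage_proportion(vx, va)
  mc_se <- sd(xl$samples) / sqrt(4000)
  expect_lt(abs(xl$summary$mean - 15.6), 3 * mc_se + 0.05)
  expect_true(all(xl$samples >= 0 & xl$samples <= 100))
  expect_equal(xl$reference, c(euchromatin = 18.8, genes = 15.6))
  # zero denominators dropped and counted
  xl2 <- x_linkage_proportion(c(0, 1, 1), c(0, 1, 3))
  expect_equal(xl2$n_dropped, 1L)
  expect_true(is.na(xl2$samples[1]))
  # a single finite sample yields no summary rather than an error
  expect_null(x_linkage_proportion(c(0, 1), c(0, 1))$summary)
})

test_that("ratio statistics express the dosage-compensation expectation", {
  const <- data.frame(VA_F = rep(4, 50), VA_M = rep(4, 50),
                      CVA_F = rep(0.1, 50), CVA_M = rep(0.1, 50))
  rs0 <- ratio_stats(const, const)
  expect_true(all(rs0$ratio_of_ratios$samples == 1))

  # twofold male X variance, equal means, equal autosomal variances:
  # the ratio-of-ratios median sits at sqrt(2). Posterior-style samples
  # built as scaled chi-squares with line-level degrees of freedom.
  set.seed(55)
  df <- 39; n <- 2000
  mk <- function(v) v * rchisq(n, df) / df
  sx <- data.frame(VA_F = mk(10), VA_M = mk(20))
  sa <- data.frame(VA_F = mk(10), VA_M = mk(10))
  sx$CVA_F <- sqrt(sx$VA_F) / 60; sx$CVA_M <- sqrt(sx$VA_M) / 60
  sa$CVA_F <- sqrt(sa$VA_F) / 60; sa$CVA_M <- sqrt(sa$VA_M) / 60
  rs <- ratio_stats(sx, sa)
  expect_lt(abs(rs$ratio_of_ratios$summary$median - sqrt(2)), 0.06)
  expect_true(rs$ratio_of_ratios$summary$skewed)

  # near-zero female variance samples: mean far above median, warning on
  # heavy dropping
  sx2 <- sx
  sx2$VA_F <- pmax(sx$VA_F - quantile(sx$VA_F, 0.3), 0)
  sx2$CVA_F <- sqrt(sx2$VA_F) / 60
  expect_warning(rs2 <- ratio_stats(sx2, sa), "dropped")
  expect_gt(rs2$va_ratio_x$summary$mean, rs2$va_ratio_x$summary$median)
})

test_that("derived statistics are computed per sample, never from summaries", {
  rec <- quick_records(seed = 56, n_lines = 10, n_flies = 8)
  ch <- run_gibbs(rec, "lifespan", config = quick_chain_config(seed = 57))
  ds <- derive_stats(ch)
  # per-sample identity against direct recomputation from the raw chain
  expect_equal(ds$samples$VA_F, 2 * ch$samples[, "V_L_F"], ignore_attr = TRUE)
  expect_equal(ds$samples$CVA_M,
               sqrt(2 * ch$samples[, "V_L_M"]) / ch$samples[, "trait_M"],
               ignore_attr = TRUE)
  expect_equal(ds$summary$VA_F$mean, mean(ds$samples$VA_F))
  # the posterior mean of a ratio is not the ratio of posterior means
  expect_false(isTRUE(all.equal(ds$summary$CVA_F$mean,
                                sqrt(ds$summary$VA_F$mean) /
                                  ds$summary$mean_F$mean)))

  # X-type chain applies the hemizygous male rule
  cfgx <- small_design(n_lines = 10, n_flies = 8, types = "X")
  recx <- simulate_lifespans(cfgx, fly_lifespan_params("X", 2), seed = 58)
  chx <- run_gibbs(recx, "lifespan", config = quick_chain_config(seed = 59))
  dsx <- derive_stats(chx)
  expect_equal(dsx$samples$VA_M, chx$samples[, "V_L_M"], ignore_attr = TRUE)
  expect_equal(dsx$samples$VA_F, 2 * chx$samples[, "V_L_F"],
               ignore_attr = TRUE)

  # cross-type contrasts assemble without dropping samples on healthy chains
  ct <- cross_type_stats(dsx, ds, seed = 60)
  expect_true(all(ct$x_linkage_F$samples >= 0 & ct$x_linkage_F$samples <= 100))
  expect_length(ct$rmf_difference$differences, nrow(ds$samples))
  # scale invariance of the ratio-of-ratios: rescaling all lifespans by a
  # constant multiplies means and sqrt-variances alike
  ds_scaled <- ds
  ds_scaled$samples <- transform(ds$samples,
                                 VA_F = VA_F * 4, VA_M = VA_M * 4,
                                 mean_F = mean_F * 2, mean_M = mean_M * 2)
  dsx_scaled <- dsx
  dsx_scaled$samples <- transform(dsx$samples,
                                  VA_F = VA_F * 4, VA_M = VA_M * 4,
                                  mean_F = mean_F * 2, mean_M = mean_M * 2)
  ds_scaled$samples$CVA_F <- with(ds_scaled$samples, sqrt(VA_F) / mean_F)
  ds_scaled$samples$CVA_M <- with(ds_scaled$samples, sqrt(VA_M) / mean_M)
  dsx_scaled$samples$CVA_F <- with(dsx_scaled$samples, sqrt(VA_F) / mean_F)
  dsx_scaled$samples$CVA_M <- with(dsx_scaled$samples, sqrt(VA_M) / mean_M)
  ct2 <- cross_type_stats(dsx_scaled, ds_scaled, seed = 60)
  expect_equal(ct2$ratios$ratio_of_ratios$summary$median,
               ct$ratios$ratio_of_ratios$summary$median, tolerance = 1e-10)
})
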