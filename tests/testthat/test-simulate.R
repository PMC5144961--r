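test_that("line effects reproduce the generative covariance, including degenerate G", {
  # zero-variance: all effects exactly zero
  eff0 <- simulate_line_effects(20, diag(c(0, 0)), seed = 1)
  expect_true(all(eff0$effect_F == 0) && all(eff0$effect_M == 0))

  # perfect correlation: male effect an exact linear function of the female
  VF <- 15.00; VM <- 17.36
  G1 <- matrix(c(VF, sqrt(VF * VM), sqrt(VF * VM), VM), 2, 2)
  eff1 <- simulate_line_effects(500, G1, seed = 2)
  expect_equal(eff1$effect_M, eff1$effect_F * sqrt(VM / VF), tolerance = 1e-6)

  # law of large numbers: sample covariance within 3 Monte-Carlo SE of G
  n <- 1e5
  r <- 0.50
  G <- matrix(c(VF, r * sqrt(VF * VM), r * sqrt(VF * VM), VM), 2, 2)
  eff <- simulate_line_effects(n, G, seed = 3)
  S <- cov(cbind(eff$effect_F, eff$effect_M))
  for (i in 1:2) for (j in 1:2) {
    mc_se <- sqrt((G[i, i] * G[j, j] + G[i, j]^2) / n)
    expect_lt(abs(S[i, j] - G[i, j]), 3 * mc_se)
  }

  # non-PSD G rejected with the offending eigenvalue named
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_line_effects(10, bad, seed = 1),
               "positive semidefinite.*-1")

  # reproducible given seed
  expect_identical(simulate_line_effects(50, G, seed = 9),
                   simulate_line_effects(50, G, seed = 9))
})

test_that("lifespan simulator recovers generative moments and keeps the design books", {
  # zero-variance: lifespan is exactly grand mean + batch effect
  be <- rbind(F = c(-2, 2), M = c(1, -1))
  p0 <- genetic_params(grand_mean = c(F = 60, M = 50), G = diag(c(0, 0)),
                       V_V = c(F = 0, M = 0), V_R = c(F = 0, M = 0),
                       batch_effects = be)
  cfg0 <- small_design(n_lines = 4, n_batches = 2, n_flies = 5)
  rec0 <- simulate_lifespans(cfg0, p0, seed = 1)
  expected <- ifelse(rec0$sex == "F", 60, 50) +
    be[cbind(match(rec0$sex, c("F", "M")), rec0$batch)]
  expect_equal(rec0$lifespan, unname(expected))

  # full design: record count and vial bookkeeping
  cfg <- design_config()
  params <- list(autosome = fly_lifespan_params("autosome"),
                 X = fly_lifespan_params("X"))
  rec <- simulate_lifespans(cfg, params, seed = 5)
  expect_equal(nrow(rec), 40 * 2 * 2 * 4 * 50)
  vs <- vial_summaries(rec)
  expect_equal(nrow(vs), 40 * 2 * 2 * 4)
  # no vial spans two lines or sexes
  expect_equal(nrow(unique(rec[, c("vial_id", "line_id", "sex")])), nrow(vs))

  # moment recovery at generative female-autosome parameters:
  # grand mean within 3 SE; line-variance of line means, corrected for the
  # within-line sampling term, within 3 MC SE of V_L
  fem <- rec[rec$sex == "F" & rec$chromosome_type == "autosome", ]
  V_L <- 15.00; V_V <- 4.78; V_R <- 73.72
  se_mean <- sqrt((V_L + (V_V + V_R / 50) / 4) / 40)
  expect_lt(abs(mean(fem$lifespan) - 64.75), 3 * se_mean)
  line_means <- tapply(fem$lifespan, fem$line_id, mean)
  vhat <- var(line_means) - (V_V + V_R / 50) / 4
  tot <- V_L + (V_V + V_R / 50) / 4
  mc_se <- tot * sqrt(2 / 39)
  expect_lt(abs(vhat - V_L), 3 * mc_se)

  # reproducibility: identical seed and config give identical tables
  expect_identical(simulate_lifespans(cfg0, p0, seed = 3),
                   simulate_lifespans(cfg0, p0, seed = 3))

  # truncation floor: strong downward shift produces floored lifespans
  plow <- genetic_params(grand_mean = c(F = 2, M = 2), G = diag(c(0, 0)),
                         V_V = c(F = 0, M = 0), V_R = c(F = 25, M = 25))
  rlow <- simulate_lifespans(cfg0, plow, seed = 2)
  expect_true(all(rlow$lifespan >= 1))
  expect_gt(attr(rlow, "n_truncated"), 0)
})

test_that("Gompertz cohort sampler matches analytic quantiles and survival", {
  # exponential limit: beta = 0, alpha = 0.1/day -> mean death age ~ 10 d
  s0 <- simulate_gompertz_cohort(0.1, 0, 1e4, census_interval = 0.5,
                                 max_age = 200, seed = 1)
  mids <- (s0$boundaries[-1] + s0$boundaries[-length(s0$boundaries)]) / 2
  emp_mean <- sum(mids * s0$deaths) / sum(s0$deaths)
  expect_lt(abs(emp_mean - 10), 3 * 10 / sqrt(1e4) + 0.25)  # + binning width

  # analytic median of the Gompertz distribution
  alpha <- 2.8e-6; beta <- 0.17; n <- 1e5
  set.seed(2)
  t <- rgompertz(n, alpha, beta)
  med_true <- log(1 - (beta / alpha) * log(0.5)) / beta
  f_med <- alpha * exp(beta * med_true) *
    gompertz_survival(alpha, beta, med_true)
  mc_se <- 1 / (2 * f_med * sqrt(n))
  expect_lt(abs(median(t) - med_true), 3 * mc_se)

  # empirical survival within the Dvoretzky-Kiefer-Wolfowitz band
  grid <- seq(0, 120, by = 1)
  S_emp <- vapply(grid, function(g) mean(t > g), 0)
  S_true <- gompertz_survival(alpha, beta, grid)
  eps_dkw <- sqrt(log(2 / 0.001) / (2 * n))
  expect_lt(max(abs(S_emp - S_true)), eps_dkw)

  # degenerate cohort: assay ends before the first census
  s1 <- simulate_gompertz_cohort(0.1, 0, 1, census_interval = 2,
                                 max_age = 1, seed = 3)
  expect_length(s1$deaths, 0)
  expect_equal(s1$censored, 1L)

  # schedule bookkeeping: deaths + censored = cohort size
  s2 <- simulate_gompertz_cohort(0.01, -0.05, 500, max_age = 80, seed = 4)
  expect_equal(sum(s2$deaths) + s2$censored, 500L)
  expect_gt(s2$censored, 0)  # negative beta leaves a survival plateau
})

test_that("outlier injection hits the requested vials and nothing else", {
  rec <- quick_records(seed = 7, n_lines = 10, n_flies = 20)

  out0 <- inject_outlier_vials(rec, fraction = 0, seed = 1)
  expect_identical(out0$records, rec)
  expect_length(out0$affected_vials, 0)

  out1 <- inject_outlier_vials(rec, fraction = 1, shift = 25, seed = 1)
  fem_vials <- unique(rec$vial_id[rec$sex == "F"])
  expect_setequal(out1$affected_vials, fem_vials)
  expect_identical(out1$records$lifespan[out1$records$sex == "M"],
                   rec$lifespan[rec$sex == "M"])

  out <- inject_outlier_vials(rec, fraction = 0.2, shift = 25, seed = 2)
  hit <- rec$vial_id %in% out$affected_vials
  expect_equal(out$records$lifespan[hit],
               pmax(rec$lifespan[hit] - 25, 1))
  expect_identical(out$records$lifespan[!hit], rec$lifespan[!hit])

  # shifted vials fall below the 51-day screen at assay-scale parameters
  vs <- vial_summaries(out$records)
  shifted <- vs[vs$vial_id %in% out$affected_vials, ]
  expect_true(all(shifted$mean_lifespan < 51))
})

test_that("lifespan and schedule CSV round trips preserve the data", {
  rec <- quick_records(seed = 3, n_lines = 4, n_flies = 6)
  f1 <- tempfile(fileext = ".csv")
  write_lifespans(rec, f1)
  back <- read_lifespans(f1)
  expect_equal(back$lifespan, rec$lifespan)
  expect_equal(back$vial_id, rec$vial_id)

  sch <- list(
    simulate_gompertz_cohort(5e-5, 0.12, 50, seed = 1, vial_id = "v1"),
    simulate_gompertz_cohort(1e-4, 0.10, 50, max_age = 60, seed = 2,
                             vial_id = "v2")
  )
  f2 <- tempfile(fileext = ".csv")
  write_schedules(sch, f2)
  back2 <- read_schedules(f2)
  for (v in c("v1", "v2")) {
    orig <- sch[[which(vapply(sch, `[[`, "", "vial_id") == v)]]
    keep <- orig$deaths  # writer stores every interval
    expect_equal(back2[[v]]$deaths, keep)
    expect_equal(back2[[v]]$censored, orig$censored)
    expect_equal(back2[[v]]$boundaries, orig$boundaries)
  }

  # binning records reproduces per-vial death counts
  sch3 <- records_to_schedules(rec, census_interval = 2)
  expect_length(sch3, length(unique(rec$vial_id)))
  tot <- sum(vapply(sch3, function(s) sum(s$deaths), 0))
  expect_equal(tot, nrow(rec))
})

test_that("master seed splitting is deterministic and non-colliding", {
  s1 <- split_seed(42, 10)
  s2 <- split_seed(42, 10)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 10)
  expect_false(identical(split_seed(43, 10), s1))
})
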