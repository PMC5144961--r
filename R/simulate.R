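#' Derive deterministic child seeds from one master seed
#'
#' All stochastic stages of the package draw their seeds from a single master
#' seed through this splitter: the master seed seeds R's RNG once and `n`
#' integer child seeds are drawn without replacement from `1:(2^31 - 2)`.
#' The same master seed therefore always yields the same child seeds, and
#' stages remain decoupled (changing the number of draws in one stage does
#' not perturb another stage's stream as long as the split itself is fixed).
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master), n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

#' Simulate cross-sex line effects
#'
#' Draws one pair of additive line effects (female, male) per substitution
#' line from a bivariate normal with mean zero and cross-sex covariance
#' matrix `G`. This is the generative counterpart of estimating the line
#' (co)variance matrix: the sample covariance of the returned effects
#' converges to `G` as the number of lines grows.
#'
#' @param n_lines Number of lines.
#' @param G 2x2 symmetric positive semidefinite covariance matrix
#'   (F first, M second).
#' @param seed Integer seed.
#' @return A data.frame with columns `line_id`, `effect_F`, `effect_M`.
#' @export
simulate_line_effects <- function(n_lines, G, seed) {
  G <- as.matrix(G)
  stopifnot(identical(dim(G), c(2L, 2L)))
  .check_psd(G, "G")
  set.seed(seed)
  Z <- matrix(rnorm(2 * n_lines), n_lines, 2)
  # eigen square root: tolerates semidefinite G (e.g. r = +/-1, or zeros)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  eff <- Z %*% rt
  data.frame(
    line_id = seq_len(n_lines),
    effect_F = eff[, 1],
    effect_M = eff[, 2]
  )
}

#' Simulate individual lifespans under the hemiclone design
#'
#' Generates one lifespan record per focal fly following the Gaussian
#' decomposition the downstream mixed models assume:
#' `lifespan = grand_mean[sex] + batch_effect[sex, batch] +
#' line_effect[line, sex] + vial_effect[vial] + residual`,
#' with line effects bivariate normal across the sexes (covariance `G`),
#' vial effects `N(0, V_V[sex])` and residuals `N(0, V_R[sex])`. There is a
#' single vial per line x sex x batch. Gaussian draws below `floor_days` are
#' truncated to the floor (real lifespans cannot be negative) and the number
#' of truncations is recorded in the `"n_truncated"` attribute.
#'
#' @param config A [design_config()].
#' @param params Named list of [genetic_params()], one element per
#'   chromosome type in `config` (names `autosome`, `X`), or a single
#'   `genetic_params` applied to all types.
#' @param seed Integer master seed (split internally per chromosome type).
#' @param floor_days Truncation floor for non-positive draws (default 1).
#' @return A data.frame of lifespan records with columns `line_id`,
#'   `chromosome_type`, `sex`, `batch`, `vial_id`, `lifespan`; true line
#'   effects attached as attribute `"line_effects"`.
#' @export
simulate_lifespans <- function(config, params, seed, floor_days = 1) {
  stopifnot(inherits(config, "design_config"))
  if (inherits(params, "genetic_params")) {
    params <- setNames(
      rep(list(params), length(config$chromosome_types)),
      config$chromosome_types
    )
  }
  if (!all(config$chromosome_types %in% names(params))) {
    stop("params must be supplied for every chromosome type in config")
  }
  seeds <- split_seed(seed, length(config$chromosome_types))
  out <- vector("list", length(config$chromosome_types))
  eff_out <- vector("list", length(config$chromosome_types))
  n_trunc <- 0L
  for (k in seq_along(config$chromosome_types)) {
    type <- config$chromosome_types[k]
    pp <- params[[type]]
    stopifnot(inherits(pp, "genetic_params"))
    sub_seeds <- split_seed(seeds[k], 2)
    eff <- simulate_line_effects(config$n_lines_per_type, pp$G, sub_seeds[1])
    prefix <- if (type == "autosome") "A" else "X"
    eff$line_id <- sprintf("%s%02d", prefix, eff$line_id)

    set.seed(sub_seeds[2])
    grid <- expand.grid(
      line = seq_len(config$n_lines_per_type),
      sex = config$sexes,
      batch = seq_len(config$n_batches),
      stringsAsFactors = FALSE
    )
    n_vials <- nrow(grid)
    nf <- config$n_flies_per_vial
    vial_eff <- rnorm(n_vials, 0, sqrt(pp$V_V[grid$sex]))
    line_eff <- ifelse(grid$sex == "F",
                       eff$effect_F[grid$line], eff$effect_M[grid$line])
    batch_eff <- if (is.null(pp$batch_effects)) {
      rep(0, n_vials)
    } else {
      pp$batch_effects[cbind(match(grid$sex, c("F", "M")), grid$batch)]
    }
    mu_vial <- pp$grand_mean[grid$sex] + batch_eff + line_eff + vial_eff
    resid <- rnorm(n_vials * nf, 0, rep(sqrt(pp$V_R[grid$sex]), each = nf))
    lifespan <- rep(mu_vial, each = nf) + resid
    below <- lifespan < floor_days
    n_trunc <- n_trunc + sum(below)
    lifespan[below] <- floor_days

    line_id <- eff$line_id[grid$line]
    out[[k]] <- data.frame(
      line_id = rep(line_id, each = nf),
      chromosome_type = type,
      sex = rep(grid$sex, each = nf),
      batch = rep(grid$batch, each = nf),
      vial_id = rep(sprintf("%s_%s_b%d", line_id, grid$sex, grid$batch),
                    each = nf),
      lifespan = lifespan,
      stringsAsFactors = FALSE
    )
    eff$chromosome_type <- type
    eff_out[[k]] <- eff
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "line_effects") <- do.call(rbind, eff_out)
  attr(res, "n_truncated") <- n_trunc
  res
}

#' Simulate an interval-censored Gompertz mortality cohort
#'
#' Draws `n` death ages from the Gompertz distribution with hazard
#' `mu(t) = alpha * exp(beta * t)` (survival
#' `S(t) = exp(-(alpha/beta) * (exp(beta*t) - 1))`, reducing to the
#' exponential `exp(-alpha*t)` at `beta = 0`) by inverse-CDF sampling, and
#' bins the deaths into half-open census intervals `(t[j-1], t[j]]` of width
#' `census_interval` up to `max_age`. Flies alive at `max_age` (possible for
#' `beta < 0`, where a fraction never dies) are recorded as right-censored.
#'
#' @param alpha Baseline mortality rate (1/day), > 0.
#' @param beta Demographic aging rate (1/day).
#' @param n Cohort size.
#' @param census_interval Census interval in days.
#' @param max_age Assay end in days.
#' @param seed Integer seed.
#' @param vial_id Identifier attached to the schedule.
#' @return A `mortality_schedule` object (see [mortality_schedule()]).
#' @export
simulate_gompertz_cohort <- function(alpha, beta, n, census_interval = 2,
                                     max_age = 200, seed = 1,
                                     vial_id = "vial1") {
  if (alpha <= 0) stop("alpha must be > 0")
  stopifnot(n >= 1, census_interval > 0, max_age > 0)
  set.seed(seed)
  t <- rgompertz(n, alpha, beta)
  # censuses happen only at whole census intervals; flies alive at the last
  # census before max_age are right-censored
  boundaries <- seq(0, max_age, by = census_interval)
  died <- t <= boundaries[length(boundaries)]
  # findInterval with left.open gives j for t in (b_j, b_{j+1}], which is
  # exactly the census-interval index
  deaths <- if (length(boundaries) > 1) {
    tabulate(findInterval(t[died], boundaries, left.open = TRUE),
             nbins = length(boundaries) - 1)
  } else integer(0)
  mortality_schedule(vial_id, boundaries, deaths, censored = sum(!died))
}

#' Gompertz random death ages
#'
#' Inverse-CDF sampler for the Gompertz distribution; returns `Inf` for
#' draws beyond the survival plateau when `beta < 0`.
#'
#' @param n Number of draws.
#' @param alpha,beta Gompertz parameters (1/day); `alpha > 0`.
#' @return Numeric vector of death ages in days.
#' @export
rgompertz <- function(n, alpha, beta) {
  if (alpha <= 0) stop("alpha must be > 0")
  u <- runif(n)
  if (abs(beta) < 1e-12) {
    -log(u) / alpha
  } else {
    arg <- 1 - (beta / alpha) * log(u)
    t <- rep(Inf, n)
    ok <- arg > 0
    t[ok] <- log(arg[ok]) / beta
    t
  }
}

#' Per-vial mortality schedule
#'
#' Container for an interval-censored death schedule: strictly increasing
#' census boundaries `t_0 < t_1 < ... < t_J`, the death count in each
#' half-open interval `(t[j-1], t[j]]`, and the number of individuals
#' surviving past `t_J` (right-censored).
#'
#' @param vial_id Identifier.
#' @param boundaries Numeric vector of census times (length J+1, `t_0 >= 0`).
#' @param deaths Integer vector of per-interval death counts (length J).
#' @param censored Count surviving past the last boundary.
#' @return An object of class `mortality_schedule`.
#' @export
mortality_schedule <- function(vial_id, boundaries, deaths, censored = 0) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) >= 2 && any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing")
  }
  if (length(boundaries) >= 1 && boundaries[1] < 0) {
    stop("boundaries must be non-negative")
  }
  deaths <- as.integer(deaths)
  if (length(deaths) != max(length(boundaries) - 1, 0)) {
    stop("deaths must have one entry per census interval")
  }
  if (any(deaths < 0) || censored < 0) stop("counts must be non-negative")
  structure(
    list(vial_id = vial_id, boundaries = boundaries, deaths = deaths,
         censored = as.integer(censored)),
    class = "mortality_schedule"
  )
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("Mortality schedule", x$vial_id, "-", sum(x$deaths), "deaths in",
      length(x$deaths), "intervals,", x$censored, "censored\n")
  invisible(x)
}

#' Simulate per-vial mortality schedules with line-level aging variation
#'
#' For each line and sex, draws per-line Gompertz parameters: the aging rate
#' `beta` from a cross-sex bivariate normal (covariance
#' `aging$G_beta`), and `log(alpha)` conditionally on `beta` with
#' within-sex correlation `aging$rho_la_beta` (default -0.9; baseline
#' mortality and aging rate trade off strongly in fly cohorts). Each line x
#' sex x batch vial is then an independent Gompertz cohort of
#' `n_flies_per_vial` flies scored on the census grid.
#'
#' @param config A [design_config()] (a single chromosome type is simulated;
#'   use the first element of `config$chromosome_types`).
#' @param aging An [aging_params()] object.
#' @param seed Integer master seed.
#' @param max_age Assay end in days.
#' @return List with `schedules` (list of `mortality_schedule`), `vials`
#'   (data.frame mapping vial_id to line/sex/batch) and `line_params`
#'   (data.frame of the true per-line `log_alpha` and `beta` per sex).
#' @export
simulate_mortality_schedules <- function(config, aging, seed, max_age = 200) {
  stopifnot(inherits(config, "design_config"), inherits(aging, "aging_params"))
  type <- config$chromosome_types[1]
  prefix <- if (type == "autosome") "A" else "X"
  seeds <- split_seed(seed, 3)
  nl <- config$n_lines_per_type

  beta_eff <- simulate_line_effects(nl, aging$G_beta, seeds[1])
  set.seed(seeds[2])
  lp <- vector("list", 2)
  for (i in 1:2) {
    s <- c("F", "M")[i]
    beta <- aging$mean_beta[[s]] +
      (if (s == "F") beta_eff$effect_F else beta_eff$effect_M)
    sd_b <- sqrt(aging$G_beta[i, i])
    rho <- aging$rho_la_beta
    z <- if (sd_b > 0) (beta - aging$mean_beta[[s]]) / sd_b else rep(0, nl)
    la <- aging$mean_log_alpha[[s]] +
      aging$sd_log_alpha[[s]] * (rho * z + sqrt(1 - rho^2) * rnorm(nl))
    lp[[i]] <- data.frame(
      line_id = sprintf("%s%02d", prefix, seq_len(nl)),
      sex = s, log_alpha = la, beta = beta, stringsAsFactors = FALSE
    )
  }
  line_params <- do.call(rbind, lp)

  grid <- expand.grid(
    line = seq_len(nl), sex = c("F", "M"),
    batch = seq_len(config$n_batches), stringsAsFactors = FALSE
  )
  vial_seeds <- split_seed(seeds[3], nrow(grid))
  schedules <- vector("list", nrow(grid))
  for (v in seq_len(nrow(grid))) {
    row <- match(
      paste(sprintf("%s%02d", prefix, grid$line[v]), grid$sex[v]),
      paste(line_params$line_id, line_params$sex)
    )
    vid <- sprintf("%s%02d_%s_b%d", prefix, grid$line[v], grid$sex[v],
                   grid$batch[v])
    schedules[[v]] <- simulate_gompertz_cohort(
      alpha = exp(line_params$log_alpha[row]),
      beta = line_params$beta[row],
      n = config$n_flies_per_vial,
      census_interval = config$census_interval,
      max_age = max_age, seed = vial_seeds[v], vial_id = vid
    )
  }
  vials <- data.frame(
    vial_id = vapply(schedules, `[[`, "", "vial_id"),
    line_id = sprintf("%s%02d", prefix, grid$line),
    chromosome_type = type, sex = grid$sex, batch = grid$batch,
    stringsAsFactors = FALSE
  )
  list(schedules = schedules, vials = vials, line_params = line_params)
}

#' Inject non-genetic outlier vials
#'
#' Contaminates a fraction of vials of the target sex by shifting all their
#' lifespans down by `shift` days (floored at `floor_days`), emulating an
#' extrinsic insult such as disease in individual vials. By default affected
#' vials are chosen uniformly at random across lines, i.e. with no
#' association to genotype; `genetic_outliers = TRUE` instead concentrates
#' contamination in the shortest-lived lines, for testing the power of the
#' genetic-association check.
#'
#' @param records Lifespan records from [simulate_lifespans()].
#' @param fraction Proportion of target-sex vials to contaminate, in [0, 1].
#' @param shift Downward shift in days.
#' @param target_sex Sex whose vials are affected (default `"F"`).
#' @param seed Integer seed.
#' @param floor_days Lower floor applied after shifting.
#' @param genetic_outliers If `TRUE`, sample vials with probability
#'   proportional to how short-lived their line is.
#' @return List with `records` (modified data.frame) and `affected_vials`
#'   (character vector of vial ids).
#' @export
inject_outlier_vials <- function(records, fraction, shift = 25,
                                 target_sex = "F", seed = 1, floor_days = 1,
                                 genetic_outliers = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  vials <- unique(records$vial_id[records$sex == target_sex])
  n_pick <- round(fraction * length(vials))
  if (n_pick == 0) {
    return(list(records = records, affected_vials = character(0)))
  }
  set.seed(seed)
  if (genetic_outliers) {
    vial_line <- records$line_id[match(vials, records$vial_id)]
    line_means <- tapply(records$lifespan[records$sex == target_sex],
                         records$line_id[records$sex == target_sex], mean)
    w <- rank(-line_means[vial_line])  # short-lived lines get large weight
    picked <- sample(vials, n_pick, prob = w)
  } else {
    picked <- sample(vials, n_pick)
  }
  hit <- records$vial_id %in% picked
  records$lifespan[hit] <- pmax(records$lifespan[hit] - shift, floor_days)
  list(records = records, affected_vials = sort(picked))
}

#' Bin lifespan records into per-vial mortality schedules
#'
#' Converts individual death ages into the interval-censored schedules the
#' Gompertz fitter consumes, using the assay's census grid: deaths are
#' tallied in half-open intervals `(t[j-1], t[j]]` of width
#' `census_interval` starting at 0. This mirrors a lifespan assay in which
#' deaths are only observed at transfers, so the lifespan records and the
#' mortality schedules are two views of the same data.
#'
#' @param records Lifespan records.
#' @param census_interval Census interval in days.
#' @return A list of `mortality_schedule`, one per vial.
#' @export
records_to_schedules <- function(records, census_interval = 2) {
  split_idx <- split(seq_len(nrow(records)), records$vial_id)
  lapply(names(split_idx), function(vid) {
    t <- records$lifespan[split_idx[[vid]]]
    max_b <- census_interval * ceiling(max(t) / census_interval)
    boundaries <- seq(0, max_b, by = census_interval)
    deaths <- tabulate(findInterval(t, boundaries, left.open = TRUE),
                       nbins = length(boundaries) - 1)
    mortality_schedule(vid, boundaries, deaths, censored = 0)
  })
}

#' Read and write lifespan records and mortality schedules as CSV
#'
#' `write_lifespans()`/`read_lifespans()` use the schema
#' `line_id,chromosome_type,sex,batch,vial_id,lifespan_days`;
#' `write_schedules()`/`read_schedules()` use
#' `vial_id,interval_start_day,interval_end_day,deaths,censored` (the
#' censored count is carried on each vial's last row).
#'
#' @param records Lifespan records data.frame.
#' @param schedules List of `mortality_schedule`.
#' @param path File path.
#' @return The input (writers, invisibly) or the parsed object (readers).
#' @export
write_lifespans <- function(records, path) {
  out <- data.frame(
    line_id = records$line_id,
    chromosome_type = records$chromosome_type,
    sex = records$sex,
    batch = records$batch,
    vial_id = records$vial_id,
    lifespan_days = records$lifespan
  )
  write.csv(out, path, row.names = FALSE)
  invisible(records)
}

#' @rdname write_lifespans
#' @export
read_lifespans <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "chromosome_type", "sex", "batch", "vial_id",
            "lifespan_days")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  data.frame(
    line_id = df$line_id, chromosome_type = df$chromosome_type,
    sex = df$sex, batch = df$batch, vial_id = df$vial_id,
    lifespan = df$lifespan_days, stringsAsFactors = FALSE
  )
}

#' @rdname write_lifespans
#' @export
write_schedules <- function(schedules, path) {
  rows <- lapply(schedules, function(s) {
    J <- length(s$deaths)
    if (J == 0) {
      return(data.frame(vial_id = s$vial_id, interval_start_day = NA_real_,
                        interval_end_day = NA_real_, deaths = 0L,
                        censored = s$censored))
    }
    data.frame(
      vial_id = s$vial_id,
      interval_start_day = s$boundaries[-(J + 1)],
      interval_end_day = s$boundaries[-1],
      deaths = s$deaths,
      censored = c(rep(0L, J - 1), s$censored)
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(schedules)
}

#' @rdname write_lifespans
#' @export
read_schedules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$vial_id), function(d) {
    d <- d[order(d$interval_start_day), ]
    if (all(is.na(d$interval_start_day))) {
      return(mortality_schedule(d$vial_id[1], numeric(0), integer(0),
                                sum(d$censored)))
    }
    mortality_schedule(
      d$vial_id[1],
      boundaries = c(d$interval_start_day[1], d$interval_end_day),
      deaths = d$deaths,
      censored = sum(d$censored)
    )
  })
}
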