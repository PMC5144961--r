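#' Prior specification for the Bayesian mixed models
#'
#' Random-effect (line and vial) covariance matrices receive
#' parameter-expanded priors with belief parameter `nu_random` (default 2):
#' the working covariance is inverse-Wishart with scale `nu_random *
#' scale_random * I` and the expansion scales are centred at zero with
#' variance `alpha_var`. Residual variances receive a near-flat scaled
#' inverse chi-squared (inverse-Wishart) prior with `nu_residual` (default
#' 0.002). Setting `px = FALSE` fixes the expansion scales at 1, giving
#' plain inverse-Wishart priors — useful for conjugate closed-form checks.
#'
#' @param nu_random Belief (shape) parameter for random-effect priors.
#' @param nu_residual Belief parameter for residual priors.
#' @param scale_random,scale_residual Prior scale (identity multiplier).
#' @param alpha_var Prior variance of the expansion scale parameters.
#' @param px Use parameter expansion for the random terms.
#' @param beta_prior_var Prior variance of fixed effects (near-flat).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(nu_random = 2, nu_residual = 0.002,
                       scale_random = 1, scale_residual = 1,
                       alpha_var = 1e6, px = TRUE, beta_prior_var = 1e8) {
  stopifnot(nu_random > 0, nu_residual > 0, scale_random > 0,
            scale_residual > 0, alpha_var > 0, beta_prior_var > 0)
  structure(
    list(nu_random = nu_random, nu_residual = nu_residual,
         scale_random = scale_random, scale_residual = scale_residual,
         alpha_var = alpha_var, px = isTRUE(px),
         beta_prior_var = beta_prior_var),
    class = "prior_spec"
  )
}

#' MCMC chain settings
#'
#' The default is a desk-scale chain (30,000 iterations, 5,000 burn-in,
#' thinning 25, so 1,000 retained samples). [paper_scale_chain_config()]
#' returns the full-length production settings (1,100,000 / 100,000 /
#' 1,000).
#'
#' @param iterations Total iterations.
#' @param burn_in Burn-in iterations (must be < `iterations`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed for the chain.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(iterations = 30000L, burn_in = 5000L, thin = 25L,
                         seed = 1L) {
  stopifnot(burn_in < iterations, thin >= 1, burn_in >= 0)
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = as.integer(seed)),
    class = "chain_config"
  )
}

#' @rdname chain_config
#' @export
paper_scale_chain_config <- function(seed = 1L) {
  chain_config(iterations = 1100000L, burn_in = 100000L, thin = 1000L,
               seed = seed)
}

#' Build the fixed-effect design for a multi-response fit
#'
#' Constructs sex-specific intercepts plus sex-specific centred batch
#' dummies: batches 2..B are coded 0/1, centred by subtracting their
#' (weight-adjusted) column means, and crossed with the sex indicator. With
#' this coding the intercepts estimate the global mean per sex rather than
#' the mean of a reference batch. Full column rank is verified; collinear
#' columns are reported by name.
#'
#' @param df Data.frame with columns `sex` and `batch` (one row per
#'   observation unit).
#' @param weights Optional row weights (e.g. flies per vial) used for the
#'   centring constants.
#' @return List with `X` (design matrix), `columns` (names), and
#'   `centering` (the per-batch centring constants).
#' @export
build_design <- function(df, weights = NULL) {
  stopifnot(all(c("sex", "batch") %in% names(df)))
  sexes <- sort(unique(df$sex))
  if (!all(c("F", "M") %in% sexes)) {
    stop("both sexes must be present in the data")
  }
  batches <- sort(unique(df$batch))
  nr <- nrow(df)
  if (is.null(weights)) weights <- rep(1, nr)
  cols <- list()
  cnames <- character(0)
  for (s in c("F", "M")) {
    cols[[length(cols) + 1]] <- as.numeric(df$sex == s)
    cnames <- c(cnames, paste0("trait_", s))
  }
  centering <- numeric(0)
  if (length(batches) >= 2) {
    for (b in batches[-1]) {
      ind <- as.numeric(df$batch == b)
      ctr <- sum(weights * ind) / sum(weights)
      centering[as.character(b)] <- ctr
      for (s in c("F", "M")) {
        cols[[length(cols) + 1]] <- (ind - ctr) * (df$sex == s)
        cnames <- c(cnames, sprintf("trait_%s:batch%s", s, b))
      }
    }
  } else {
    warning("single batch: no batch dummies included")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- cnames
  qr_x <- qr(sqrt(weights) * X)
  if (qr_x$rank < ncol(X)) {
    bad <- cnames[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(X = X, columns = cnames, centering = centering)
}

# Aggregate data to the group (vial) level the sampler operates on.
# Returns a data.frame sorted canonically by (line_id, sex, batch) so that
# record order never affects the sampler's random-number stream.
.group_data <- function(data, trait, include_vial) {
  if (trait == "lifespan") {
    need <- c("line_id", "sex", "batch", "vial_id", "lifespan")
    stopifnot(all(need %in% names(data)))
    idx <- split(seq_len(nrow(data)), data$vial_id)
    g <- data.frame(
      vial_id = names(idx),
      line_id = data$line_id[vapply(idx, `[`, 0L, 1)],
      sex = data$sex[vapply(idx, `[`, 0L, 1)],
      batch = data$batch[vapply(idx, `[`, 0L, 1)],
      n = lengths(idx),
      ybar = vapply(idx, function(i) mean(data$lifespan[i]), 0),
      ss = vapply(idx, function(i) {
        y <- data$lifespan[i]
        sum((y - mean(y))^2)
      }, 0),
      stringsAsFactors = FALSE
    )
  } else {
    value_col <- if ("beta_x100" %in% names(data)) "beta_x100" else "value"
    need <- c("line_id", "sex", "batch", value_col)
    stopifnot(all(need %in% names(data)))
    g <- data.frame(
      vial_id = if ("vial_id" %in% names(data)) data$vial_id else
        sprintf("%s_%s_b%s", data$line_id, data$sex, data$batch),
      line_id = data$line_id, sex = data$sex, batch = data$batch,
      n = 1, ybar = data[[value_col]], ss = 0,
      stringsAsFactors = FALSE
    )
    g <- g[is.finite(g$ybar), ]
  }
  g <- g[order(g$line_id, g$sex, g$batch), ]
  rownames(g) <- NULL
  if (include_vial && all(g$n == 1)) {
    stop("vial and residual variances are not identifiable with one ",
         "observation per vial; drop the vial term")
  }
  g
}

#' Fit a multi-response mixed model by blocked Gibbs sampling
#'
#' Fits the Gaussian multi-response model used for hemiclone variance
#' partitioning: female and male trait values as separate responses,
#' sex-specific intercepts and centred batch dummies as fixed effects, an
#' unstructured 2x2 cross-sex line covariance, per-sex vial variances (for
#' individual-level lifespan data only; cross-sex vial and residual
#' covariances are structurally zero because every vial and fly is a single
#' sex), and per-sex residual variances. Sampling is by a blocked Gibbs
#' scheme with parameter expansion for the random terms (see
#' [prior_spec()]); all conditionals are conjugate.
#'
#' Supply individual lifespan records (`trait = "lifespan"`, vial random
#' effect included) or a table of per-vial aging rates
#' (`trait = "aging"`, column `beta_x100` or `value`; no vial term, since
#' there is a single aging estimate per vial). Data must contain a single
#' chromosome type — X-lines and A-lines are fitted separately.
#'
#' @param data Lifespan records or an aging-rate table.
#' @param trait `"lifespan"` or `"aging"`.
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @param include_vial Include the vial random effect (default: yes for
#'   lifespan, no for aging).
#' @return An object of class `posterior_chain`: a list with `samples` (one
#'   row per retained draw; fixed effects, `V_L_F`, `Cov_MF`, `V_L_M`, vial
#'   and residual variances), plus metadata.
#' @export
run_gibbs <- function(data, trait = c("lifespan", "aging"),
                      prior = prior_spec(), config = chain_config(),
                      include_vial = NULL) {
  trait <- match.arg(trait)
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "chain_config"))
  if (is.null(include_vial)) include_vial <- trait == "lifespan"
  if ("chromosome_type" %in% names(data)) {
    types <- unique(data$chromosome_type)
    if (length(types) > 1) {
      stop("data contains more than one chromosome type; fit them separately")
    }
    line_type <- types
  } else {
    line_type <- NA_character_
  }
  g <- .group_data(data, trait, include_vial)
  des <- build_design(g, weights = g$n)
  lines <- sort(unique(g$line_id))

  set.seed(config$seed)
  res <- gibbs_chain_cpp(
    ybar = g$ybar, n = g$n, ss = g$ss,
    sex = as.integer(g$sex == "M"),
    line = match(g$line_id, lines) - 1L,
    X = des$X, n_lines = length(lines), vial_effect = include_vial,
    n_iter = config$iterations, burn = config$burn_in, thin = config$thin,
    nu_g = prior$nu_random, v0_g = prior$scale_random,
    nu_r = prior$nu_residual, v0_r = prior$scale_residual,
    alpha_var = prior$alpha_var, px = prior$px,
    beta_prior_var = prior$beta_prior_var
  )
  samples <- res$samples
  vc_names <- c("V_L_F", "Cov_MF", "V_L_M",
                if (include_vial) c("V_V_F", "V_V_M"),
                "V_R_F", "V_R_M")
  colnames(samples) <- c(des$columns, vc_names)
  structure(
    list(samples = samples, trait = trait, line_type = line_type,
         include_vial = include_vial, prior = prior, config = config,
         n_obs = sum(g$n), n_lines = length(lines), n_groups = nrow(g)),
    class = "posterior_chain"
  )
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "Posterior chain (%s%s): %d retained samples, %d lines, %d groups, %d obs\n",
    x$trait, if (!is.na(x$line_type)) paste0(", ", x$line_type) else "",
    nrow(x$samples), x$n_lines, x$n_groups, x$n_obs))
  vc <- grep("^(V_|Cov_)", colnames(x$samples), value = TRUE)
  print(round(t(apply(x$samples[, vc, drop = FALSE], 2, function(v) {
    c(mean = mean(v), sd = sd(v),
      `2.5%` = unname(quantile(v, 0.025)),
      `97.5%` = unname(quantile(v, 0.975)))
  })), 3))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor (PSRF) with its upper confidence limit,
#' computed per parameter from two or more chains of equal length via the
#' corrected between/within-chain variance ratio (including the
#' degrees-of-freedom adjustment and an F-based upper limit). Parameters
#' whose upper limit exceeds `threshold` (default 1.05, the conventional
#' convergence bar for these models) are flagged.
#'
#' @param chains List of `posterior_chain` objects or numeric matrices with
#'   identical dimensions and column names.
#' @param confidence Confidence level of the upper limit.
#' @param threshold Flagging threshold on the upper limit.
#' @return Data.frame with columns `parameter`, `psrf`, `upper`, `flagged`.
#' @export
gelman_rubin <- function(chains, confidence = 0.95, threshold = 1.05) {
  mats <- lapply(chains, function(ch) {
    if (inherits(ch, "posterior_chain")) ch$samples else as.matrix(ch)
  })
  m <- length(mats)
  if (m < 2) stop("at least two chains are required")
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 0L) == n)) {
    stop("chains must have equal retained length")
  }
  pars <- colnames(mats[[1]])
  if (is.null(pars)) pars <- paste0("par", seq_len(ncol(mats[[1]])))
  res <- lapply(seq_along(pars), function(j) {
    x <- vapply(mats, function(M) M[, j], numeric(n))   # n x m
    s2 <- apply(x, 2, var)
    xbar <- colMeans(x)
    W <- mean(s2)
    B <- n * var(xbar)
    if (W <= 0) {
      warning("zero within-chain variance for ", pars[j])
      return(data.frame(parameter = pars[j], psrf = NA_real_,
                        upper = NA_real_, flagged = NA))
    }
    if (B == 0) {
      warning("identical chain means for ", pars[j],
              " (duplicated chains?): PSRF is degenerate")
    }
    muhat <- mean(xbar)
    Vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
    var_w <- var(s2) / m
    var_b <- 2 * B^2 / (m - 1)
    cov_wb <- (n / m) * (cov(s2, xbar^2) - 2 * muhat * cov(s2, xbar))
    var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
                2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
    df_V <- if (var_V > 0) 2 * Vhat^2 / var_V else Inf
    corr <- if (is.finite(df_V)) (df_V + 3) / (df_V + 1) else 1
    psrf <- sqrt(corr * Vhat / W)
    w_df <- if (var_w > 0) 2 * W^2 / var_w else Inf
    R2_fixed <- (n - 1) / n
    R2_random <- (1 + 1 / m) / n * B / W
    upper <- sqrt(corr * (R2_fixed +
                            qf((1 + confidence) / 2, m - 1, w_df) * R2_random))
    data.frame(parameter = pars[j], psrf = psrf, upper = upper,
               flagged = upper > threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @importFrom stats cov
NULL
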