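#' Gompertz hazard and survival functions
#'
#' The Gompertz mortality model decomposes a cohort's death schedule into a
#' baseline mortality rate `alpha` and a demographic aging rate `beta`:
#' the hazard is `mu(t) = alpha * exp(beta * t)` and the survivorship is
#' `S(t) = exp(-(alpha/beta) * (exp(beta*t) - 1))`. At `beta = 0` the model
#' collapses to constant-hazard (exponential) mortality `S(t) = exp(-alpha*t)`;
#' below `|beta| < beta_tol` a series expansion of `(exp(beta*t)-1)/beta` is
#' used so the survival function is continuous through zero.
#'
#' @param alpha Baseline mortality (1/day), > 0.
#' @param beta Aging rate (1/day).
#' @param t Age in days (vectorized; `t >= 0` for survival).
#' @param beta_tol Switch point to the series form (default 1e-8).
#' @return Hazard rate (1/day) or survival probability.
#' @export
gompertz_hazard <- function(alpha, beta, t) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  alpha * exp(beta * t)
}

#' @rdname gompertz_hazard
#' @export
gompertz_survival <- function(alpha, beta, t, beta_tol = 1e-8) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  exp(-alpha * .cumhaz_factor(beta, t, beta_tol))
}

# (exp(beta*t) - 1)/beta, stable through beta = 0
.cumhaz_factor <- function(beta, t, beta_tol = 1e-8) {
  if (abs(beta) < beta_tol) {
    t * (1 + beta * t / 2 + (beta * t)^2 / 6)
  } else {
    expm1(beta * t) / beta
  }
}

#' Fit a Gompertz mortality model to an interval-censored death schedule
#'
#' Maximum-likelihood estimation of `(alpha, beta)` from per-vial census
#' counts. The log-likelihood is the multinomial interval-censored form
#' `sum_j d_j * log(S(t[j-1]) - S(t[j])) + c * log(S(t_J))`, where `d_j` are
#' the deaths in `(t[j-1], t[j]]` and `c` the count surviving past the last
#' census. Optimization is on `(log(alpha), beta)`, which enforces
#' `alpha > 0` and tames the skew of `alpha`; a 3x3 multi-start grid guards
#' against the flat-likelihood ridges that small cohorts produce. Standard
#' errors come from the observed information at the optimum (delta method
#' for `alpha`); `converged` requires optimizer success, a small gradient
#' norm and a positive-definite Hessian.
#'
#' A schedule in which all deaths fall in a single census interval leaves
#' `beta` unidentifiable; the fit is returned non-converged with flag
#' `"beta_unidentifiable"`.
#'
#' @param schedule A [mortality_schedule()].
#' @param min_deaths Minimum death count required to attempt a fit.
#' @return An object of class `gompertz_fit` with elements `alpha`, `beta`,
#'   `log_alpha`, `loglik`, `se_alpha`, `se_beta`, `se_log_alpha`,
#'   `converged`, `flag`, `n_deaths`, `vial_id`.
#' @export
fit_gompertz <- function(schedule, min_deaths = 2L) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  d <- schedule$deaths
  b <- schedule$boundaries
  cens <- schedule$censored
  if (length(d) == 0 || sum(d) == 0) stop("schedule contains no deaths")
  res <- list(vial_id = schedule$vial_id, alpha = NA_real_, beta = NA_real_,
              log_alpha = NA_real_, loglik = NA_real_, se_alpha = NA_real_,
              se_beta = NA_real_, se_log_alpha = NA_real_, converged = FALSE,
              flag = "", n_deaths = sum(d))
  if (sum(d > 0) < 2 || sum(d) < min_deaths) {
    res$flag <- "beta_unidentifiable"
    class(res) <- "gompertz_fit"
    return(res)
  }

  nll <- function(par) {
    a <- exp(par[1]); be <- par[2]
    S <- exp(-a * vapply(b, .cumhaz_factor, 0, beta = be))
    p <- S[-length(S)] - S[-1]
    p[p < 1e-300] <- 1e-300
    SJ <- max(S[length(S)], 1e-300)
    -(sum(d * log(p)) + cens * log(SJ))
  }

  # crude location: median death age via the survival identity at S = 0.5
  mids <- (b[-1] + b[-length(b)]) / 2
  med <- mids[which.max(cumsum(d) >= sum(d) / 2)]
  starts <- list()
  for (be0 in c(0.0, 0.08, 0.2)) {
    a0 <- if (be0 == 0) log(2) / med else be0 * log(2) / expm1(be0 * med)
    for (f in c(0.3, 1, 3)) starts[[length(starts) + 1]] <- c(log(a0 * f), be0)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    res$flag <- "optim_failed"
    class(res) <- "gompertz_fit"
    return(res)
  }
  # polish from the incumbent (a fresh start refreshes BFGS's Hessian
  # approximation, which matters on the flat beta-ridges of small cohorts)
  again <- tryCatch(
    optim(best$par, nll, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL
  )
  if (!is.null(again) && again$value <= best$value) best <- again
  par <- best$par
  res$log_alpha <- par[1]
  res$alpha <- exp(par[1])
  res$beta <- par[2]
  res$loglik <- -best$value

  g <- tryCatch(.num_grad(nll, par), error = function(e) c(NA, NA))
  H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  ok_grad <- FALSE
  ok_hess <- FALSE
  if (!is.null(H) && all(is.finite(H))) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) {
      V <- solve(H)
      res$se_log_alpha <- sqrt(V[1, 1])
      res$se_beta <- sqrt(V[2, 2])
      res$se_alpha <- res$alpha * res$se_log_alpha
      ok_hess <- TRUE
      # curvature-scaled stationarity: the expected log-likelihood gain of
      # one Newton step (half the squared Newton decrement) must be tiny;
      # a raw gradient norm is scale-blind on flat likelihoods
      if (all(is.finite(g))) {
        ok_grad <- 0.5 * drop(t(g) %*% V %*% g) < 1e-3
      }
    }
  }
  res$converged <- (best$convergence == 0) && ok_grad && ok_hess
  if (!ok_hess) res$flag <- "information_not_pd"
  class(res) <- "gompertz_fit"
  res
}

.num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Gompertz fit %s: alpha = %.4g (se %.3g), beta = %.4g (se %.3g), logLik = %.2f, converged = %s%s\n",
    x$vial_id, x$alpha, x$se_alpha, x$beta, x$se_beta, x$loglik,
    x$converged, if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Fit Gompertz models to a collection of schedules
#'
#' Applies [fit_gompertz()] to each schedule and assembles the per-vial
#' estimates into a data.frame with the columns
#' `vial_id, alpha, beta, beta_x100, log_alpha, loglik, se_alpha, se_beta,
#' converged, flag`. `beta_x100` is the reporting scale conventionally used
#' for fly aging rates (exactly `100 * beta`).
#'
#' @param schedules List of `mortality_schedule`.
#' @param min_deaths Passed to [fit_gompertz()].
#' @return A data.frame, one row per vial.
#' @export
fit_gompertz_vials <- function(schedules, min_deaths = 2L) {
  fits <- lapply(schedules, function(s) {
    tryCatch(fit_gompertz(s, min_deaths = min_deaths),
             error = function(e) {
               list(vial_id = s$vial_id, alpha = NA_real_, beta = NA_real_,
                    log_alpha = NA_real_, loglik = NA_real_,
                    se_alpha = NA_real_, se_beta = NA_real_,
                    se_log_alpha = NA_real_,
                    converged = FALSE, flag = conditionMessage(e),
                    n_deaths = sum(s$deaths))
             })
  })
  data.frame(
    vial_id = vapply(fits, function(f) as.character(f$vial_id), ""),
    alpha = vapply(fits, `[[`, 0, "alpha"),
    beta = vapply(fits, `[[`, 0, "beta"),
    beta_x100 = 100 * vapply(fits, `[[`, 0, "beta"),
    log_alpha = vapply(fits, `[[`, 0, "log_alpha"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    se_alpha = vapply(fits, `[[`, 0, "se_alpha"),
    se_beta = vapply(fits, `[[`, 0, "se_beta"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    flag = vapply(fits, function(f) as.character(f$flag), ""),
    stringsAsFactors = FALSE
  )
}

#' Correlation between log baseline mortality and aging rate
#'
#' Pearson correlation of `log(alpha_hat)` with `beta_hat` across converged
#' per-vial fits (alpha is log-transformed because its sampling distribution
#' is strongly right-skewed), with the Fisher-z confidence interval and
#' two-sided p-value.
#'
#' @param fits Data.frame from [fit_gompertz_vials()] (or any data.frame
#'   with columns `log_alpha`, `beta`, `converged`).
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return List with `r`, `ci`, `p`, `n`.
#' @export
log_alpha_beta_correlation <- function(fits, conf_level = 0.95) {
  keep <- fits$converged & is.finite(fits$log_alpha) & is.finite(fits$beta)
  la <- fits$log_alpha[keep]
  be <- fits$beta[keep]
  if (length(la) < 3) stop("at least 3 converged fits required")
  if (sd(la) == 0 || sd(be) == 0) {
    stop("correlation undefined: zero variance in the fitted parameters")
  }
  ct <- cor.test(la, be, method = "pearson", conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(la))
}
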