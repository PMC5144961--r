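#' Restricted maximum likelihood fits with variance constraints
#'
#' Fits the hemiclone mixed model by direct maximization of the restricted
#' log-likelihood, treating each sex x chromosome-type combination as a
#' separate trait (up to four traits when both line types are supplied).
#' The model has fixed trait x batch cell means, a line random effect with
#' free variances per trait and free cross-sex covariances *within* each
#' line type (cross-type covariances are structurally zero: a line is either
#' an X-line or an A-line), per-trait vial variances (individual-level
#' lifespan data only), and per-trait residual variances.
#'
#' The likelihood is evaluated on vial-level sufficient statistics (vial
#' means plus within-vial sums of squares), which is exact for the Gaussian
#' model: vial means within a line are jointly normal with a cross-sex
#' line covariance plus a diagonal `V_V + V_R/n` term, and within-vial
#' deviations depend on the residual variance only. Variances are
#' parameterized on the log scale and cross-sex correlations via `atanh`,
#' so every iterate is a valid covariance structure; constraints are
#' implemented by reparameterization (tying or dropping parameters), never
#' by penalties.
#'
#' Supported constraints (combine in a list):
#' \describe{
#'   \item{`zero_line`}{character vector of traits (e.g. `"X.F"`) whose line
#'     variance is fixed at zero (the null of the univariate variance
#'     tests).}
#'   \item{`x_proportion`}{`list(sex =, prop =)`: the X-linked share of
#'     additive variance `V_A_X / (V_A_X + V_A_A)` in the given sex is fixed
#'     at `prop` (e.g. 0.188 for the euchromatin share, 0.156 for the gene
#'     share).}
#'   \item{`va_ratio_mf_x`}{`list(ratio =, mean_standardize =)`: the
#'     male-to-female ratio of X-linked additive variance is fixed at
#'     `ratio` (hemizygous conversion applied: `V_A = V_L` for male X,
#'     `2 V_L` otherwise). With `mean_standardize = TRUE` the ratio applies
#'     to squared coefficients of variation, using the observed sex means.}
#'   \item{`equal_rmf`}{`TRUE`: one common cross-sex correlation for both
#'     line types.}
#' }
#'
#' @param data Lifespan records (columns `line_id`, `chromosome_type`,
#'   `sex`, `batch`, `vial_id`, `lifespan`) or an aging table (column
#'   `beta_x100` or `value`; one row per vial).
#' @param trait `"lifespan"` or `"aging"`.
#' @param constraints Optional list of constraints (see Details).
#' @param include_vial Include the vial variance (default: lifespan yes,
#'   aging no).
#' @return An object of class `reml_fit` with the component estimates
#'   (`VL`, `VV`, `VR`, `cov` and `r` per line type, `VA`), fixed-effect
#'   cell means, the restricted log-likelihood `loglik`, and convergence
#'   information.
#' @export
reml_fit <- function(data, trait = c("lifespan", "aging"),
                     constraints = NULL, include_vial = NULL) {
  trait <- match.arg(trait)
  if (is.null(include_vial)) include_vial <- trait == "lifespan"
  g <- .reml_groups(data, trait)
  pm <- .reml_parmap(g, include_vial, constraints)
  lik <- .reml_likelihood_env(g, pm, include_vial)

  start <- .reml_start(g, pm, include_vial)
  ctrl <- list(iter.max = 1000, eval.max = 2000, rel.tol = 1e-12,
               x.tol = 1e-10)
  opt <- nlminb(start, lik$nll, lower = pm$lower, upper = pm$upper,
                control = ctrl)
  # polish / restart if the first attempt did not cleanly converge (very
  # tight tolerances can trip nlminb's false-convergence heuristic)
  if (opt$convergence != 0) {
    opt2 <- nlminb(opt$par, lik$nll, lower = pm$lower, upper = pm$upper,
                   control = list(iter.max = 1000, eval.max = 2000))
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  if (opt$convergence != 0) {
    opt3 <- nlminb(start + rnorm(length(start), 0, 0.3), lik$nll,
                   lower = pm$lower, upper = pm$upper, control = ctrl)
    if (opt3$objective < opt$objective) opt <- opt3
  }
  est <- pm$unpack(opt$par)
  beta <- lik$beta_hat(opt$par)

  va <- vapply(pm$traits, function(t) .va_factor(t) * est$VL[[t]], 0)
  means <- vapply(pm$traits, function(t) {
    cells <- grep(paste0("^", t, ":"), names(beta))
    mean(beta[cells])
  }, 0)
  structure(
    list(trait = trait, include_vial = include_vial, traits = pm$traits,
         VL = est$VL, VV = est$VV, VR = est$VR, cov = est$cov, r = est$r,
         VA = va, means = means, cell_means = beta,
         loglik = -opt$objective, converged = opt$convergence == 0,
         opt_message = opt$message, constraints = constraints,
         n_obs = sum(g$n), n_params = length(start)),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s): restricted logLik = %.3f, converged = %s\n",
              x$trait, x$loglik, x$converged))
  tab <- data.frame(trait = x$traits,
                    mean = round(x$means[x$traits], 2),
                    V_L = round(x$VL[x$traits], 3),
                    V_A = round(x$VA[x$traits], 3))
  if (x$include_vial) tab$V_V <- round(x$VV[x$traits], 3)
  tab$V_R <- round(x$VR[x$traits], 3)
  print(tab, row.names = FALSE)
  if (length(x$r)) {
    cat("cross-sex r:",
        paste(sprintf("%s = %.3f", names(x$r), x$r), collapse = ", "), "\n")
  }
  if (!is.null(x$constraints)) cat("constraints applied\n")
  invisible(x)
}

#' Likelihood ratio test between nested REML fits
#'
#' `X^2 = 2 (l_full - l_constrained)` referred to a chi-squared distribution
#' with `df` degrees of freedom. For variance components tested on the
#' boundary of the parameter space, the naive `chi^2_1` reference is
#' conservative; `boundary_mixture = TRUE` uses the
#' `0.5 chi^2_0 + 0.5 chi^2_1` mixture instead.
#'
#' Both fits must come from the same data and share the fixed-effect
#' structure (REML likelihoods are only comparable then). A constrained fit
#' with a *higher* restricted likelihood than the full fit signals an
#' optimizer failure and is surfaced as an error.
#'
#' @param full,constrained `reml_fit` objects, constrained nested in full.
#' @param df Degrees of freedom of the test.
#' @param boundary_mixture Use the 50:50 boundary mixture reference.
#' @return List with `statistic`, `df`, `p`, `method`.
#' @export
lrt <- function(full, constrained, df = 1, boundary_mixture = FALSE) {
  stopifnot(inherits(full, "reml_fit"), inherits(constrained, "reml_fit"))
  if (full$n_obs != constrained$n_obs) {
    stop("fits are not on the same data")
  }
  if (full$n_params < constrained$n_params) {
    stop("constrained model is not nested in the full model")
  }
  x2 <- 2 * (full$loglik - constrained$loglik)
  if (x2 < -1e-2) {
    stop(sprintf(
      "constrained fit has higher restricted likelihood (delta = %.4f): optimizer failure; no p-value",
      x2))
  }
  x2 <- max(x2, 0)
  if (boundary_mixture && df == 1) {
    p <- if (x2 == 0) 1 else 0.5 * pchisq(x2, 1, lower.tail = FALSE)
    method <- "0.5*chisq(0) + 0.5*chisq(1) boundary mixture"
  } else {
    p <- pchisq(x2, df, lower.tail = FALSE)
    method <- sprintf("chisq(%d)", df)
  }
  list(statistic = x2, df = df, p = p, method = method)
}

# additive-variance conversion factor: hemiclones clone haploid sets, so
# V_A = 2 V_L, except the hemizygous male X where V_A = V_L
.va_factor <- function(trait) {
  if (trait == "X.M") 1 else 2
}

.reml_groups <- function(data, trait) {
  if (!("chromosome_type" %in% names(data))) {
    data$chromosome_type <- "autosome"
  }
  tshort <- ifelse(data$chromosome_type == "X", "X", "A")
  if (trait == "lifespan") {
    stopifnot(all(c("line_id", "sex", "batch", "vial_id", "lifespan") %in%
                    names(data)))
    idx <- split(seq_len(nrow(data)), data$vial_id)
    first <- vapply(idx, `[`, 0L, 1)
    g <- data.frame(
      vial_id = names(idx),
      line_id = data$line_id[first],
      trait = paste0(tshort[first], ".", data$sex[first]),
      batch = data$batch[first],
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
    g <- data.frame(
      vial_id = if ("vial_id" %in% names(data)) data$vial_id else
        seq_len(nrow(data)),
      line_id = data$line_id,
      trait = paste0(tshort, ".", data$sex),
      batch = data$batch,
      n = 1, ybar = data[[value_col]], ss = 0,
      stringsAsFactors = FALSE
    )
    g <- g[is.finite(g$ybar), ]
  }
  g <- g[order(g$line_id, g$trait, g$batch), ]
  rownames(g) <- NULL
  g
}

# Parameter map: which (co)variance parameters are free, how tied/fixed
# ones are reconstructed, box bounds, and the unpack function.
.reml_parmap <- function(g, include_vial, constraints) {
  traits <- sort(unique(g$trait))
  types <- sort(unique(sub("\\..*$", "", traits)))
  zero <- character(0)
  tie <- list()   # trait -> list(source, factor_fun(VL_source, means))
  if (!is.null(constraints$zero_line)) {
    zero <- constraints$zero_line
    if (!all(zero %in% traits)) stop("unknown trait in zero_line constraint")
  }
  means_obs <- vapply(traits, function(t) {
    sum(g$ybar[g$trait == t] * g$n[g$trait == t]) / sum(g$n[g$trait == t])
  }, 0)
  if (!is.null(constraints$x_proportion)) {
    xp <- constraints$x_proportion
    s <- xp$sex
    src <- paste0("A.", s); tgt <- paste0("X.", s)
    if (!all(c(src, tgt) %in% traits)) {
      stop("x_proportion constraint needs both line types for sex ", s)
    }
    fac <- (xp$prop / (1 - xp$prop)) * .va_factor(src) / .va_factor(tgt)
    tie[[tgt]] <- list(source = src, factor = fac)
  }
  if (!is.null(constraints$va_ratio_mf_x)) {
    vr <- constraints$va_ratio_mf_x
    ratio <- if (is.null(vr$ratio)) 1 else vr$ratio
    ms <- if (isTRUE(vr$mean_standardize)) {
      (means_obs[["X.M"]] / means_obs[["X.F"]])^2
    } else 1
    if (!all(c("X.F", "X.M") %in% traits)) {
      stop("va_ratio_mf_x constraint needs both sexes of the X lines")
    }
    fac <- ratio * ms * .va_factor("X.F") / .va_factor("X.M")
    tie[["X.M"]] <- list(source = "X.F", factor = fac)
  }
  free_vl <- setdiff(traits, c(zero, names(tie)))
  equal_r <- isTRUE(constraints$equal_rmf)
  # an r parameter exists for each type whose two traits both have
  # (possibly tied) nonzero line variance
  r_types <- types[vapply(types, function(ty) {
    tt <- paste0(ty, c(".F", ".M"))
    all(tt %in% traits) && !any(tt %in% zero)
  }, TRUE)]
  r_names <- if (equal_r && length(r_types) > 1) "r_shared" else
    paste0("r_", r_types)

  par_names <- c(paste0("logVL_", free_vl),
                 r_names,
                 if (include_vial) paste0("logVV_", traits),
                 paste0("logVR_", traits))
  lower <- rep(-30, length(par_names))
  upper <- rep(30, length(par_names))
  is_r <- grepl("^r_", par_names)
  lower[is_r] <- -5; upper[is_r] <- 5

  unpack <- function(par) {
    names(par) <- par_names
    VL <- setNames(numeric(length(traits)), traits)
    for (t in free_vl) VL[t] <- exp(par[[paste0("logVL_", t)]])
    for (t in names(tie)) VL[t] <- tie[[t]]$factor * VL[tie[[t]]$source]
    VV <- if (include_vial) {
      setNames(exp(par[paste0("logVV_", traits)]), traits)
    } else setNames(rep(0, length(traits)), traits)
    VR <- setNames(exp(par[paste0("logVR_", traits)]), traits)
    r <- setNames(numeric(length(r_types)), r_types)
    for (ty in r_types) {
      nm <- if (equal_r && length(r_types) > 1) "r_shared" else
        paste0("r_", ty)
      r[ty] <- tanh(par[[nm]])
    }
    cov <- setNames(numeric(length(r_types)), r_types)
    for (ty in r_types) {
      cov[ty] <- r[ty] * sqrt(VL[[paste0(ty, ".F")]] * VL[[paste0(ty, ".M")]])
    }
    list(VL = VL, VV = VV, VR = VR, r = r, cov = cov)
  }
  list(traits = traits, types = types, r_types = r_types,
       par_names = par_names, lower = lower, upper = upper,
       free_vl = free_vl, tie = tie, zero = zero, equal_r = equal_r,
       unpack = unpack, means_obs = means_obs)
}

# Moment (method-of-moments / ANOVA-type) starting values.  For balanced
# line x batch layouts these are the expected-mean-square estimators, i.e.
# the REML optimum itself, so the optimizer only needs to confirm them.
.reml_start <- function(g, pm, include_vial) {
  start <- setNames(numeric(length(pm$par_names)), pm$par_names)
  VL0s <- setNames(rep(1e-3, length(pm$traits)), pm$traits)
  lm_store <- list()
  for (t in pm$traits) {
    gt <- g[g$trait == t, ]
    vtot <- max(var(gt$ybar), 1e-3)
    VR0 <- if (any(gt$n > 1)) {
      max(sum(gt$ss) / sum(pmax(gt$n - 1, 0)), 1e-3)
    } else 0.8 * vtot
    nbar <- mean(gt$n)
    lm <- tapply(gt$ybar, gt$line_id, mean)
    bm <- tapply(gt$ybar, gt$batch, mean)
    gm <- mean(gt$ybar)
    Bn <- length(bm)
    inter <- gt$ybar - lm[as.character(gt$line_id)] -
      bm[as.character(gt$batch)] + gm
    ms_inter <- if (length(lm) > 1 && Bn > 1) {
      sum(inter^2) / ((length(lm) - 1) * (Bn - 1))
    } else vtot
    ms_line <- if (length(lm) > 1) Bn * sum((lm - gm)^2) / (length(lm) - 1)
      else vtot
    if (include_vial) {
      VV0 <- max(ms_inter - VR0 / nbar, 1e-3)
      VL0 <- max((ms_line - ms_inter) / Bn, 1e-3)
      start[paste0("logVV_", t)] <- log(VV0)
    } else {
      VL0 <- max((ms_line - ms_inter) / Bn, 1e-3)
    }
    VL0s[t] <- VL0
    lm_store[[t]] <- lm
    nm <- paste0("logVL_", t)
    if (nm %in% pm$par_names) start[nm] <- log(VL0)
    start[paste0("logVR_", t)] <- log(VR0)
  }
  for (ty in pm$r_types) {
    nm <- if (pm$equal_r && length(pm$r_types) > 1) "r_shared" else
      paste0("r_", ty)
    if (!(nm %in% pm$par_names)) next
    lf <- lm_store[[paste0(ty, ".F")]]
    lmm <- lm_store[[paste0(ty, ".M")]]
    common <- intersect(names(lf), names(lmm))
    r0 <- if (length(common) > 3) {
      cv <- cov(lf[common], lmm[common])
      max(min(cv / sqrt(VL0s[[paste0(ty, ".F")]] *
                          VL0s[[paste0(ty, ".M")]]), 0.9), -0.9)
    } else 0
    start[nm] <- atanh(r0)
  }
  start
}

# Builds the restricted log-likelihood closure on vial-level statistics.
.reml_likelihood_env <- function(g, pm, include_vial) {
  cell <- paste0(g$trait, ":", g$batch)
  cells <- sort(unique(cell))
  p <- length(cells)
  A_col <- match(cell, cells)
  line_ids <- unique(g$line_id)
  line_rows <- split(seq_len(nrow(g)), g$line_id)[line_ids]
  # pattern = the (trait, batch, n) composition of a line's vials; lines
  # sharing a pattern share the same covariance matrix and design rows
  pattern_key <- vapply(line_rows, function(rows) {
    paste(g$trait[rows], g$batch[rows], g$n[rows], collapse = "|")
  }, "")
  patterns <- split(seq_along(line_ids), pattern_key)
  N <- sum(g$n)
  const <- (N - p) * log(2 * pi)

  compute <- function(par, want_beta = FALSE) {
    est <- pm$unpack(par)
    VR_g <- est$VR[g$trait]
    tau <- (if (include_vial) est$VV[g$trait] else 0) + VR_g / g$n
    within <- sum((g$n - 1) * log(VR_g)) + sum(g$ss / VR_g)

    XtCX <- matrix(0, p, p)
    XtCy <- numeric(p)
    yCy <- 0
    logdet <- 0
    for (pat in patterns) {
      rows0 <- line_rows[[pat[1]]]
      k <- length(rows0)
      t0 <- g$trait[rows0]
      ty <- sub("\\..*$", "", t0[1])
      Gm <- matrix(0, k, k)
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          Gm[i, j] <- if (t0[i] == t0[j]) est$VL[[t0[i]]] else
            if (ty %in% names(est$cov)) est$cov[[ty]] else 0
        }
      }
      C <- Gm + diag(tau[rows0], k)
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      Ci <- chol2inv(ch)
      logdet <- logdet + length(pat) * 2 * sum(log(diag(ch)))
      Ap <- matrix(0, k, p)
      Ap[cbind(seq_len(k), A_col[rows0])] <- 1
      M <- vapply(pat, function(li) g$ybar[line_rows[[li]]], numeric(k))
      M <- matrix(M, nrow = k)
      CiM <- Ci %*% M
      XtCX <- XtCX + length(pat) * crossprod(Ap, Ci %*% Ap)
      XtCy <- XtCy + crossprod(Ap, rowSums(CiM))[, 1]
      yCy <- yCy + sum(M * CiM)
    }
    chX <- tryCatch(chol(XtCX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    beta <- backsolve(chX, forwardsolve(t(chX), XtCy))
    quad <- yCy - sum(beta * XtCy)
    logdet_X <- 2 * sum(log(diag(chX)))
    nll <- 0.5 * (logdet + within + quad + logdet_X + const)
    if (want_beta) {
      names(beta) <- cells
      list(nll = nll, beta = beta)
    } else nll
  }

  nll <- function(par) {
    v <- compute(par, want_beta = FALSE)
    if (is.null(v) || !is.finite(v)) 1e10 else v
  }
  beta_hat <- function(par) compute(par, want_beta = TRUE)$beta
  list(nll = nll, beta_hat = beta_hat)
}
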