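#' Experimental design of a hemiclone lifespan assay
#'
#' Describes the sampling design of a chromosome-substitution ("hemiclone")
#' lifespan experiment: a set of substitution lines per chromosome type, both
#' sexes assayed in replicate batches, one vial of flies per line x sex x
#' batch, and mortality scored on a fixed census interval.
#'
#' The defaults encode the study design this package targets: 40 X-lines and
#' 40 autosome-lines, two sexes, four batches, 50 flies per vial (so 200
#' focal flies per sex and line), and a 48-hour census.
#'
#' @param n_lines_per_type Number of substitution lines per chromosome type.
#' @param n_batches Number of replicate batches.
#' @param n_flies_per_vial Number of focal flies per vial.
#' @param census_interval Census interval in days (mortality is scored on
#'   this grid).
#' @param sexes Character vector of sexes, subset of `c("F", "M")`.
#' @param chromosome_types Character vector, subset of
#'   `c("autosome", "X")`.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_lines_per_type = 40L,
                          n_batches = 4L,
                          n_flies_per_vial = 50L,
                          census_interval = 2,
                          sexes = c("F", "M"),
                          chromosome_types = c("autosome", "X")) {
  stopifnot(
    n_lines_per_type >= 1, n_batches >= 1, n_flies_per_vial >= 1,
    census_interval > 0
  )
  sexes <- match.arg(sexes, c("F", "M"), several.ok = TRUE)
  chromosome_types <- match.arg(chromosome_types, c("autosome", "X"),
                                several.ok = TRUE)
  structure(
    list(
      n_lines_per_type = as.integer(n_lines_per_type),
      n_batches = as.integer(n_batches),
      n_flies_per_vial = as.integer(n_flies_per_vial),
      census_interval = census_interval,
      sexes = sexes,
      chromosome_types = chromosome_types
    ),
    class = "design_config"
  )
}

#' Generative parameters for Gaussian lifespan variation
#'
#' Holds the sex-specific grand means, batch effects, the 2x2 cross-sex line
#' (co)variance matrix G, and the vial and residual variances used by
#' [simulate_lifespans()]. `G[1,1]` is the female line variance `V_LF`,
#' `G[2,2]` the male `V_LM`, and the off-diagonal the cross-sex line
#' covariance `Cov_MF`; the intersexual genetic correlation is
#' `r_MF = Cov_MF / sqrt(V_LF * V_LM)`.
#'
#' @param grand_mean Named numeric, mean trait value per sex (days for
#'   lifespan), names `F` and `M`.
#' @param G 2x2 symmetric positive semidefinite cross-sex line covariance
#'   matrix (rows/cols ordered F, M).
#' @param V_V Named numeric, vial variance per sex (>= 0).
#' @param V_R Named numeric, residual variance per sex (> 0).
#' @param batch_effects Matrix (2 x n_batches, rows F then M) of batch
#'   deviations summing to zero within each sex, or `NULL` for no batch
#'   structure.
#' @return An object of class `genetic_params`.
#' @export
genetic_params <- function(grand_mean, G, V_V, V_R, batch_effects = NULL) {
  grand_mean <- .named_fm(grand_mean, "grand_mean")
  V_V <- .named_fm(V_V, "V_V")
  V_R <- .named_fm(V_R, "V_R")
  G <- as.matrix(G)
  stopifnot(identical(dim(G), c(2L, 2L)))
  if (abs(G[1, 2] - G[2, 1]) > 1e-8 * (1 + max(abs(G)))) {
    stop("G must be symmetric")
  }
  G[2, 1] <- G[1, 2]
  .check_psd(G, "G")
  if (any(V_V < 0)) stop("V_V must be >= 0")
  if (any(V_R < 0)) stop("V_R must be >= 0")
  if (!is.null(batch_effects)) {
    batch_effects <- as.matrix(batch_effects)
    if (nrow(batch_effects) != 2) {
      stop("batch_effects must have one row per sex (F then M)")
    }
    sums <- rowSums(batch_effects)
    if (any(abs(sums) > 1e-8)) {
      stop("batch effects must sum to zero within each sex")
    }
    rownames(batch_effects) <- c("F", "M")
  }
  dimnames(G) <- list(c("F", "M"), c("F", "M"))
  structure(
    list(grand_mean = grand_mean, G = G, V_V = V_V, V_R = V_R,
         batch_effects = batch_effects),
    class = "genetic_params"
  )
}

.named_fm <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- c(F = x, M = x) else names(x) <- c("F", "M")
  }
  if (!all(c("F", "M") %in% names(x))) {
    stop(sprintf("%s must be named with F and M", what))
  }
  x[c("F", "M")]
}

.check_psd <- function(M, name) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  tol <- -1e-8 * max(1, max(abs(ev)))
  if (any(ev < tol)) {
    stop(sprintf("%s is not positive semidefinite: smallest eigenvalue %.6g",
                 name, min(ev)))
  }
  invisible(ev)
}

#' Generative parameters for per-line Gompertz aging variation
#'
#' Parameters for simulating per-line demographic aging: within each sex,
#' each line receives an aging rate `beta` (per day) and a baseline log
#' mortality `log(alpha)`. Across lines, `beta` varies between the sexes
#' according to a 2x2 covariance matrix `G_beta` (on the beta-per-day scale),
#' and `log(alpha)` co-varies with `beta` within a sex with correlation
#' `rho_la_beta` (strongly negative in fly cohorts: high baseline mortality
#' accompanies slow aging).
#'
#' @param mean_beta Named numeric per sex, mean aging rate (1/day).
#' @param G_beta 2x2 cross-sex line covariance of beta (1/day^2).
#' @param mean_log_alpha Named numeric per sex, mean of `log(alpha)`.
#' @param sd_log_alpha Named numeric per sex, between-line SD of
#'   `log(alpha)`.
#' @param rho_la_beta Within-sex correlation between `log(alpha)` and `beta`
#'   across lines (default -0.9).
#' @return An object of class `aging_params`.
#' @export
aging_params <- function(mean_beta, G_beta, mean_log_alpha, sd_log_alpha,
                         rho_la_beta = -0.9) {
  mean_beta <- .named_fm(mean_beta, "mean_beta")
  mean_log_alpha <- .named_fm(mean_log_alpha, "mean_log_alpha")
  sd_log_alpha <- .named_fm(sd_log_alpha, "sd_log_alpha")
  G_beta <- as.matrix(G_beta)
  stopifnot(identical(dim(G_beta), c(2L, 2L)), abs(rho_la_beta) <= 1)
  .check_psd(G_beta, "G_beta")
  structure(
    list(mean_beta = mean_beta, G_beta = G_beta,
         mean_log_alpha = mean_log_alpha, sd_log_alpha = sd_log_alpha,
         rho_la_beta = rho_la_beta),
    class = "aging_params"
  )
}

#' Default lifespan parameters at the scale of the fly assay
#'
#' Convenience constructors returning [genetic_params()] objects at the
#' magnitudes typical of outbred *D. melanogaster* hemiclone assays:
#' female/male mean lifespans in the 50--68 day range, line variances of a
#' few to ~17 days^2, small vial variances, and residual variances of
#' 60--100 days^2. `fly_lifespan_params("autosome")` uses a cross-sex line
#' correlation of 0.50, `fly_lifespan_params("X")` a near-zero 0.06.
#'
#' @param chromosome_type `"autosome"` or `"X"`.
#' @param n_batches Number of batches for the default batch-effect matrix.
#' @return A `genetic_params` object.
#' @export
fly_lifespan_params <- function(chromosome_type = c("autosome", "X"),
                                n_batches = 4L) {
  chromosome_type <- match.arg(chromosome_type)
  be <- .default_batch_effects(n_batches)
  if (chromosome_type == "autosome") {
    V_L <- c(F = 15.00, M = 17.36)
    r <- 0.50
    genetic_params(
      grand_mean = c(F = 64.75, M = 50.03),
      G = .g_from_r(V_L, r),
      V_V = c(F = 4.78, M = 4.82),
      V_R = c(F = 73.72, M = 89.92),
      batch_effects = be
    )
  } else {
    V_L <- c(F = 2.28, M = 8.95)
    r <- 0.06
    genetic_params(
      grand_mean = c(F = 67.80, M = 51.36),
      G = .g_from_r(V_L, r),
      V_V = c(F = 5.96, M = 3.19),
      V_R = c(F = 60.95, M = 98.84),
      batch_effects = be
    )
  }
}

#' @rdname fly_lifespan_params
#' @export
fly_aging_params <- function(chromosome_type = c("autosome", "X")) {
  chromosome_type <- match.arg(chromosome_type)
  # means/variances on the per-day beta scale (x100 gives the reporting
  # scale); log(alpha) chosen so cohort mean lifespans land in 50-68 d
  if (chromosome_type == "autosome") {
    vb <- c(F = 6.97, M = 3.07) / 1e4
    r <- -0.12
    aging_params(
      mean_beta = c(F = 0.1729, M = 0.1241),
      G_beta = .g_from_r(vb, r),
      mean_log_alpha = c(F = -11.0, M = -8.3),
      sd_log_alpha = c(F = 0.45, M = 0.40)
    )
  } else {
    vb <- c(F = 1.01, M = 0.78) / 1e4
    r <- -0.42
    aging_params(
      mean_beta = c(F = 0.1477, M = 0.1095),
      G_beta = .g_from_r(vb, r),
      mean_log_alpha = c(F = -10.7, M = -7.6),
      sd_log_alpha = c(F = 0.40, M = 0.35)
    )
  }
}

.g_from_r <- function(V_L, r) {
  cov <- r * sqrt(V_L[["F"]] * V_L[["M"]])
  matrix(c(V_L[["F"]], cov, cov, V_L[["M"]]), 2, 2)
}

.default_batch_effects <- function(n_batches) {
  if (n_batches < 2) return(NULL)
  # a couple of days of batch-to-batch variation, sum-to-zero within sex
  base <- seq(-1, 1, length.out = n_batches)
  rbind(F = 1.2 * (base - mean(base)), M = 0.8 * (base - mean(base)))
}

#' @export
print.design_config <- function(x, ...) {
  cat("Hemiclone design:",
      x$n_lines_per_type, "lines per type x",
      length(x$chromosome_types), "type(s) x",
      length(x$sexes), "sex(es) x",
      x$n_batches, "batch(es) x",
      x$n_flies_per_vial, "flies/vial;",
      "census every", x$census_interval, "d\n")
  invisible(x)
}
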