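#' Convert line variance to additive genetic variance
#'
#' Hemiclone lines clone a haploid chromosome set, so the variance among
#' line means estimates half the additive genetic variance and
#' `V_A = 2 V_L` — except for X-lines measured in males, where the X is
#' hemizygous and `V_A = V_L`.
#'
#' @param V_L Line variance (vectorized; e.g. a posterior sample vector).
#' @param chromosome_type `"autosome"` or `"X"`.
#' @param sex `"F"` or `"M"`.
#' @return `V_A` on the same scale as `V_L`.
#' @export
additive_variance <- function(V_L, chromosome_type, sex) {
  chromosome_type <- match.arg(chromosome_type, c("autosome", "X"))
  sex <- match.arg(sex, c("F", "M"))
  if (any(V_L < 0)) stop("V_L must be >= 0")
  if (chromosome_type == "X" && sex == "M") V_L else 2 * V_L
}

#' Total phenotypic variance from components
#'
#' `V_P = V_L + V_V + V_R`; the vial component is omitted for aging fits
#' (pass `V_V = NULL`), where no vial variance is estimable.
#'
#' @param V_L,V_V,V_R Variance components (vectorized).
#' @return `V_P`.
#' @export
phenotypic_variance <- function(V_L, V_V = NULL, V_R) {
  if (any(V_L < 0) || any(V_R < 0) || (!is.null(V_V) && any(V_V < 0))) {
    stop("variance components must be >= 0")
  }
  if (is.null(V_V)) V_L + V_R else V_L + V_V + V_R
}

#' Coefficient of additive genetic variation
#'
#' `CV_A = sqrt(V_A) / mean`: a mean-standardized, scale-free measure of
#' additive variability that permits comparisons across sexes and traits
#' with different means.
#'
#' @param V_A Additive genetic variance (vectorized).
#' @param mean Trait mean (> 0).
#' @return `CV_A`.
#' @export
cv_a <- function(V_A, mean) {
  if (any(mean <= 0)) stop("mean must be > 0")
  if (any(V_A < 0)) stop("V_A must be >= 0")
  sqrt(V_A) / mean
}

#' Intersexual additive genetic correlation
#'
#' `r_MF = Cov_MF / sqrt(V_LF * V_LM)`. Samples with a zero line variance in
#' either sex leave the correlation undefined; those samples are returned as
#' `NA` with the count attached as attribute `"n_dropped"` (near-zero
#' denominators are what makes posterior ratios of these quantities heavily
#' skewed).
#'
#' @param Cov_MF Cross-sex line covariance (vectorized).
#' @param V_LF,V_LM Line variances per sex.
#' @return Correlation values in `[-1, 1]` for valid samples.
#' @export
rmf <- function(Cov_MF, V_LF, V_LM) {
  bad <- V_LF <= 0 | V_LM <= 0
  out <- rep(NA_real_, length(Cov_MF))
  out[!bad] <- Cov_MF[!bad] / sqrt(V_LF[!bad] * V_LM[!bad])
  if (all(bad)) stop("r_MF undefined: zero line variance in every sample")
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Summarize a posterior sample vector
#'
#' Default summary: mean, SD (the Bayesian SE) and the equal-tail 95%
#' credible interval. For heavily skewed quantities (ratios with near-zero
#' denominators), `skewed = TRUE` marks the median and interquartile range
#' as the primary location/spread summaries; both sets are always returned.
#'
#' @param samples Numeric vector (NA values dropped and counted).
#' @param skewed Flag the summary as skew-robust.
#' @param level Credible level (default 0.95).
#' @return List with `mean`, `sd`, `median`, `iqr` (length-2), `ci`
#'   (length-2), `n`, `n_dropped`, `skewed`.
#' @export
posterior_summary <- function(samples, skewed = FALSE, level = 0.95) {
  n_dropped <- sum(!is.finite(samples))
  x <- samples[is.finite(samples)]
  if (length(x) < 2) stop("at least 2 finite samples required")
  a <- (1 - level) / 2
  list(
    mean = mean(x), sd = sd(x), median = median(x),
    iqr = unname(quantile(x, c(0.25, 0.75))),
    ci = unname(quantile(x, c(a, 1 - a))),
    n = length(x), n_dropped = n_dropped, skewed = isTRUE(skewed)
  )
}

#' Posterior of a difference between two independent chains
#'
#' Quantities estimated in separate model runs (X-lines vs A-lines) have
#' independent posteriors; their difference is obtained by linking the
#' chains in random order and differencing the randomly paired samples.
#' The fraction of differences `>= 0` is reported as a one-sided posterior
#' probability.
#'
#' @param chain_a,chain_b Numeric sample vectors. If lengths differ, the
#'   shorter is resampled with replacement (flagged in the output).
#' @param seed Integer seed for the random pairing.
#' @return List with `differences`, `frac_ge0`, `summary`
#'   (a [posterior_summary()]), `resampled`.
#' @export
chain_difference <- function(chain_a, chain_b, seed = 1) {
  resampled <- FALSE
  set.seed(seed)
  n <- max(length(chain_a), length(chain_b))
  if (length(chain_a) < n) {
    chain_a <- sample(chain_a, n, replace = TRUE)
    resampled <- TRUE
  }
  if (length(chain_b) < n) {
    chain_b <- sample(chain_b, n, replace = TRUE)
    resampled <- TRUE
  }
  d <- chain_a - chain_b[sample.int(n)]
  list(
    differences = d,
    frac_ge0 = mean(d >= 0, na.rm = TRUE),
    summary = posterior_summary(d),
    resampled = resampled
  )
}

#' Posterior X-linkage proportion of additive variance
#'
#' Per sample, `V_A_X / (V_A_X + V_A_A)`, reported as a percentage.
#' Samples with a zero denominator are dropped and counted. The genomic
#' reference shares of the X chromosome (18.8% of euchromatin, 15.6% of
#' genes) are attached for comparison.
#'
#' @param V_A_X,V_A_A Paired sample vectors of X-linked and autosomal
#'   additive variance (link independent chains with [chain_difference()]'s
#'   pairing logic first, or supply randomly permuted vectors of equal
#'   length).
#' @return List with `samples` (percent), `summary`, `n_dropped`,
#'   `reference` (named percentages).
#' @export
x_linkage_proportion <- function(V_A_X, V_A_A) {
  stopifnot(length(V_A_X) == length(V_A_A))
  den <- V_A_X + V_A_A
  bad <- !is.finite(den) | den <= 0
  prop <- rep(NA_real_, length(den))
  prop[!bad] <- 100 * V_A_X[!bad] / den[!bad]
  list(
    samples = prop,
    summary = if (sum(!bad) >= 2) posterior_summary(prop),
    n_dropped = sum(bad),
    reference = c(euchromatin = 18.8, genes = 15.6)
  )
}

#' Male-to-female variance and evolvability ratios
#'
#' Per-sample male:female ratios of `V_A` and `CV_A` within each chromosome
#' type, and the ratio of X to autosomal CV ratios
#' `(CV_AMX / CV_AFX) / (CV_AMA / CV_AFA)` — the statistic that asks whether
#' males carry disproportionately more X-linked variability once the sexes'
#' overall variability difference is factored out (full dosage compensation
#' of a purely additive X predicts sqrt(2) = 1.41). Ratio posteriors are
#' heavily right-skewed when female variance samples approach zero, so the
#' skew-robust summary (median, IQR) is applied; zero-denominator samples
#' are dropped and counted, with a warning above 10%.
#'
#' @param samples_x,samples_a Data.frames (or lists) of paired posterior
#'   sample vectors with elements `VA_F`, `VA_M`, `CVA_F`, `CVA_M` for the
#'   X and autosome fits respectively.
#' @return List of components, each with `samples` and a skewed `summary`:
#'   `va_ratio_x`, `va_ratio_a`, `cva_ratio_x`, `cva_ratio_a`,
#'   `ratio_of_ratios`; drop counts in `n_dropped`.
#' @export
ratio_stats <- function(samples_x, samples_a) {
  ratio <- function(num, den) {
    bad <- !is.finite(den) | den <= 0 | !is.finite(num)
    r <- rep(NA_real_, length(num))
    r[!bad] <- num[!bad] / den[!bad]
    r
  }
  va_ratio_x <- ratio(samples_x$VA_M, samples_x$VA_F)
  va_ratio_a <- ratio(samples_a$VA_M, samples_a$VA_F)
  cva_ratio_x <- ratio(samples_x$CVA_M, samples_x$CVA_F)
  cva_ratio_a <- ratio(samples_a$CVA_M, samples_a$CVA_F)
  ror <- ratio(cva_ratio_x, cva_ratio_a)
  mk <- function(x) list(samples = x, summary = posterior_summary(x, skewed = TRUE))
  n_dropped <- vapply(list(va_ratio_x, va_ratio_a, cva_ratio_x,
                           cva_ratio_a, ror),
                      function(v) sum(!is.finite(v)), 0L)
  names(n_dropped) <- c("va_ratio_x", "va_ratio_a", "cva_ratio_x",
                        "cva_ratio_a", "ratio_of_ratios")
  frac <- max(n_dropped) / length(ror)
  if (frac > 0.10) {
    warning(sprintf("%.1f%% of ratio samples dropped (zero denominators)",
                    100 * frac))
  }
  list(
    va_ratio_x = mk(va_ratio_x), va_ratio_a = mk(va_ratio_a),
    cva_ratio_x = mk(cva_ratio_x), cva_ratio_a = mk(cva_ratio_a),
    ratio_of_ratios = mk(ror), n_dropped = n_dropped
  )
}

#' Derived quantitative-genetic statistics from a posterior chain
#'
#' Applies the conversion rules per retained MCMC sample — additive
#' variance ([additive_variance()]), phenotypic variance
#' ([phenotypic_variance()]), evolvability ([cv_a()], using the per-sample
#' posterior of the sex-specific global mean), and the intersexual
#' correlation ([rmf()]) — and summarizes the resulting sample vectors.
#' Derived statistics are never computed from plugged-in posterior means;
#' plug-in values from a Table-style summary are available separately via
#' [make_table1()].
#'
#' @param chain A `posterior_chain` from [run_gibbs()].
#' @param chromosome_type Chromosome type of the fit (taken from the chain
#'   metadata when available).
#' @return An object of class `derived_stats`: list with `samples`
#'   (data.frame of per-sample derived quantities), `summary` (list of
#'   [posterior_summary()] results), and metadata.
#' @export
derive_stats <- function(chain, chromosome_type = NULL) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (is.null(chromosome_type)) chromosome_type <- chain$line_type
  if (is.na(chromosome_type)) {
    stop("chromosome_type not recorded in chain; supply it explicitly")
  }
  S <- chain$samples
  mean_F <- S[, "trait_F"]
  mean_M <- S[, "trait_M"]
  V_L_F <- S[, "V_L_F"]; V_L_M <- S[, "V_L_M"]; Cov <- S[, "Cov_MF"]
  has_vial <- "V_V_F" %in% colnames(S)
  VA_F <- additive_variance(V_L_F, chromosome_type, "F")
  VA_M <- additive_variance(V_L_M, chromosome_type, "M")
  VP_F <- phenotypic_variance(V_L_F, if (has_vial) S[, "V_V_F"], S[, "V_R_F"])
  VP_M <- phenotypic_variance(V_L_M, if (has_vial) S[, "V_V_M"], S[, "V_R_M"])
  r_mf <- rmf(Cov, V_L_F, V_L_M)
  samples <- data.frame(
    mean_F = mean_F, mean_M = mean_M,
    V_L_F = V_L_F, V_L_M = V_L_M, Cov_MF = Cov,
    V_R_F = S[, "V_R_F"], V_R_M = S[, "V_R_M"],
    VA_F = VA_F, VA_M = VA_M, VP_F = VP_F, VP_M = VP_M,
    CVA_F = cv_a(VA_F, mean_F), CVA_M = cv_a(VA_M, mean_M),
    r_MF = as.numeric(r_mf)
  )
  if (has_vial) {
    samples$V_V_F <- S[, "V_V_F"]
    samples$V_V_M <- S[, "V_V_M"]
  }
  summ <- lapply(samples, posterior_summary)
  structure(
    list(samples = samples, summary = summ,
         chromosome_type = chromosome_type, trait = chain$trait,
         rmf_dropped = attr(r_mf, "n_dropped"),
         n_samples = nrow(samples)),
    class = "derived_stats"
  )
}

#' @export
print.derived_stats <- function(x, ...) {
  cat(sprintf("Derived statistics (%s, %s): %d posterior samples\n",
              x$trait, x$chromosome_type, x$n_samples))
  rows <- c("mean_F", "mean_M", "VA_F", "VA_M", "CVA_F", "CVA_M", "r_MF")
  for (r in rows) {
    s <- x$summary[[r]]
    cat(sprintf("  %-7s %8.3f +/- %.3f  [%.3f, %.3f]\n", r, s$mean, s$sd,
                s$ci[1], s$ci[2]))
  }
  invisible(x)
}

#' Cross-chromosome-type posterior contrasts
#'
#' Combines the derived statistics of separately fitted X-line and A-line
#' models: the female X-linkage proportion of additive variance, the
#' male:female ratios of `V_A` and `CV_A` within each type, the
#' ratio-of-ratios, and the difference of intersexual correlations
#' `r_MF_X - r_MF_A` (via random chain linking, since the fits are
#' independent).
#'
#' @param derived_x,derived_a `derived_stats` objects for X and autosomes.
#' @param seed Seed for the random chain pairings.
#' @return List with `x_linkage_F`, `x_linkage_M`, `ratios`
#'   (see [ratio_stats()]), and `rmf_difference`
#'   (a [chain_difference()] result).
#' @export
cross_type_stats <- function(derived_x, derived_a, seed = 1) {
  stopifnot(inherits(derived_x, "derived_stats"),
            inherits(derived_a, "derived_stats"))
  seeds <- split_seed(seed, 3)
  n <- min(derived_x$n_samples, derived_a$n_samples)
  set.seed(seeds[1])
  perm <- sample.int(n)
  sx <- derived_x$samples[seq_len(n), ]
  sa <- derived_a$samples[perm, ]
  xl_F <- x_linkage_proportion(sx$VA_F, sa$VA_F)
  xl_M <- x_linkage_proportion(sx$VA_M, sa$VA_M)
  ratios <- ratio_stats(sx, sa)
  rmf_diff <- chain_difference(derived_x$samples$r_MF,
                               derived_a$samples$r_MF, seed = seeds[2])
  list(x_linkage_F = xl_F, x_linkage_M = xl_M, ratios = ratios,
       rmf_difference = rmf_diff)
}
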