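#' Published reference estimates for the fly hemiclone assay
#'
#' Posterior-mean estimates (with Bayesian SEs and 95% credible bounds) of
#' the mean, line, vial, residual, phenotypic and additive variance
#' components and evolvability coefficients of lifespan (days) and aging
#' (beta x 100) from a large published chromosome-substitution assay of an
#' outbred *D. melanogaster* population (40 X-lines + 40 autosome-lines,
#' both sexes, four batches, 32,000 flies). Shipped as plain CSV; these
#' values serve as reference inputs — e.g. to parameterize simulations at
#' realistic magnitudes, or to verify the arithmetic conversion rules
#' ([additive_variance()], [phenotypic_variance()], [cv_a()]) against the
#' published numbers.
#'
#' @param trait Optional filter, `"lifespan"` or `"aging"`.
#' @return Data.frame with columns `trait`, `quantity` (`Mean`, `V_L`,
#'   `V_V`, `V_R`, `V_P`, `V_A`, `CV_A`), `chromosome_type`, `sex`,
#'   `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
reference_estimates <- function(trait = NULL) {
  path <- system.file("extdata", "reference_table1.csv", package = "hemivar")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(trait)) {
    trait <- match.arg(trait, c("lifespan", "aging"))
    df <- df[df$trait == trait, ]
  }
  df
}

#' Look up one reference estimate
#'
#' @param trait,quantity,chromosome_type,sex Selectors into
#'   [reference_estimates()].
#' @return The scalar `estimate`.
#' @export
reference_value <- function(trait, quantity, chromosome_type, sex) {
  df <- reference_estimates()
  hit <- df$trait == trait & df$quantity == quantity &
    df$chromosome_type == chromosome_type & df$sex == sex
  if (sum(hit) != 1) stop("no unique reference entry for that selector")
  df$estimate[hit]
}
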