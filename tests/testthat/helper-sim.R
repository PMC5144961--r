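# shared fixtures, built in code at load time

# small autosome-only design for quick model tests
small_design <- function(n_lines = 12, n_batches = 2, n_flies = 12,
                         types = "autosome", sexes = c("F", "M")) {
  design_config(n_lines_per_type = n_lines, n_batches = n_batches,
                n_flies_per_vial = n_flies, chromosome_types = types,
                sexes = sexes)
}

quick_records <- function(seed = 1, ...) {
  cfg <- small_design(...)
  simulate_lifespans(cfg, fly_lifespan_params("autosome",
                                              cfg$n_batches), seed = seed)
}

quick_chain_config <- function(seed = 1) {
  chain_config(iterations = 6000L, burn_in = 1000L, thin = 5L, seed = seed)
}

# closed-form ANOVA variance-component estimators for a balanced line x
# batch design with one vial per cell (single sex), batch treated as fixed:
# the expected-mean-square solution of the two-way decomposition, an
# independent oracle for REML on balanced data
anova_components <- function(records) {
  y <- records$lifespan
  line <- factor(records$line_id)
  batch <- factor(records$batch)
  vial <- factor(records$vial_id)
  L <- nlevels(line)
  B <- nlevels(batch)
  n <- length(y) / nlevels(vial)
  gm <- mean(y)
  lm_ <- tapply(y, line, mean)
  bm <- tapply(y, batch, mean)
  cm <- tapply(y, vial, mean)
  cell_line <- tapply(as.integer(line), vial, `[`, 1)
  cell_batch <- tapply(as.integer(batch), vial, `[`, 1)
  ss_line <- n * B * sum((lm_ - gm)^2)
  ss_inter <- n * sum((cm - lm_[cell_line] - bm[cell_batch] + gm)^2)
  ss_err <- sum((y - cm[vial])^2)
  ms_line <- ss_line / (L - 1)
  ms_inter <- ss_inter / ((L - 1) * (B - 1))
  ms_err <- ss_err / (L * B * (n - 1))
  c(V_L = (ms_line - ms_inter) / (n * B),
    V_V = (ms_inter - ms_err) / n,
    V_R = ms_err)
}
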