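#' Configuration for an end-to-end hemiclone analysis run
#'
#' Exactly one of `input` (a lifespan-records CSV readable by
#' [read_lifespans()]) or `sim` (a simulation specification: list with
#' `design` = [design_config()] and `params` = named list of
#' [genetic_params()]) must be supplied. Settings can also be read from a
#' YAML file via `pipeline_config_from_yaml()`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stochastic stage receives a child seed
#'   derived from it via [split_seed()].
#' @param input Path to a lifespan CSV, or `NULL`.
#' @param sim Simulation spec, or `NULL`.
#' @param outlier_threshold Mean-lifespan threshold in days for the vial
#'   screen.
#' @param skip_outliers Skip the outlier screen entirely.
#' @param chain A [chain_config()] (its seed field is overridden per chain).
#' @param n_chains Chains per model (>= 2 enables the Gelman-Rubin check).
#' @param census_interval Census interval used to bin lifespans into
#'   mortality schedules for the aging arm.
#' @param reml Also run unconstrained REML fits per line type.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input = NULL, sim = NULL,
                       outlier_threshold = 51, skip_outliers = FALSE,
                       chain = chain_config(), n_chains = 2L,
                       census_interval = 2, reml = FALSE) {
  if (is.null(input) == is.null(sim)) {
    stop("supply exactly one of `input` or `sim`")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), input = input,
         sim = sim, outlier_threshold = outlier_threshold,
         skip_outliers = isTRUE(skip_outliers), chain = chain,
         n_chains = as.integer(n_chains),
         census_interval = census_interval, reml = isTRUE(reml)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file mirroring the `run_config` fields (simulation
#'   parameters given as plain lists of the [design_config()] /
#'   [genetic_params()] arguments).
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    design <- do.call(design_config, y$sim$design)
    params <- lapply(y$sim$params, function(p) {
      genetic_params(
        grand_mean = unlist(p$grand_mean),
        G = matrix(unlist(p$G), 2, 2),
        V_V = unlist(p$V_V), V_R = unlist(p$V_R),
        batch_effects = if (!is.null(p$batch_effects)) {
          matrix(unlist(p$batch_effects), nrow = 2, byrow = TRUE)
        }
      )
    })
    sim <- list(design = design, params = params)
  }
  chain <- if (!is.null(y$chain)) do.call(chain_config, y$chain) else
    chain_config()
  run_config(
    out_dir = y$out_dir, seed = y$seed %||% 1L, input = y$input, sim = sim,
    outlier_threshold = y$outlier_threshold %||% 51,
    skip_outliers = y$skip_outliers %||% FALSE,
    chain = chain, n_chains = y$n_chains %||% 2L,
    census_interval = y$census_interval %||% 2,
    reml = y$reml %||% FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full variance-partitioning pipeline
#'
#' Orchestrates the analysis end to end: obtain lifespan records (simulate
#' or read), screen for outlier vials with the genetic-association check,
#' fit the multi-response lifespan model per chromosome type (`n_chains`
#' independent chains each), check convergence by Gelman-Rubin, bin the
#' records into per-vial mortality schedules and fit Gompertz models, fit
#' the two-step aging model on the per-vial aging rates, derive the
#' quantitative-genetic statistics and cross-type contrasts, and write a
#' Table-1-shaped CSV plus a JSON report. Every artifact is written under
#' `config$out_dir`; all child seeds are logged in the report, and
#' re-running with the same config reproduces all numbers.
#'
#' A stage failure aborts with the stage name; artifacts from earlier
#' stages persist. The aging arm degrades gracefully: if too few vials
#' yield converged Gompertz fits (e.g. degenerate zero-variance data), the
#' aging models are skipped and the reason recorded.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: list of all in-memory results
#'   plus `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(config$seed, 16)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- data -----------------------------------------------------------
  records <- stage("data", {
    if (!is.null(config$input)) {
      read_lifespans(config$input)
    } else {
      simulate_lifespans(config$sim$design, config$sim$params,
                         seed = seeds[1])
    }
  })
  paths$records <- file.path(config$out_dir, "lifespans.csv")
  write_lifespans(records, paths$records)

  ## -- outlier screen -------------------------------------------------
  screen <- NULL
  if (config$skip_outliers) {
    filtered <- records
  } else {
    screen <- stage("outliers", {
      outlier_screen(records, threshold = config$outlier_threshold)
    })
    filtered <- screen$records_filtered
    paths$filtered <- file.path(config$out_dir, "lifespans_filtered.csv")
    write_lifespans(filtered, paths$filtered)
  }

  types <- unique(filtered$chromosome_type)
  chain_seeds <- matrix(split_seed(seeds[2], 2 * config$n_chains * 2),
                        nrow = 2 * config$n_chains)

  ## -- lifespan models ------------------------------------------------
  lifespan_fits <- stage("lifespan_model", {
    out <- list()
    for (k in seq_along(types)) {
      ty <- types[k]
      dat <- filtered[filtered$chromosome_type == ty, ]
      chains <- lapply(seq_len(config$n_chains), function(i) {
        cc <- config$chain
        cc$seed <- chain_seeds[i, k]
        run_gibbs(dat, trait = "lifespan", config = cc)
      })
      gr <- if (length(chains) >= 2) gelman_rubin(chains) else NULL
      out[[ty]] <- list(chains = chains, gelman_rubin = gr)
      write.csv(chains[[1]]$samples,
                file.path(config$out_dir,
                          sprintf("chain_lifespan_%s.csv", ty)),
                row.names = FALSE)
    }
    out
  })

  ## -- Gompertz fits --------------------------------------------------
  gompertz <- stage("gompertz", {
    schedules <- records_to_schedules(filtered, config$census_interval)
    fits <- fit_gompertz_vials(schedules)
    meta <- vial_summaries(filtered)
    fits <- merge(fits, meta[, c("vial_id", "line_id", "chromosome_type",
                                 "sex", "batch")], by = "vial_id")
    fits
  })
  paths$gompertz <- file.path(config$out_dir, "gompertz_fits.csv")
  write.csv(gompertz, paths$gompertz, row.names = FALSE)

  ## -- aging models ---------------------------------------------------
  aging_fits <- NULL
  aging_skipped <- NULL
  ok <- gompertz[gompertz$converged & is.finite(gompertz$beta_x100), ]
  enough <- all(vapply(types, function(ty) {
    sub <- ok[ok$chromosome_type == ty, ]
    all(table(factor(sub$sex, levels = c("F", "M"))) >= 4) &&
      length(unique(sub$batch)) >= 2
  }, TRUE))
  if (!enough) {
    aging_skipped <- "too few converged Gompertz fits per type and sex"
  } else {
    aging_fits <- stage("aging_model", {
      out <- list()
      for (k in seq_along(types)) {
        ty <- types[k]
        dat <- ok[ok$chromosome_type == ty, ]
        chains <- lapply(seq_len(config$n_chains), function(i) {
          cc <- config$chain
          cc$seed <- chain_seeds[config$n_chains + i, k]
          run_gibbs(dat, trait = "aging", config = cc)
        })
        gr <- if (length(chains) >= 2) gelman_rubin(chains) else NULL
        out[[ty]] <- list(chains = chains, gelman_rubin = gr)
        write.csv(chains[[1]]$samples,
                  file.path(config$out_dir,
                            sprintf("chain_aging_%s.csv", ty)),
                  row.names = FALSE)
      }
      out
    })
  }

  ## -- REML (optional) ------------------------------------------------
  reml_fits <- NULL
  if (config$reml) {
    reml_fits <- stage("reml", {
      lapply(setNames(types, types), function(ty) {
        reml_fit(filtered[filtered$chromosome_type == ty, ],
                 trait = "lifespan")
      })
    })
  }

  ## -- derived statistics ---------------------------------------------
  derived <- stage("derive", {
    out <- list()
    for (ty in types) {
      out[[ty]] <- list(
        lifespan = derive_stats(lifespan_fits[[ty]]$chains[[1]]),
        aging = if (!is.null(aging_fits)) {
          derive_stats(aging_fits[[ty]]$chains[[1]])
        }
      )
    }
    cross <- NULL
    if (all(c("autosome", "X") %in% types)) {
      cross <- list(
        lifespan = cross_type_stats(out$X$lifespan, out$autosome$lifespan,
                                    seed = seeds[3]),
        aging = if (!is.null(aging_fits)) {
          cross_type_stats(out$X$aging, out$autosome$aging, seed = seeds[4])
        }
      )
    }
    list(per_type = out, cross = cross)
  })

  ## -- report ----------------------------------------------------------
  tab1 <- stage("table1", {
    make_table1(
      lifespan_A = derived$per_type$autosome$lifespan,
      lifespan_X = derived$per_type$X$lifespan,
      aging_A = derived$per_type$autosome$aging,
      aging_X = derived$per_type$X$aging
    )
  })
  paths$table1 <- file.path(config$out_dir, "table1.csv")
  write.csv(tab1, paths$table1, row.names = FALSE)

  gr_tab <- do.call(rbind, lapply(types, function(ty) {
    g <- lifespan_fits[[ty]]$gelman_rubin
    if (is.null(g)) return(NULL)
    cbind(model = paste0("lifespan_", ty), g)
  }))
  if (!is.null(gr_tab)) {
    paths$gelman_rubin <- file.path(config$out_dir, "gelman_rubin.csv")
    write.csv(gr_tab, paths$gelman_rubin, row.names = FALSE)
  }

  report <- list(
    seed = config$seed, child_seeds = as.integer(seeds),
    chain_seeds = as.integer(chain_seeds),
    n_records = nrow(records), n_filtered = nrow(filtered),
    outliers = if (!is.null(screen)) {
      list(flagged = screen$flagged,
           tests = lapply(screen$tests, function(t) {
             if (is.null(t)) NULL else t[c("t", "df", "p",
                                           "mean_difference")]
           }))
    },
    aging_skipped = aging_skipped,
    summary = lapply(derived$per_type, function(d) {
      lapply(d, function(ds) {
        if (is.null(ds)) return(NULL)
        lapply(ds$summary[c("VA_F", "VA_M", "CVA_F", "CVA_M", "r_MF")],
               function(s) s[c("mean", "sd", "median", "ci")])
      })
    })
  )
  paths$report <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  structure(
    list(records = records, filtered = filtered, screen = screen,
         lifespan = lifespan_fits, gompertz = gompertz, aging = aging_fits,
         reml = reml_fits, derived = derived, table1 = tab1,
         aging_skipped = aging_skipped, paths = paths, config = config),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$config$out_dir, "\n")
  cat(" ", nrow(x$records), "records,", nrow(x$filtered),
      "after outlier screen\n")
  if (!is.null(x$aging_skipped)) cat("  aging arm skipped:",
                                     x$aging_skipped, "\n")
  cat("  artifacts:", paste(basename(unlist(x$paths)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assemble a Table-1-shaped summary of the model fits
#'
#' Rows `Mean, V_L, V_V, V_R, V_P, V_A, CV_A` for the lifespan block and
#' `Mean, V_L, V_R, V_P, V_A, CV_A` for the aging block (no vial variance
#' is estimable for aging), columns for the four sex x chromosome-type
#' combinations. Entries are posterior means with the posterior SD as the
#' Bayesian SE (`estimate +/- SE`) plus the 95% credible bounds in
#' separate columns. Missing fits produce explicit empty cells.
#'
#' @param lifespan_A,lifespan_X,aging_A,aging_X `derived_stats` objects
#'   (aging entries may be `NULL`).
#' @return Data.frame in the table layout.
#' @export
make_table1 <- function(lifespan_A = NULL, lifespan_X = NULL,
                        aging_A = NULL, aging_X = NULL) {
  if (is.null(lifespan_A) && is.null(lifespan_X)) {
    stop("at least one lifespan fit is required")
  }
  col_specs <- list(
    `A-F` = list(d = "A", sex = "F"), `A-M` = list(d = "A", sex = "M"),
    `X-F` = list(d = "X", sex = "F"), `X-M` = list(d = "X", sex = "M")
  )
  get_stat <- function(ds, row, sex) {
    if (is.null(ds)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    key <- switch(row,
                  Mean = paste0("mean_", sex),
                  V_L = paste0("V_L_", sex),
                  V_V = paste0("V_V_", sex),
                  V_R = paste0("V_R_", sex),
                  V_P = paste0("VP_", sex),
                  V_A = paste0("VA_", sex),
                  CV_A = paste0("CVA_", sex))
    s <- ds$summary[[key]]
    if (is.null(s)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(s$mean, s$sd, s$ci[1], s$ci[2])
  }
  build_block <- function(block, dA, dX, rows) {
    out <- list()
    for (row in rows) {
      vals <- lapply(col_specs, function(cs) {
        ds <- if (cs$d == "A") dA else dX
        get_stat(ds, row, cs$sex)
      })
      entry <- data.frame(
        block = block, quantity = row, stringsAsFactors = FALSE
      )
      for (cn in names(vals)) {
        v <- vals[[cn]]
        entry[[paste0(cn, "_estimate")]] <- v[1]
        entry[[paste0(cn, "_se")]] <- v[2]
        entry[[paste0(cn, "_ci_lo")]] <- v[3]
        entry[[paste0(cn, "_ci_hi")]] <- v[4]
        entry[[cn]] <- ifelse(is.na(v[1]), "",
                              sprintf("%.2f ± %.2f", v[1], v[2]))
      }
      out[[row]] <- entry
    }
    do.call(rbind, out)
  }
  lifespan_rows <- c("Mean", "V_L", "V_V", "V_R", "V_P", "V_A", "CV_A")
  aging_rows <- c("Mean", "V_L", "V_R", "V_P", "V_A", "CV_A")
  tab <- build_block("lifespan", lifespan_A, lifespan_X, lifespan_rows)
  if (!is.null(aging_A) || !is.null(aging_X)) {
    tab <- rbind(tab, build_block("aging", aging_A, aging_X, aging_rows))
  }
  rownames(tab) <- NULL
  tab
}
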