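#' Per-vial summaries of lifespan records
#'
#' @param records Lifespan records.
#' @return Data.frame with one row per vial: `vial_id`, `line_id`,
#'   `chromosome_type`, `sex`, `batch`, `mean_lifespan`, `n_flies`.
#' @export
vial_summaries <- function(records) {
  idx <- split(seq_len(nrow(records)), records$vial_id)
  first <- vapply(idx, `[`, 0L, 1)
  out <- data.frame(
    vial_id = names(idx),
    line_id = records$line_id[first],
    chromosome_type = if ("chromosome_type" %in% names(records)) {
      records$chromosome_type[first]
    } else NA_character_,
    sex = records$sex[first],
    batch = records$batch[first],
    mean_lifespan = vapply(idx, function(i) mean(records$lifespan[i]), 0),
    n_flies = lengths(idx),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$vial_id), ]
  rownames(out) <- NULL
  out
}

#' Flag outlier vials by a mean-lifespan threshold
#'
#' Vials of the filtered sex whose mean lifespan falls strictly below the
#' threshold are flagged (ties at the threshold are kept). The rule targets
#' the bimodal pattern produced by extrinsic insults (e.g. disease) hitting
#' whole vials: a small low mode well separated from the main distribution.
#' A bimodality diagnostic is reported alongside — histogram counts of the
#' per-vial means, and the separation (in days) between the highest flagged
#' vial and the lowest unflagged vial: a separation of several days marks a
#' genuinely detached low mode rather than a tail of the main distribution.
#'
#' @param summaries Vial summaries from [vial_summaries()].
#' @param threshold Mean-lifespan threshold in days (default 51).
#' @param sex_filter Sex whose vials are screened (default `"F"`).
#' @param min_gap Separation (days) above which the low mode is reported as
#'   detached (default twice the 2-day census interval).
#' @param binwidth Histogram bin width in days.
#' @return List with `flagged` (character vial ids, sorted) and
#'   `diagnostic` (`breaks`, `counts`, `separation`, `gap_present`).
#' @export
detect_outlier_vials <- function(summaries, threshold = 51,
                                 sex_filter = "F", min_gap = 4,
                                 binwidth = 2) {
  stopifnot(nrow(summaries) > 0)
  s <- summaries[summaries$sex == sex_filter, ]
  low <- s$mean_lifespan < threshold
  flagged <- sort(s$vial_id[low])
  rng <- range(s$mean_lifespan)
  breaks <- seq(floor(rng[1]), ceiling(rng[2]) + binwidth, by = binwidth)
  counts <- tabulate(findInterval(s$mean_lifespan, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  separation <- if (any(low) && any(!low)) {
    min(s$mean_lifespan[!low]) - max(s$mean_lifespan[low])
  } else NA_real_
  list(
    flagged = flagged,
    diagnostic = list(breaks = breaks, counts = counts,
                      separation = separation,
                      gap_present = isTRUE(separation >= min_gap))
  )
}

#' One-tailed test for a genetic component to outlier vials
#'
#' If low-scoring vials reflected genotype rather than extrinsic insult,
#' lines that produced such a vial should be short-lived in their remaining
#' vials too. The check: remove the flagged vials, compute each line's mean
#' lifespan from what remains, and run a pooled-variance two-sample t-test
#' (df = n1 + n2 - 2) of whether lines *without* a flagged vial outlive
#' lines *with* one, one-tailed in that direction.
#'
#' @param line_means_without,line_means_with Numeric vectors of line mean
#'   lifespans for the two groups (each of length >= 2).
#' @return List with `t`, `df`, `p` (one-tailed), `mean_difference`
#'   (without - with).
#' @export
line_group_test <- function(line_means_without, line_means_with) {
  if (length(line_means_without) < 2 || length(line_means_with) < 2) {
    stop("each group must contain at least 2 lines")
  }
  tt <- t.test(line_means_without, line_means_with, var.equal = TRUE,
               alternative = "greater")
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    mean_difference = mean(line_means_without) - mean(line_means_with)
  )
}

#' Run the outlier-vial screen and genetic-association check
#'
#' Convenience wrapper: flags outlier vials, recomputes target-sex line
#' means with the flagged vials excluded, and runs [line_group_test()]
#' within each chromosome type and over all lines pooled. Lines all of
#' whose vials were flagged contribute no post-removal mean and are
#' excluded with a note.
#'
#' @param records Lifespan records.
#' @param threshold,sex_filter Passed to [detect_outlier_vials()].
#' @return List with `flagged`, `diagnostic`, `tests` (named list of
#'   [line_group_test()] results, possibly `NULL` when a group is too
#'   small), and `records_filtered` (records minus flagged vials).
#' @export
outlier_screen <- function(records, threshold = 51, sex_filter = "F") {
  vs <- vial_summaries(records)
  det <- detect_outlier_vials(vs, threshold = threshold,
                              sex_filter = sex_filter)
  keep <- !(records$vial_id %in% det$flagged)
  filtered <- records[keep, ]
  sexed <- filtered[filtered$sex == sex_filter, ]
  line_means <- tapply(sexed$lifespan, sexed$line_id, mean)
  lines_with <- unique(vs$line_id[vs$vial_id %in% det$flagged])
  line_type <- vs$chromosome_type[match(names(line_means), vs$line_id)]

  run_test <- function(sel) {
    lm_sel <- line_means[sel]
    with <- lm_sel[names(lm_sel) %in% lines_with]
    without <- lm_sel[!(names(lm_sel) %in% lines_with)]
    if (length(with) < 2 || length(without) < 2) return(NULL)
    line_group_test(without, with)
  }
  tests <- list(
    X = run_test(!is.na(line_type) & line_type == "X"),
    autosome = run_test(!is.na(line_type) & line_type == "autosome"),
    all = run_test(rep(TRUE, length(line_means)))
  )
  list(flagged = det$flagged, diagnostic = det$diagnostic, tests = tests,
       records_filtered = filtered)
}
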