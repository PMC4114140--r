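#' Early/late replication-domain statistics of one profile
#'
#' Pools the autosomal log2 ratios of a cell by replication-domain class
#' (early: timing < 0.5; late otherwise) and quantifies the S-phase
#' oscillation: in an S-phase cell, early-replicating regions show high
#' log2 ratios and late-replicating regions low ones, while the wave is
#' absent in G0/G1 cells. Computes the early/late pool means, a two-sided
#' rank-sum test of the two pools, the Spearman correlation `r_t` of the
#' log2 ratio with replication earliness (`-timing`), and the linear slope
#' of the log2 ratio on GC content (early domains are GC-rich, so S-phase
#' profiles trend upward in GC).
#'
#' @param profile A `ratio_profile` carrying `timing` (and optionally `gc`)
#'   columns, as produced from a probe map with a timing track.
#' @param min_pool Minimum probes required in each pool (default 20);
#'   smaller pools give an `indeterminate` result with a reason.
#' @return A list of class `phase_call`: `cell_id`, `early_mean`,
#'   `late_mean`, `statistic`, `p`, `r_t`, `gc_slope`, `call` (`NA` until
#'   [classify_phase()]), `reason`.
#' @export
early_late_statistics <- function(profile, min_pool = 20) {
  if (!"timing" %in% names(profile))
    stop("profile carries no replication-timing annotation")
  aut <- profile[is_autosome(profile$chrom), , drop = FALSE]
  early <- aut$log2ratio[aut$timing < 0.5]
  late <- aut$log2ratio[aut$timing >= 0.5]
  res <- list(cell_id = attr(profile, "cell_id"),
              early_mean = mean(early), late_mean = mean(late),
              statistic = NA_real_, p = NA_real_, r_t = NA_real_,
              gc_slope = NA_real_, call = NA_character_, reason = NA_character_)
  class(res) <- "phase_call"
  if (length(early) < min_pool || length(late) < min_pool) {
    res$call <- "indeterminate"
    res$reason <- sprintf("pool too small (early %d, late %d, need %d)",
                          length(early), length(late), min_pool)
    return(res)
  }
  ht <- rank_sum_test(early, late, mode = "normal")
  res$statistic <- unname(ht$statistic)
  res$p <- ht$p.value
  r_t <- suppressWarnings(cor(aut$log2ratio, -aut$timing,
                              method = "spearman"))
  res$r_t <- if (is.na(r_t)) 0 else r_t   # constant profile: no oscillation
  if ("gc" %in% names(aut))
    res$gc_slope <- unname(coef(lm(aut$log2ratio ~ aut$gc))[2])
  res
}

#' Attribute a cell-cycle phase from oscillation statistics
#'
#' A profile is called `S-like` when the early/late separation is
#' significant (`p < alpha`), the timing correlation exceeds `min_r`, and
#' the early pool mean exceeds the late pool mean; `G-like` when the
#' separation is non-significant and the timing correlation negligible;
#' `indeterminate` otherwise (including significant oscillation in the
#' wrong direction). G2/M is not distinguished from G0/G1: neither shows
#' replication oscillation.
#'
#' @param result A `phase_call` from [early_late_statistics()].
#' @param alpha Significance level for the rank-sum test (default 0.01).
#' @param min_r Minimum timing correlation for an S call (default 0.2).
#' @return The `phase_call` with `call` filled in.
#' @export
classify_phase <- function(result, alpha = 0.01, min_r = 0.2) {
  stopifnot(inherits(result, "phase_call"))
  if (!is.na(result$call) && result$call == "indeterminate") return(result)
  osc_up <- result$early_mean > result$late_mean
  result$call <-
    if (result$p < alpha && result$r_t > min_r && osc_up) "S-like"
    else if (result$p >= alpha && abs(result$r_t) <= min_r) "G-like"
    else "indeterminate"
  result
}

#' @export
print.phase_call <- function(x, ...) {
  cat(sprintf(paste0("<phase_call> %s: %s (early %.3f vs late %.3f, ",
                     "p = %.3g, r_t = %.3f)\n"),
              x$cell_id, if (is.na(x$call)) "unclassified" else x$call,
              x$early_mean, x$late_mean, x$p, x$r_t))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Full phase attribution for one profile
#'
#' @inheritParams early_late_statistics
#' @inheritParams classify_phase
#' @return A classified `phase_call`.
#' @export
phase_call <- function(profile, alpha = 0.01, min_r = 0.2, min_pool = 20)
  classify_phase(early_late_statistics(profile, min_pool), alpha, min_r)

#' Phase-call concordance against known phases
#'
#' Cross-tabulates true phases (S versus non-S, i.e. G0/G1 and G2/M
#' jointly) against attributed calls, and reports the concordance
#' fraction: the proportion of cells whose call matches their true phase
#' class (S to `S-like`, non-S to `G-like`).
#'
#' @param calls `data.frame` with columns `true_phase` (`"S"`, `"G0G1"`,
#'   `"G2M"`) and `call` (`"S-like"`, `"G-like"`, `"indeterminate"`).
#' @return A 2x3 contingency table with attributes `concordance` (fraction)
#'   and `n`. An empty input yields an empty (all-zero) table.
#' @export
concordance_report <- function(calls) {
  true <- factor(ifelse(calls$true_phase == "S", "S", "G"),
                 levels = c("S", "G"))
  called <- factor(calls$call,
                   levels = c("S-like", "G-like", "indeterminate"))
  tab <- table(true = true, called = called)
  n <- sum(tab)
  conc <- if (n == 0) NA_real_ else (tab["S", "S-like"] + tab["G", "G-like"]) / n
  structure(tab, concordance = conc, n = n)
}
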