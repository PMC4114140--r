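# Region sizes (Mb) of the five regions of interest.
.region_mb <- c(dup7p = 25.16, dup9p = 24, del18p = 8, dup18p = 9.3,
                del20p = 1.7)

#' Packaged per-cell probe counts for the three carrier cell lines
#'
#' The published per-cell counts of region-of-interest probes passing the
#' +/-0.3 log2-ratio threshold: 26 S-phase and 22 G0/G1-phase single cells
#' over five regions (40, 42, 28, 30 and 8 probes). Two no-call annotations
#' are shipped: `nocall` carries the flags as tallied by the published
#' summary (part B) and named in the running text (complete failure to
#' detect in S_1_9, S_2_1's 18p deletion, S_3_3's 18p duplication, and
#' G0/G1_3_1's 18p duplication), while `printed_flag` additionally carries
#' the per-cell superscripts printed on S_1_5 and S_1_6, which the summary
#' row nevertheless counts as underestimations. [derive_table1B()] uses
#' `nocall`.
#'
#' @return A `data.frame` of class `table1_fixture` with columns `cell_id`,
#'   `phase`, `cell_line`, `region`, `k`, `n`, `nocall`, `printed_flag`,
#'   `size_mb`, validated against its row/column invariants (a corrupt file
#'   is an error).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1a.tsv", package = "sccgh",
                      mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$nocall <- as.logical(df$nocall)
  df$printed_flag <- as.logical(df$printed_flag)
  df$size_mb <- unname(.region_mb[df$region])
  # integrity checks: cell counts, per-region probe totals, count checksums
  cells <- unique(df[, c("cell_id", "phase")])
  ok <- nrow(df) == 79 &&
    sum(cells$phase == "S") == 26 && sum(cells$phase == "G0G1") == 22 &&
    all(tapply(df$n, df$region, function(x) length(unique(x))) == 1) &&
    identical(sort(unique(df$n)), c(8L, 28L, 30L, 40L, 42L)) &&
    sum(df$k) == 1354L && sum(df$n) == 2434L && all(df$k <= df$n)
  if (!ok) stop("table1 fixture corrupt: checksum failed")
  structure(df, class = c("table1_fixture", "data.frame"))
}

#' Build a per-(cell, region) detection table from cohort calls
#'
#' Arranges region calls (from [evaluate_region()]) into the layout of the
#' packaged fixture: one row per cell and region of interest with the
#' passing count `k`, the region probe total `n`, and the region class.
#'
#' @param region_calls `data.frame` of stacked region calls with columns
#'   `cell_id`, `phase`, `region`, `k`, `n`, `klass` (extra columns are
#'   kept).
#' @return The table ordered by phase, cell and region, with `size_mb`
#'   attached where the region is one of the five regions of interest.
#' @export
build_table1A <- function(region_calls) {
  need <- c("cell_id", "phase", "region", "k", "n", "klass")
  stopifnot(all(need %in% names(region_calls)))
  df <- as.data.frame(region_calls)
  df$size_mb <- unname(.region_mb[df$region])
  df <- df[order(df$phase, df$cell_id, df$region), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Region class from a fixture-style row: an external no-call flag overrides,
# otherwise the at-least-half rule applies.
.row_klass <- function(k, n, nocall = NULL) {
  klass <- ifelse(k >= ceiling(n / 2), "accurate", "underestimated")
  if (!is.null(nocall)) klass[nocall] <- "nocall"
  klass
}

#' Per-phase false-negative summary (part-B table)
#'
#' Aggregates a per-(cell, region) detection table to cell level
#' ([classify_cell()] semantics: a cell is a false negative when any of its
#' constitutive regions is not accurately detected; a no-call region
#' dominates underestimation) and tallies per phase.
#'
#' @param table1a A table from [build_table1A()] or [table1_fixture()].
#'   Rows need `klass`, or `k`/`n` (plus optional `nocall`) from which the
#'   class is derived.
#' @return A `data.frame` of class `table1b`, one row per phase:
#'   `underestimation`, `no_call`, `false_negative`, `accurate`, `total`.
#' @export
derive_table1B <- function(table1a) {
  df <- as.data.frame(table1a)
  if (!"klass" %in% names(df))
    df$klass <- .row_klass(df$k, df$n,
                           if ("nocall" %in% names(df)) df$nocall else NULL)
  cells <- split(df, paste(df$phase, df$cell_id))
  cc <- do.call(rbind, lapply(cells, classify_cell))
  phases <- intersect(c("S", "G0G1", "G2M"), unique(cc$phase))
  out <- do.call(rbind, lapply(phases, function(ph) {
    sub <- cc[cc$phase == ph, , drop = FALSE]
    data.frame(phase = ph,
               underestimation = sum(sub$fn_subtype == "underestimation"),
               no_call = sum(sub$fn_subtype == "no_call"),
               false_negative = sum(sub$cell_class == "false_negative"),
               accurate = sum(sub$cell_class == "accurate"),
               total = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("table1b", "data.frame"))
}

#' @export
print.table1b <- function(x, ...) {
  cat("Per-phase false-negative summary\n")
  cat(sprintf("  %-5s underestimation %2d | no call %2d | false negative %2d / %2d cells\n",
              x$phase, x$underestimation, x$no_call, x$false_negative,
              x$total), sep = "")
  invisible(x)
}

#' Rank-sum comparison of probe-passing rates between phases
#'
#' Compares S- against G0/G1-phase cells on one observation per
#' (cell, region): by default the fraction `k / n` of region probes passing
#' the detection threshold (regions differ in probe totals, so fractions
#' put them on one scale; raw counts are available behind
#' `observations = "count"`). Optionally restricted to regions larger than
#' `size_filter_mb`.
#'
#' @param table1a A per-(cell, region) table with `phase`, `k`, `n` and
#'   (when filtering) `size_mb`.
#' @param size_filter_mb Keep only regions strictly larger than this size
#'   in Mb (`NULL`: all regions).
#' @param observations `"fraction"` (default) or `"count"`.
#' @param mode Passed to [rank_sum_test()] (default `"normal"`).
#' @return An `htest` from [rank_sum_test()] (S group first).
#' @export
phase_comparison <- function(table1a, size_filter_mb = NULL,
                             observations = c("fraction", "count"),
                             mode = "normal") {
  observations <- match.arg(observations)
  df <- as.data.frame(table1a)
  if (!is.null(size_filter_mb)) {
    stopifnot("size_mb" %in% names(df))
    df <- df[!is.na(df$size_mb) & df$size_mb > size_filter_mb, , drop = FALSE]
  }
  obs <- if (observations == "fraction") df$k / df$n else df$k
  ht <- rank_sum_test(obs[df$phase == "S"], obs[df$phase != "S"], mode = mode)
  ht$data.name <- sprintf("passing %ss, S vs G0/G1%s", observations,
                          if (is.null(size_filter_mb)) ""
                          else sprintf(" (regions > %g Mb)", size_filter_mb))
  ht
}

#' Reproduce the published detection summary and statistics
#'
#' From the packaged fixture alone: derives the per-phase false-negative
#' summary, the Pearson chi-square on accurate-versus-false-negative by
#' phase, and the rank-sum comparisons of probe-passing fractions over all
#' regions and over the regions larger than 9 Mb.
#'
#' @return A list of class `table1_report`: `table1b`, `chi2_table`,
#'   `p_chisq`, `p_all`, `p_large`, with a print method that prints the two
#'   summary rows and the three p-values.
#' @export
reproduce_table1 <- function() {
  fx <- table1_fixture()
  t1b <- derive_table1B(fx)
  m <- matrix(c(t1b$accurate[t1b$phase == "S"],
                t1b$false_negative[t1b$phase == "S"],
                t1b$accurate[t1b$phase == "G0G1"],
                t1b$false_negative[t1b$phase == "G0G1"]),
              nrow = 2, byrow = TRUE,
              dimnames = list(phase = c("S", "G0G1"),
                              call = c("accurate", "false_negative")))
  structure(list(table1b = t1b, chi2_table = m,
                 p_chisq = chi_square_2x2(m)$p.value,
                 p_all = phase_comparison(fx)$p.value,
                 p_large = phase_comparison(fx, size_filter_mb = 9)$p.value),
            class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  print(x$table1b)
  cat(sprintf("Chi-square (accurate vs false negative x phase): p = %.3f\n",
              x$p_chisq))
  cat(sprintf("Mann-Whitney, passing fractions, all regions:    p = %.3f\n",
              x$p_all))
  cat(sprintf("Mann-Whitney, passing fractions, regions > 9 Mb: p = %.3f\n",
              x$p_large))
  invisible(x)
}
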