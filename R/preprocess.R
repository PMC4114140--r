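#' Signal-to-noise filtering of array probes
#'
#' Probes with a signal-to-noise ratio strictly below `min_snr` are excluded
#' from the profile (a probe at exactly the threshold is retained). Excluded
#' probes are recorded, with their reason, in the `excluded` attribute of the
#' result.
#'
#' @param table An `intensity_table`.
#' @param min_snr Threshold (default 2).
#' @return The filtered `intensity_table`. Filtering away every probe is an
#'   error ("empty profile").
#' @export
snr_filter <- function(table, min_snr = 2) {
  stopifnot(inherits(table, "intensity_table"), is.numeric(min_snr))
  drop <- table$snr < min_snr
  if (all(drop)) stop("empty profile: all probes fall below SNR ", min_snr)
  excl <- data.frame(probe_id = table$probe_id[drop],
                     reason = sprintf("snr %.3g < %.3g", table$snr[drop],
                                      min_snr),
                     stringsAsFactors = FALSE)
  out <- table[!drop, , drop = FALSE]
  attrs <- attributes(table)
  for (a in c("cell_id", "phase", "s", "label")) attr(out, a) <- attrs[[a]]
  attr(out, "excluded") <- excl
  out
}

#' Normalize two-channel intensities to log2 ratios
#'
#' Implements ratio-of-means normalization: intensities are scaled so that
#' the ratio of the channel means equals 1, i.e.
#' `L_p = log2(test_p / ref_p) - log2(mean(test) / mean(ref))`. By default
#' the normalization means run over autosomal probes only, because the
#' reference DNA is of the opposite sex and the X/Y constitutive offset
#' would otherwise bias the scale; set `autosomes_only = FALSE` to
#' normalize over all probes.
#'
#' @param table A (filtered) `intensity_table`; both channels must be
#'   positive at every retained probe.
#' @param autosomes_only Logical; restrict the normalization means to
#'   autosomes (default `TRUE`).
#' @return A `data.frame` of class `ratio_profile` with per-probe `log2ratio`
#'   plus probe annotation; cell metadata and the exclusion record travel in
#'   attributes. After normalization `mean(test') / mean(ref') == 1` exactly
#'   over the probes entering the normalization.
#' @export
normalize_ratios <- function(table, autosomes_only = TRUE) {
  stopifnot(inherits(table, "intensity_table"))
  bad <- table$test <= 0 | table$ref <= 0
  if (any(bad))
    stop("nonpositive intensity at probe ",
         paste(table$probe_id[which(bad)[seq_len(min(3, sum(bad)))]],
               collapse = ", "))
  norm_sel <- if (autosomes_only && any(is_autosome(table$chrom)))
    is_autosome(table$chrom) else rep(TRUE, nrow(table))
  scale <- mean(table$test[norm_sel]) / mean(table$ref[norm_sel])
  L <- log2(table$test / table$ref) - log2(scale)
  out <- data.frame(probe_id = table$probe_id, chrom = table$chrom,
                    start = table$start, end = table$end,
                    log2ratio = L, stringsAsFactors = FALSE)
  for (col in c("gc", "timing", "domain", "early"))
    if (col %in% names(table)) out[[col]] <- table[[col]]
  structure(out, class = c("ratio_profile", "data.frame"),
            cell_id = attr(table, "cell_id"), phase = attr(table, "phase"),
            s = attr(table, "s"), label = attr(table, "label"),
            excluded = attr(table, "excluded"),
            norm_scale = scale)
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("<ratio_profile> cell %s (%s), %d probes, median L = %.3f\n",
              attr(x, "cell_id"), attr(x, "phase"), nrow(x),
              stats::median(x$log2ratio)))
  invisible(x)
}

#' Preprocess one simulated cell to a normalized ratio profile
#'
#' Convenience wrapper: [snr_filter()] then [normalize_ratios()].
#'
#' @param entry One element of an `sc_cohort` (or an `intensity_table`).
#' @param min_snr SNR threshold.
#' @param autosomes_only Passed to [normalize_ratios()].
#' @return A `ratio_profile`.
#' @export
cell_profile <- function(entry, min_snr = 2, autosomes_only = TRUE) {
  tab <- if (inherits(entry, "intensity_table")) entry else entry$intensities
  normalize_ratios(snr_filter(tab, min_snr), autosomes_only)
}
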