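#' Segmental-imbalance detection rule configuration
#'
#' The caller declares an imbalance reliably detected in its full length
#' when the log2 ratio passes +`threshold` (gain) or -`threshold` (loss)
#' for at least `min_fraction` of the probes in the region of interest,
#' with at least `min_run` consecutive probes passing. A region where the
#' passing count falls at or below `nocall_fraction` of its probes is a
#' complete no-call rather than an underestimation.
#'
#' @param threshold Log2-ratio threshold (default 0.3).
#' @param min_fraction Fraction of region probes required (default 1/2).
#' @param min_run Required run of consecutive passing probes (default 10);
#'   for regions with fewer probes than `min_run` the requirement drops to
#'   the region's probe count and the region is flagged below reliable
#'   resolution.
#' @param nocall_fraction No-call cutoff fraction (default 1/4); must be
#'   below `min_fraction`.
#' @param strict Logical; compare strictly (`L > threshold`) as by default,
#'   or inclusively (`L >= threshold`).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold = 0.3, min_fraction = 0.5,
                             min_run = 10L, nocall_fraction = 0.25,
                             strict = TRUE) {
  stopifnot(threshold > 0, min_fraction > 0, min_fraction <= 1,
            nocall_fraction > 0, nocall_fraction < min_fraction,
            min_run >= 1)
  structure(list(threshold = threshold, min_fraction = min_fraction,
                 min_run = as.integer(min_run),
                 nocall_fraction = nocall_fraction, strict = strict),
            class = "detection_config")
}

#' Per-probe gain/loss/neutral calls
#'
#' @param profile A `ratio_profile` (normalized).
#' @param config A [detection_config()]; only its threshold and strictness
#'   are used.
#' @return Character vector (`"gain"`, `"loss"`, `"neutral"`), one per probe.
#' @export
probe_calls <- function(profile, config = detection_config()) {
  L <- profile$log2ratio
  th <- config$threshold
  if (config$strict)
    ifelse(L > th, "gain", ifelse(L < -th, "loss", "neutral"))
  else
    ifelse(L >= th, "gain", ifelse(L <= -th, "loss", "neutral"))
}

#' Longest run of TRUE values
#'
#' @param x Logical vector.
#' @return Length of the longest stretch of consecutive `TRUE`s (0 for none).
#' @export
longest_run <- function(x) {
  x <- as.logical(x)
  if (length(x) == 0 || !any(x, na.rm = TRUE)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values], 0L)
}

#' Evaluate the detection rule on one region of one cell
#'
#' Counts the region probes whose call matches the region direction,
#' measures the longest consecutive passing run, and classifies the region:
#' `accurate` when at least `ceiling(n * min_fraction)` probes pass,
#' `nocall` when at most `floor(n * nocall_fraction)` pass (or when an
#' externally supplied no-call flag overrides the rule), otherwise
#' `underestimated`. `reliable` additionally requires the consecutive-run
#' criterion (`min(min_run, n)`).
#'
#' @param profile A `ratio_profile`.
#' @param region A [region()]; its `direction` is the expected imbalance.
#' @param config A [detection_config()].
#' @param nocall_flag Optional logical overriding the rule-based no-call
#'   (used when reproducing externally curated calls); `NA` (default)
#'   applies the rule.
#' @return One-row `data.frame` of class `region_call`: `cell_id`, `phase`,
#'   `region`, `k`, `n`, `longest_run`, `reliable`, `below_resolution`,
#'   `klass`.
#' @export
evaluate_region <- function(profile, region, config = detection_config(),
                            nocall_flag = NA) {
  stopifnot(inherits(region, "cgh_region"))
  mid <- (profile$start + profile$end) / 2
  sel <- profile$chrom == region$chrom &
    mid >= region$start & mid <= region$end
  n <- sum(sel)
  if (n == 0) stop("region '", region$name, "' contains no retained probe")
  sub <- profile[sel, , drop = FALSE]
  sub <- sub[order(sub$start), , drop = FALSE]
  pass <- probe_calls(sub, config) == region$direction
  k <- sum(pass)
  run <- longest_run(pass)
  below <- n < config$min_run
  reliable <- k >= ceiling(n * config$min_fraction) &&
    run >= min(config$min_run, n)
  nocall <- if (is.na(nocall_flag)) k <= floor(n * config$nocall_fraction)
            else isTRUE(nocall_flag)
  klass <- if (nocall) "nocall"
           else if (k >= ceiling(n * config$min_fraction)) "accurate"
           else "underestimated"
  structure(data.frame(cell_id = attr(profile, "cell_id"),
                       phase = attr(profile, "phase"),
                       region = region$name, k = k, n = n,
                       longest_run = run, reliable = reliable,
                       below_resolution = below, klass = klass,
                       stringsAsFactors = FALSE),
            class = c("region_call", "data.frame"))
}

#' Classify a cell from its region calls
#'
#' A cell is `accurate` when every constitutive region is accurately
#' detected; otherwise it is a `false_negative`, subtyped `no_call` when at
#' least one region is a complete no-call (no-call dominates
#' underestimation) and `underestimation` otherwise.
#'
#' @param region_calls `data.frame` of region calls for one cell (rows from
#'   [evaluate_region()], or any frame with a `klass` column).
#' @return One-row `data.frame`: `cell_id`, `phase`, `cell_class`,
#'   `fn_subtype`.
#' @export
classify_cell <- function(region_calls) {
  stopifnot(nrow(region_calls) >= 1, "klass" %in% names(region_calls))
  fn <- any(region_calls$klass != "accurate")
  subtype <- if (!fn) "none"
             else if (any(region_calls$klass == "nocall")) "no_call"
             else "underestimation"
  data.frame(
    cell_id = if ("cell_id" %in% names(region_calls))
      region_calls$cell_id[1] else NA_character_,
    phase = if ("phase" %in% names(region_calls))
      region_calls$phase[1] else NA_character_,
    cell_class = if (fn) "false_negative" else "accurate",
    fn_subtype = subtype, stringsAsFactors = FALSE)
}

#' Count probes falsely indicating an imbalance in a non-carrier cell
#'
#' For specificity assessment: in a cell whose karyotype does not carry the
#' region's aberration, counts the probes inside the region whose log2
#' ratio nevertheless passes the detection threshold in the stated
#' direction.
#'
#' @param profile A `ratio_profile` of a non-carrier cell.
#' @param region A [region()].
#' @param config A [detection_config()].
#' @return Integer count of falsely passing probes.
#' @export
false_positive_probe_count <- function(profile, region,
                                       config = detection_config()) {
  mid <- (profile$start + profile$end) / 2
  sel <- profile$chrom == region$chrom &
    mid >= region$start & mid <= region$end
  if (!any(sel)) return(0L)
  sum(probe_calls(profile[sel, , drop = FALSE], config) == region$direction)
}
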