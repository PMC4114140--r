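#' Configuration for synthetic BAC probe-map generation
#'
#' Parameters controlling [generate_probe_map()]. The layout emulates a
#' PGD-style BAC array: probes tile all chromosomes at roughly uniform
#' density, with extra probes in the subtelomeric and pericentromeric bands
#' (the terminal fraction of each chromosome arm).
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp. Defaults to
#'   rounded human chromosome sizes (22 autosomes plus X and Y).
#' @param n_probes Total number of probes to place across the genome.
#' @param enrichment Density multiplier for the terminal bands relative to
#'   the chromosome-arm interior (>= 1).
#' @param terminal_frac Fraction of each arm counted as terminal band
#'   (default 0.1, i.e. the outer 10 percent of each arm at both its
#'   telomeric and centromeric end).
#' @param centromere_frac Position of the nominal centromere as a fraction of
#'   chromosome length (arms are not modelled from real cytobands).
#' @param probe_width Nominal BAC clone length in bp; individual probes are
#'   shrunk where needed so that probes never overlap.
#' @param min_spacing Smallest tolerated mean probe spacing in bp; a probe
#'   count that would force spacing below this is an error.
#' @param gc_mean,gc_sd Mean and spread of the per-probe GC fraction. GC is
#'   re-drawn with replication-timing coupling by [generate_timing_track()].
#' @return A list of class `map_config`.
#' @seealso [generate_probe_map()]
#' @export
map_config <- function(chrom_lengths = .default_chrom_lengths,
                       n_probes = 3000,
                       enrichment = 3,
                       terminal_frac = 0.1,
                       centromere_frac = 0.4,
                       probe_width = 150e3,
                       min_spacing = 2e3,
                       gc_mean = 0.45,
                       gc_sd = 0.07) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0), n_probes >= length(chrom_lengths),
            enrichment >= 1, terminal_frac > 0, terminal_frac < 0.5,
            centromere_frac > 0, centromere_frac < 1,
            probe_width > 0, min_spacing > 0, gc_sd >= 0)
  structure(list(chrom_lengths = chrom_lengths, n_probes = n_probes,
                 enrichment = enrichment, terminal_frac = terminal_frac,
                 centromere_frac = centromere_frac, probe_width = probe_width,
                 min_spacing = min_spacing, gc_mean = gc_mean, gc_sd = gc_sd),
            class = "map_config")
}

# Piecewise-constant placement density along one chromosome.
# Breaks delimit [0, L]; weight `enrichment` applies inside terminal bands of
# each arm (telomeric and pericentromeric side), 1 elsewhere.
.chrom_density <- function(L, cfg) {
  cen <- cfg$centromere_frac * L
  tf <- cfg$terminal_frac
  p_len <- cen
  q_len <- L - cen
  enriched <- rbind(
    c(0, tf * p_len),                 # p subtelomere
    c(cen - tf * p_len, cen),         # p pericentromere
    c(cen, cen + tf * q_len),         # q pericentromere
    c(L - tf * q_len, L)              # q subtelomere
  )
  breaks <- sort(unique(c(0, as.vector(enriched), L)))
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  w <- vapply(mids, function(m)
    if (any(m > enriched[, 1] & m < enriched[, 2])) cfg$enrichment else 1,
    numeric(1))
  list(breaks = breaks, weight = w)
}

# Deterministic quantile placement of n midpoints under a piecewise density,
# with a small bounded jitter that cannot create overlaps.
.place_midpoints <- function(n, dens, jitter_u) {
  seg_len <- diff(dens$breaks)
  mass <- seg_len * dens$weight
  cdf <- c(0, cumsum(mass)) / sum(mass)
  q <- (seq_len(n) - 0.5) / n
  seg <- findInterval(q, cdf, rightmost.closed = TRUE)
  seg[seg > length(seg_len)] <- length(seg_len)
  frac <- (q - cdf[seg]) / (cdf[seg + 1] - cdf[seg])
  mid <- dens$breaks[seg] + frac * seg_len[seg]
  if (n > 1) {
    gap <- min(diff(mid))
    mid <- mid + (jitter_u - 0.5) * 0.5 * gap
  }
  sort(mid)
}

#' Generate a synthetic BAC probe map
#'
#' Places `n_probes` non-overlapping probes over the configured genome.
#' Probes are allocated to chromosomes in proportion to enrichment-weighted
#' length and placed by inverse-CDF quantiles of a piecewise-constant density
#' so that terminal (subtelomeric/pericentromeric) bands reach `enrichment`
#' times the interior probe density. Placement is deterministic for a fixed
#' seed.
#'
#' @param config A [map_config()] list.
#' @param seed Integer seed; the same seed always yields the same map.
#' @return A `data.frame` of class `probe_map` with columns `probe_id`,
#'   `chrom`, `start`, `end` (1-based, closed intervals), `gc`. Probes are
#'   sorted by chromosome then start and never overlap. Add replication
#'   timing with [generate_timing_track()].
#' @examples
#' pm <- generate_probe_map(map_config(n_probes = 500), seed = 1)
#' nrow(pm)
#' @export
generate_probe_map <- function(config = map_config(), seed = 1) {
  stopifnot(inherits(config, "map_config"))
  set.seed(seed)
  lens <- config$chrom_lengths
  eff <- lens * (1 + (config$enrichment - 1) * 2 * config$terminal_frac)
  # largest-remainder apportionment of the probe total
  raw <- config$n_probes * eff / sum(eff)
  n_c <- floor(raw)
  rem <- config$n_probes - sum(n_c)
  if (rem > 0) {
    bump <- order(raw - n_c, decreasing = TRUE)[seq_len(rem)]
    n_c[bump] <- n_c[bump] + 1
  }
  if (any(n_c > 0 & lens / pmax(n_c, 1) < config$min_spacing))
    stop("probe count incompatible with non-overlapping placement: ",
         "mean spacing below ", config$min_spacing, " bp on ",
         paste(names(lens)[lens / pmax(n_c, 1) < config$min_spacing],
               collapse = ", "))
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    ni <- n_c[i]
    if (ni == 0) next
    dens <- .chrom_density(lens[i], config)
    mid <- .place_midpoints(ni, dens, runif(ni))
    half <- pmin(config$probe_width / 2,
                 0.4 * c(Inf, diff(mid)), 0.4 * c(diff(mid), Inf))
    half <- pmax(half, 0.5)
    start <- pmax(1, round(mid - half))
    end <- pmin(lens[i], round(mid + half))
    end <- pmax(end, start)
    gc <- pmin(0.8, pmax(0.2, rnorm(ni, config$gc_mean, config$gc_sd)))
    out[[i]] <- data.frame(
      probe_id = sprintf("BAC_%s_%04d", sub("^chr", "", names(lens)[i]),
                         seq_len(ni)),
      chrom = names(lens)[i], start = start, end = end, gc = gc,
      stringsAsFactors = FALSE)
  }
  pm <- do.call(rbind, out)
  rownames(pm) <- NULL
  structure(pm, class = c("probe_map", "data.frame"),
            chrom_lengths = lens, config = config)
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("<probe_map> %d probes on %d chromosomes%s\n",
              nrow(x), length(unique(x$chrom)),
              if ("timing" %in% names(x)) ", with replication timing" else ""))
  print.data.frame(head(as.data.frame(x), 4), ...)
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

probe_midpoint <- function(map) (map$start + map$end) / 2

#' Probes falling in a genomic region
#'
#' Membership is by probe midpoint within the closed interval
#' `[start, end]` of the region, so a BAC clone straddling a region boundary
#' is assigned to exactly one side.
#'
#' @param probe_map A `probe_map`.
#' @param region A region as returned by [region()] (or one of
#'   [paper_regions()]).
#' @return The rows of `probe_map` in the region, in genomic order.
#'   A region containing no probe is an error: every region of interest must
#'   be queryable.
#' @export
probes_in_region <- function(probe_map, region) {
  stopifnot(inherits(region, "cgh_region"))
  if (!region$chrom %in% probe_map$chrom)
    stop("chromosome ", region$chrom, " absent from probe map")
  mid <- probe_midpoint(probe_map)
  sel <- probe_map$chrom == region$chrom &
    mid >= region$start & mid <= region$end
  if (!any(sel))
    stop("region '", region$name, "' contains no probe of the active map")
  probe_map[sel, , drop = FALSE]
}

#' Write / read a probe map as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `probe_id`, `gc`, and when present
#' `timing`, `domain`, `early`. Lines starting with `#` are ignored on read.
#' Reading back a written map restores all fields.
#'
#' @param map A `probe_map`.
#' @param path File path.
#' @return `read_probe_map()` returns a `probe_map`;
#'   `write_probe_map()` returns `path` invisibly.
#' @export
write_probe_map <- function(map, path) {
  cols <- intersect(c("chrom", "start", "end", "probe_id", "gc",
                      "timing", "domain", "early"), names(map))
  df <- as.data.frame(map)[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic BAC probe map", con)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "probe_id", "gc")
  if (!all(need %in% names(df)))
    stop("probe map file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  front <- c("probe_id", "chrom", "start", "end", "gc")
  df <- df[, c(front, setdiff(names(df), front))]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if ("early" %in% names(df)) df$early <- as.logical(df$early)
  structure(df, class = c("probe_map", "data.frame"))
}
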