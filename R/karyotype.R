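#' Define a genomic region of interest
#'
#' Coordinates are 1-based closed intervals (cytogenetics convention);
#' probe membership is decided by probe midpoint (see [probes_in_region()]).
#'
#' @param name Region label.
#' @param chrom Chromosome name (matching the probe map).
#' @param start,end Interval in bp, `start <= end`.
#' @param direction `"gain"` or `"loss"` — the direction in which the
#'   region's imbalance is expected to deviate.
#' @return A list of class `cgh_region` with a `size_mb` field.
#' @export
region <- function(name, chrom, start, end, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(start), is.numeric(end), start >= 1, start <= end)
  structure(list(name = name, chrom = chrom, start = start, end = end,
                 direction = direction,
                 size_mb = (end - start + 1) / 1e6),
            class = "cgh_region")
}

#' @export
print.cgh_region <- function(x, ...) {
  cat(sprintf("<region> %s: %s:%,.0f-%,.0f (%.2f Mb, %s)\n",
              x$name, x$chrom, x$start, x$end, x$size_mb, x$direction))
  invisible(x)
}

#' The five regions of interest of the three carrier cell lines
#'
#' The regions carried by the three studied cell lines: a 25.16 Mb
#' interstitial duplication of 7p (p14.3-p21.3), the 24 Mb 9p duplication
#' and 8 Mb 18p deletion of an unbalanced t(9;18), and the 9.3 Mb 18p
#' duplication and 1.7 Mb 20p deletion of an unbalanced t(18;20).
#' Terminal imbalances are placed at the p-terminus; the interstitial 7p
#' duplication at approximate p21.3-p14.3 coordinates. Sizes are exact.
#'
#' @return A named list of five [region()] objects: `dup7p`, `dup9p`,
#'   `del18p`, `dup18p`, `del20p`.
#' @export
paper_regions <- function() {
  list(
    dup7p  = region("dup7p",  "chr7",  8840001, 34000000, "gain"),
    dup9p  = region("dup9p",  "chr9",  1, 24000000, "gain"),
    del18p = region("del18p", "chr18", 1, 8000000,  "loss"),
    dup18p = region("dup18p", "chr18", 1, 9300000,  "gain"),
    del20p = region("del20p", "chr20", 1, 1700000,  "loss")
  )
}

#' Define a karyotype preset
#'
#' A karyotype is the constitutive copy-number state of a cell line:
#' copy number 2 on autosomes except inside the listed aberrations
#' (duplications `cn = 3`, deletions `cn = 1`), plus the sex-chromosome
#' complement.
#'
#' @param name Preset label.
#' @param sex `"XX"` or `"XY"`.
#' @param aberrations List of `list(region = <cgh_region>, cn = <1 or 3>)`.
#'   Aberration intervals must not overlap.
#' @return A list of class `karyotype_preset`.
#' @export
karyotype_preset <- function(name, sex = c("XX", "XY"), aberrations = list()) {
  sex <- match.arg(sex)
  for (ab in aberrations) {
    stopifnot(inherits(ab$region, "cgh_region"), ab$cn %in% c(1L, 3L))
    if ((ab$cn == 3) != (ab$region$direction == "gain"))
      stop("aberration copy number inconsistent with region direction: ",
           ab$region$name)
  }
  if (length(aberrations) > 1) {
    for (i in seq_along(aberrations)[-1]) for (j in seq_len(i - 1)) {
      a <- aberrations[[i]]$region; b <- aberrations[[j]]$region
      if (a$chrom == b$chrom && a$start <= b$end && b$start <= a$end)
        stop("aberration intervals overlap: ", a$name, ", ", b$name)
    }
  }
  structure(list(name = name, sex = sex, aberrations = aberrations),
            class = "karyotype_preset")
}

#' @export
print.karyotype_preset <- function(x, ...) {
  cat(sprintf("<karyotype_preset> %s (%s), %d aberration(s)\n",
              x$name, x$sex, length(x$aberrations)))
  for (ab in x$aberrations)
    cat(sprintf("  %s %s:%d-%d cn=%d (%.2f Mb)\n", ab$region$name,
                ab$region$chrom, ab$region$start, ab$region$end, ab$cn,
                ab$region$size_mb))
  invisible(x)
}

#' Karyotype presets of the three studied carrier cell lines
#'
#' @return A list of three [karyotype_preset()] objects:
#' \describe{
#'   \item{dup7p}{46,XX with a 25.16 Mb interstitial duplication of
#'     7p14.3-p21.3 (cn 3).}
#'   \item{der18_t9_18}{46,XX,der(18)t(9;18): 24 Mb duplication of 9p (cn 3)
#'     and 8 Mb deletion of 18p (cn 1).}
#'   \item{der20_t18_20}{46,XY,der(20)t(18;20): 9.3 Mb duplication of 18p
#'     (cn 3) and 1.7 Mb deletion of 20p (cn 1).}
#' }
#' @export
paper_presets <- function() {
  rg <- paper_regions()
  list(
    dup7p = karyotype_preset("dup7p", "XX",
      list(list(region = rg$dup7p, cn = 3L))),
    der18_t9_18 = karyotype_preset("der18_t9_18", "XX",
      list(list(region = rg$dup9p, cn = 3L),
           list(region = rg$del18p, cn = 1L))),
    der20_t18_20 = karyotype_preset("der20_t18_20", "XY",
      list(list(region = rg$dup18p, cn = 3L),
           list(region = rg$del20p, cn = 1L)))
  )
}

# Probe counts of the five regions of interest on the matched array layout.
.paper_region_probes <- c(dup7p = 40L, dup9p = 42L, del18p = 28L,
                          dup18p = 30L, del20p = 8L)

#' Probe map matched to the reported array layout
#'
#' Generates a synthetic probe map and then pins the probe content of the
#' five regions of interest to the reported clone counts (40 over the
#' 25.16 Mb dup7p, 42 over dup9p, 28 over del18p, 30 over dup18p and 8 over
#' the 1.7 Mb del20p) by replacing the probes inside each region with the
#' exact number of evenly spaced probes. Everything else follows
#' [generate_probe_map()]. The total array size of the real platform is not
#' public; only these five counts are constrained.
#'
#' @param config A [map_config()]; the default 3000-probe layout.
#' @param timing A [timing_config()] for the attached replication track.
#' @param seed Integer seed.
#' @return A `probe_map` with a replication-timing track, satisfying
#'   `nrow(probes_in_region(map, r)) == <reported count>` for the five
#'   regions.
#' @export
paper_probe_map <- function(config = map_config(), timing = timing_config(),
                            seed = 1) {
  pm <- generate_probe_map(config, seed = seed)
  regs <- paper_regions()
  # del18p is nested in dup18p (different cell lines, same arm): pin the
  # wider dup18p to 30 probes with its first 28 inside the 8 Mb del18p.
  pin <- function(pm, reg, k, inner = NULL, k_inner = NULL) {
    mid <- probe_midpoint(pm)
    drop <- pm$chrom == reg$chrom & mid >= reg$start & mid <= reg$end
    pm <- pm[!drop, , drop = FALSE]
    if (is.null(inner)) {
      mids <- reg$start + (seq_len(k) - 0.5) / k * (reg$end - reg$start)
    } else {
      m1 <- inner$start + (seq_len(k_inner) - 0.5) / k_inner *
        (inner$end - inner$start)
      rest <- k - k_inner
      m2 <- inner$end + (seq_len(rest) - 0.5) / rest * (reg$end - inner$end)
      mids <- c(m1, m2)
    }
    half <- pmax(0.5, pmin(75e3, 0.4 * c(Inf, diff(mids)),
                           0.4 * c(diff(mids), Inf)))
    new <- data.frame(
      probe_id = sprintf("BAC_%s_R%02d", sub("^chr", "", reg$chrom),
                         seq_along(mids)),
      chrom = reg$chrom, start = round(mids - half), end = round(mids + half),
      gc = rep(attr(pm, "config")$gc_mean, length(mids)),
      stringsAsFactors = FALSE)
    out <- rbind(as.data.frame(pm), new)
    out <- out[order(match(out$chrom, names(attr(pm, "chrom_lengths"))),
                     out$start), ]
    rownames(out) <- NULL
    structure(out, class = class(pm), chrom_lengths = attr(pm, "chrom_lengths"),
              config = attr(pm, "config"))
  }
  pm <- pin(pm, regs$dup7p, 40L)
  pm <- pin(pm, regs$dup9p, 42L)
  pm <- pin(pm, regs$dup18p, 30L, inner = regs$del18p, k_inner = 28L)
  pm <- pin(pm, regs$del20p, 8L)
  generate_timing_track(pm, timing, seed = seed)
}

#' Constitutive copy number of every probe under a karyotype
#'
#' Autosomes carry 2 copies outside aberrations; X and Y follow the preset
#' sex; aberration copy numbers apply to probes whose midpoint lies in the
#' aberration interval.
#'
#' @param probe_map A `probe_map`.
#' @param preset A [karyotype_preset()].
#' @return Integer vector of per-probe copy numbers.
#' @export
constitutive_copies <- function(probe_map, preset) {
  stopifnot(inherits(preset, "karyotype_preset"))
  cn <- ifelse(is_autosome(probe_map$chrom), 2L,
               ifelse(probe_map$chrom == "chrX",
                      if (preset$sex == "XX") 2L else 1L,
                      if (preset$sex == "XY") 1L else 0L))
  mid <- probe_midpoint(probe_map)
  for (ab in preset$aberrations) {
    r <- ab$region
    sel <- probe_map$chrom == r$chrom & mid >= r$start & mid <= r$end
    cn[sel] <- ab$cn
  }
  as.integer(cn)
}

#' Write / read a karyotype preset as a YAML config file
#'
#' @param preset A [karyotype_preset()].
#' @param path File path.
#' @return `read_karyotype()` returns a `karyotype_preset`;
#'   `write_karyotype()` returns `path` invisibly.
#' @export
write_karyotype <- function(preset, path) {
  lst <- list(name = preset$name, sex = preset$sex,
              aberrations = lapply(preset$aberrations, function(ab)
                list(name = ab$region$name, chrom = ab$region$chrom,
                     start = ab$region$start, end = ab$region$end,
                     direction = ab$region$direction, cn = ab$cn)))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_karyotype
#' @export
read_karyotype <- function(path) {
  lst <- yaml::read_yaml(path)
  karyotype_preset(lst$name, lst$sex,
    lapply(lst$aberrations, function(ab)
      list(region = region(ab$name, ab$chrom, ab$start, ab$end, ab$direction),
           cn = as.integer(ab$cn))))
}
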