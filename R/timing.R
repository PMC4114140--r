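#' Configuration for replication-timing track generation
#'
#' @param mean_domain_mb Mean replication-domain length in Mb (default 1).
#' @param domain_bounds_mb Lower/upper bounds on domain length in Mb; drawn
#'   lengths are truncated to this interval.
#' @param jitter_sd Within-domain timing jitter scale. Jitter is drawn
#'   uniformly on `+/- 1.5 * jitter_sd`, so two probes of one domain can
#'   never differ by more than `3 * jitter_sd`.
#' @param rho Target correlation between GC fraction and replication
#'   earliness (`cor(gc, -timing)`); early domains are GC-rich for
#'   positive `rho`.
#' @param timing_range Range of domain-level timing values inside `[0, 1]`.
#' @return A list of class `timing_config`.
#' @export
timing_config <- function(mean_domain_mb = 1,
                          domain_bounds_mb = c(0.3, 3),
                          jitter_sd = 0.02,
                          rho = 0.6,
                          timing_range = c(0.02, 0.98)) {
  stopifnot(mean_domain_mb > 0, length(domain_bounds_mb) == 2,
            domain_bounds_mb[1] > 0, diff(domain_bounds_mb) > 0,
            jitter_sd >= 0, abs(rho) <= 1,
            timing_range[1] >= 0, timing_range[2] <= 1,
            diff(timing_range) > 0)
  structure(list(mean_domain_mb = mean_domain_mb,
                 domain_bounds_mb = domain_bounds_mb,
                 jitter_sd = jitter_sd, rho = rho,
                 timing_range = timing_range),
            class = "timing_config")
}

#' Add a replication-timing track to a probe map
#'
#' Segments each chromosome into replication domains (lengths exponential
#' with the configured mean, truncated to the configured bounds), assigns
#' each domain a timing level `t` in `[0, 1]` (0 = earliest replicating,
#' 1 = latest) with bounded within-domain jitter, labels domains early
#' (`t < 0.5`) or late, and re-draws the per-probe GC fraction so that
#' `cor(gc, -timing)` matches the coupling `rho` (a Gaussian construction:
#' GC is a `rho`-weighted mix of standardized earliness and independent
#' noise, rescaled to a realistic GC range).
#'
#' @param probe_map A `probe_map` from [generate_probe_map()].
#' @param config A [timing_config()].
#' @param seed Integer seed.
#' @return The probe map with columns `timing`, `domain` (integer id,
#'   genome-wide), `early` (logical), and GC re-drawn with timing coupling.
#' @examples
#' pm <- generate_probe_map(map_config(n_probes = 600), seed = 1)
#' pm <- generate_timing_track(pm, timing_config(), seed = 1)
#' cor(pm$gc, -pm$timing)
#' @export
generate_timing_track <- function(probe_map, config = timing_config(),
                                  seed = 1) {
  stopifnot(inherits(probe_map, "probe_map"), inherits(config, "timing_config"))
  set.seed(seed + 1L)
  mid <- probe_midpoint(probe_map)
  chroms <- unique(probe_map$chrom)
  lo <- config$domain_bounds_mb[1] * 1e6
  hi <- config$domain_bounds_mb[2] * 1e6
  timing <- numeric(nrow(probe_map))
  domain <- integer(nrow(probe_map))
  next_id <- 1L
  for (ch in chroms) {
    sel <- probe_map$chrom == ch
    L <- max(probe_map$end[sel])
    lens <- numeric(0)
    while (sum(lens) < L)
      lens <- c(lens, pmin(hi, pmax(lo, rexp(16, 1 / (config$mean_domain_mb * 1e6)))))
    bk <- c(0, cumsum(lens))
    d <- findInterval(mid[sel], bk, rightmost.closed = TRUE)
    nd <- max(d)
    level <- runif(nd, config$timing_range[1], config$timing_range[2])
    jit <- (runif(sum(sel)) - 0.5) * 3 * config$jitter_sd
    t_p <- pmin(1, pmax(0, level[d] + jit))
    timing[sel] <- t_p
    domain[sel] <- next_id + d - 1L
    next_id <- next_id + nd
  }
  probe_map$timing <- timing
  probe_map$domain <- domain
  probe_map$early <- timing < 0.5
  # GC coupled to earliness through a Gaussian mix; linear rescaling leaves
  # the correlation at rho (up to rare clamping)
  z_t <- as.numeric(scale(-timing))
  rho <- config$rho
  eps <- rnorm(nrow(probe_map))
  z <- rho * z_t + sqrt(1 - rho^2) * eps
  cfg <- attr(probe_map, "config")
  gc_mean <- if (is.null(cfg)) 0.45 else cfg$gc_mean
  gc_sd <- if (is.null(cfg)) 0.07 else cfg$gc_sd
  probe_map$gc <- pmin(0.95, pmax(0.05, gc_mean + gc_sd * z))
  attr(probe_map, "timing_config") <- config
  probe_map
}
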