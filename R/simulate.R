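#' Stochastic origin-firing model
#'
#' In S phase each locus is replicated once its origins have fired; firing
#' is stochastic around the locus' characteristic replication time. The
#' probability that a locus with timing `t` has been replicated in a cell at
#' S-phase progression `s` is `link((s - t) / tau)`: exactly 1/2 at `s = t`,
#' approaching a deterministic replication schedule as `tau -> 0`.
#'
#' @param tau Firing-stochasticity scale (> 0, dimensionless; a locus
#'   transitions from mostly unreplicated to mostly replicated over roughly
#'   `4 * tau` of S-phase progression).
#' @param link Monotone link; only `"logistic"` is built in.
#' @return A list of class `replication_model`.
#' @export
replication_model <- function(tau = 0.05, link = "logistic") {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("tau must be a single positive number")
  link <- match.arg(link, "logistic")
  structure(list(tau = tau, link = link), class = "replication_model")
}

#' Probability that a locus is replicated
#'
#' @param s S-phase progression fraction in `[0, 1]`.
#' @param t Locus replication timing in `[0, 1]` (0 = earliest).
#' @param model A [replication_model()].
#' @return Probability in `[0, 1]`; vectorized over `s` and `t`.
#' @examples
#' replication_probability(0.5, 0.3, replication_model(tau = 0.1)) # plogis(2)
#' @export
replication_probability <- function(s, t, model = replication_model()) {
  stopifnot(inherits(model, "replication_model"),
            all(s >= 0 & s <= 1), all(t >= 0 & t <= 1))
  plogis((s - t) / model$tau)
}

#' Array noise model
#'
#' Noise sources of single-cell two-channel BAC hybridization after
#' whole-genome amplification (WGA).
#'
#' @param sigma_wga SD (log2 units) of the per-probe, per-channel
#'   multiplicative WGA representation bias.
#' @param sigma_hyb SD (log2 units) of additive log-scale measurement noise
#'   per channel.
#' @param affinity_sd SD (log2 units) of the per-probe hybridization
#'   affinity shared by both channels (cancels in the ratio, but scales
#'   absolute intensities).
#' @param background Additive intensity floor (>= 0), in units where one
#'   copy contributes ~1 to the expected intensity.
#' @param snr_meanlog,snr_sdlog Log-normal parameters of the simulated
#'   per-probe signal-to-noise ratio.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma_wga = 0.25, sigma_hyb = 0.15,
                        affinity_sd = 0.5, background = 0.01,
                        snr_meanlog = log(15), snr_sdlog = 0.8) {
  stopifnot(sigma_wga >= 0, sigma_hyb >= 0, affinity_sd >= 0,
            background >= 0, snr_sdlog >= 0)
  structure(list(sigma_wga = sigma_wga, sigma_hyb = sigma_hyb,
                 affinity_sd = affinity_sd, background = background,
                 snr_meanlog = snr_meanlog, snr_sdlog = snr_sdlog),
            class = "noise_model")
}

#' Single-cell state
#'
#' @param cell_id Unique cell identifier.
#' @param phase `"G0G1"`, `"S"` or `"G2M"`.
#' @param s S-phase progression fraction in `[0, 1]`; required exactly when
#'   `phase == "S"`.
#' @param karyotype A [karyotype_preset()].
#' @param label Recorded (sorted) phase label; defaults to the true phase,
#'   but may differ when sorting impurity is simulated.
#' @return A list of class `cell_state`.
#' @export
cell_state <- function(cell_id, phase = c("G0G1", "S", "G2M"), s = NULL,
                       karyotype, label = NULL) {
  phase <- match.arg(phase)
  if (phase == "S") {
    if (is.null(s) || is.na(s) || s < 0 || s > 1)
      stop("an S-phase cell requires a progression fraction s in [0, 1]")
  } else if (!is.null(s) && !is.na(s)) {
    stop("progression s is defined only for S-phase cells")
  }
  stopifnot(inherits(karyotype, "karyotype_preset"))
  structure(list(cell_id = cell_id, phase = phase,
                 s = if (phase == "S") s else NA_real_,
                 karyotype = karyotype,
                 label = if (is.null(label)) phase else label),
            class = "cell_state")
}

#' Per-probe effective copy number of a single cell
#'
#' A G0/G1 cell carries its constitutive copy number `c_p` at every probe; a
#' G2/M cell exactly `2 c_p`. In an S-phase cell each of the `c_p` copies has
#' been replicated with probability [replication_probability()], so the
#' effective count is `c_p + Binomial(c_p, p)`. Origin firing is coordinated
#' within replication domains: each copy's firing uniform is built from a
#' domain-level standard-normal draw (weight `sqrt(w)`) plus an independent
#' copy-level draw, which preserves the per-copy marginal probability while
#' creating the domain-length runs of shared replication state seen in
#' single-cell profiles.
#'
#' @param cell A [cell_state()].
#' @param probe_map A `probe_map` with a timing track (for S cells).
#' @param model A [replication_model()].
#' @param w Domain-sharing mixing weight in `[0, 1]` (0 = independent
#'   probes, 1 = whole domains fire together).
#' @param seed Integer seed.
#' @return Integer vector of effective copies, one per probe.
#' @export
simulate_effective_copies <- function(cell, probe_map,
                                      model = replication_model(),
                                      w = 0.7, seed = 1) {
  stopifnot(inherits(cell, "cell_state"), w >= 0, w <= 1)
  cn <- constitutive_copies(probe_map, cell$karyotype)
  if (cell$phase == "G0G1") return(cn)
  if (cell$phase == "G2M") return(2L * cn)
  if (!all(c("timing", "domain") %in% names(probe_map)))
    stop("S-phase simulation requires a probe map with a timing track")
  set.seed(seed)
  p <- replication_probability(cell$s, probe_map$timing, model)
  idx <- rep(seq_len(nrow(probe_map)), cn)      # one entry per DNA copy
  dom <- probe_map$domain[idx]
  z_dom <- rnorm(max(probe_map$domain))
  z <- sqrt(w) * z_dom[dom] + sqrt(1 - w) * rnorm(length(idx))
  fired <- pnorm(z) < p[idx]
  replicated <- tabulate(idx[fired], nbins = nrow(probe_map))
  cn + replicated
}

#' Simulate two-channel array intensities
#'
#' The test channel measures the cell's (amplified) DNA, the reference
#' channel bulk DNA of the opposite sex: constitutive copy number 2 on
#' autosomes with no replication oscillation (bulk DNA averages over cell
#' cycle phases). Each channel is
#' `affinity * copies * 2^N(0, sigma_wga) + background`, further multiplied
#' by `2^N(0, sigma_hyb)` measurement noise; the probe affinity is shared
#' between channels. A per-probe signal-to-noise value is drawn from the
#' configured log-normal and attached.
#'
#' @param copies Integer vector of per-probe effective copies (test channel).
#' @param probe_map The `probe_map` the copies refer to.
#' @param noise A [noise_model()].
#' @param ref_sex Sex of the reference DNA (`"XX"` or `"XY"`), normally the
#'   opposite of the cell line's.
#' @param seed Integer seed.
#' @param cell Optional [cell_state()] attached as metadata.
#' @return A `data.frame` of class `intensity_table`: per probe `test`,
#'   `ref`, `snr` plus probe annotation, with cell metadata in attributes.
#' @export
simulate_intensities <- function(copies, probe_map, noise = noise_model(),
                                 ref_sex = c("XY", "XX"), seed = 1,
                                 cell = NULL) {
  ref_sex <- match.arg(ref_sex)
  stopifnot(inherits(noise, "noise_model"), length(copies) == nrow(probe_map))
  set.seed(seed + 2L)
  n <- nrow(probe_map)
  ref_cn <- ifelse(is_autosome(probe_map$chrom), 2,
                   ifelse(probe_map$chrom == "chrX",
                          if (ref_sex == "XX") 2 else 1,
                          if (ref_sex == "XY") 1 else 0))
  affinity <- 2^rnorm(n, 0, noise$affinity_sd)
  test <- affinity * copies * 2^rnorm(n, 0, noise$sigma_wga) + noise$background
  ref <- affinity * ref_cn * 2^rnorm(n, 0, noise$sigma_wga) + noise$background
  test <- test * 2^rnorm(n, 0, noise$sigma_hyb)
  ref <- ref * 2^rnorm(n, 0, noise$sigma_hyb)
  snr <- rlnorm(n, noise$snr_meanlog, noise$snr_sdlog)
  out <- data.frame(probe_id = probe_map$probe_id, chrom = probe_map$chrom,
                    start = probe_map$start, end = probe_map$end,
                    test = test, ref = ref, snr = snr,
                    stringsAsFactors = FALSE)
  for (col in c("gc", "timing", "domain", "early"))
    if (col %in% names(probe_map)) out[[col]] <- probe_map[[col]]
  structure(out, class = c("intensity_table", "data.frame"),
            cell_id = if (is.null(cell)) NA_character_ else cell$cell_id,
            phase = if (is.null(cell)) NA_character_ else cell$phase,
            s = if (is.null(cell)) NA_real_ else cell$s,
            label = if (is.null(cell)) NA_character_ else cell$label)
}

# Stable 32-bit string hash used to derive per-cell RNG substreams, so that
# adding or removing cells never perturbs another cell's draws.
.hash_id <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

cell_seed <- function(seed, cell_id)
  as.integer((as.numeric(seed) * 10007 + .hash_id(cell_id)) %% 2000000000)

#' Simulate a single-cell cohort
#'
#' Draws cells of the requested phases for one karyotype preset and
#' simulates their array intensities. S-phase progressions are uniform on
#' `s_range`. Each cell uses an RNG substream derived from the global seed
#' and its cell id, so cohorts are reproducible and extensible.
#'
#' @param n_s,n_g0g1,n_g2m Cell counts per phase.
#' @param preset A [karyotype_preset()].
#' @param probe_map A `probe_map` with timing track.
#' @param model A [replication_model()].
#' @param noise A [noise_model()].
#' @param w Domain-sharing weight, see [simulate_effective_copies()].
#' @param s_range Range of S-phase progressions sampled.
#' @param mislabel_rate Probability that a cell's recorded (sorted) phase
#'   label is swapped between S and G0/G1, mimicking sorting impurity.
#' @param seed Integer seed.
#' @return A list of class `sc_cohort`; each element is
#'   `list(cell = <cell_state>, intensities = <intensity_table>)`.
#' @examples
#' pm <- generate_probe_map(map_config(n_probes = 400), seed = 1)
#' pm <- generate_timing_track(pm, seed = 1)
#' coh <- simulate_cohort(n_s = 2, n_g0g1 = 2, preset = paper_presets()$dup7p,
#'                        probe_map = pm, seed = 7)
#' length(coh)
#' @export
simulate_cohort <- function(n_s = 10, n_g0g1 = 10, n_g2m = 0,
                            preset, probe_map,
                            model = replication_model(),
                            noise = noise_model(), w = 0.7,
                            s_range = c(0.1, 0.9), mislabel_rate = 0,
                            seed = 1) {
  stopifnot(inherits(preset, "karyotype_preset"),
            n_s >= 0, n_g0g1 >= 0, n_g2m >= 0,
            mislabel_rate >= 0, mislabel_rate <= 1)
  ref_sex <- if (preset$sex == "XX") "XY" else "XX"
  ids <- c(sprintf("S_%s_%03d", preset$name, seq_len(n_s)),
           sprintf("G0G1_%s_%03d", preset$name, seq_len(n_g0g1)),
           sprintf("G2M_%s_%03d", preset$name, seq_len(n_g2m)))
  phases <- rep(c("S", "G0G1", "G2M"), c(n_s, n_g0g1, n_g2m))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cs <- cell_seed(seed, ids[i])
    set.seed(cs)
    s <- if (phases[i] == "S") runif(1, s_range[1], s_range[2]) else NULL
    label <- phases[i]
    if (mislabel_rate > 0 && phases[i] %in% c("S", "G0G1") &&
        runif(1) < mislabel_rate)
      label <- if (phases[i] == "S") "G0G1" else "S"
    cell <- cell_state(ids[i], phases[i], s = s, karyotype = preset,
                       label = label)
    copies <- simulate_effective_copies(cell, probe_map, model, w,
                                        seed = cs + 1L)
    tab <- simulate_intensities(copies, probe_map, noise, ref_sex,
                                seed = cs + 2L, cell = cell)
    out[[i]] <- list(cell = cell, intensities = tab)
  }
  names(out) <- ids
  structure(out, class = "sc_cohort", preset = preset$name, seed = seed)
}

#' @export
print.sc_cohort <- function(x, ...) {
  ph <- vapply(x, function(e) e$cell$phase, character(1))
  cat(sprintf("<sc_cohort> %d cells (%s), preset %s\n", length(x),
              paste(sprintf("%s:%d", names(table(ph)), table(ph)),
                    collapse = ", "),
              attr(x, "preset")))
  invisible(x)
}
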