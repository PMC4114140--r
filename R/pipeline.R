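#' Analyze a simulated cohort end to end
#'
#' Preprocesses every cell (SNR filter, ratio-of-means normalization),
#' attributes a cell-cycle phase from the replication-domain oscillation,
#' applies the segmental detection rule to the constitutive regions of the
#' cohort's karyotype, and classifies each cell as accurate or false
#' negative.
#'
#' @param cohort An `sc_cohort` from [simulate_cohort()].
#' @param preset The cohort's [karyotype_preset()] (its aberration regions
#'   are the regions of interest).
#' @param config A [detection_config()].
#' @param min_snr SNR filter threshold.
#' @param alpha,min_r Phase-attribution thresholds, see [classify_phase()].
#' @return A list of class `cohort_analysis`: `region_calls`, `cell_calls`,
#'   `phase_calls` (one row per cell), `table1a`, `table1b`.
#' @export
analyze_cohort <- function(cohort, preset, config = detection_config(),
                           min_snr = 2, alpha = 0.01, min_r = 0.2) {
  stopifnot(inherits(preset, "karyotype_preset"))
  regions <- lapply(preset$aberrations, function(ab) ab$region)
  rc <- list(); cc <- list(); pc <- list()
  for (entry in cohort) {
    prof <- cell_profile(entry, min_snr = min_snr)
    calls <- do.call(rbind, lapply(regions, function(r)
      evaluate_region(prof, r, config)))
    rc[[length(rc) + 1]] <- calls
    cc[[length(cc) + 1]] <- classify_cell(calls)
    ph <- phase_call(prof, alpha = alpha, min_r = min_r)
    pc[[length(pc) + 1]] <- data.frame(
      cell_id = entry$cell$cell_id, true_phase = entry$cell$phase,
      label = entry$cell$label, s = entry$cell$s,
      early_mean = ph$early_mean, late_mean = ph$late_mean,
      p = ph$p, r_t = ph$r_t, gc_slope = ph$gc_slope, call = ph$call,
      stringsAsFactors = FALSE)
  }
  region_calls <- do.call(rbind, rc)
  rownames(region_calls) <- NULL
  t1a <- build_table1A(region_calls)
  structure(list(region_calls = region_calls,
                 cell_calls = do.call(rbind, cc),
                 phase_calls = do.call(rbind, pc),
                 table1a = t1a,
                 table1b = derive_table1B(t1a)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d cells, %d region calls\n",
              nrow(x$cell_calls), nrow(x$region_calls)))
  print(x$table1b)
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Writes the probe map, the karyotype, one intensity TSV per cell
#' (`probe_id`, `test`, `ref`, `snr`), a cohort manifest and the fully
#' resolved configuration (YAML), so that a run is reproducible from its
#' output directory alone.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset Preset name (one of `names(paper_presets())`) or a
#'   [karyotype_preset()].
#' @param n_s,n_g0g1,n_g2m Cell counts per phase.
#' @param seed Integer seed.
#' @param probe_map Optional `probe_map` with timing track; default is the
#'   matched layout of [paper_probe_map()] built from `seed`.
#' @param model,noise,w,s_range,mislabel_rate Passed to [simulate_cohort()].
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(out_dir, preset = "dup7p", n_s = 10, n_g0g1 = 10,
                         n_g2m = 0, seed = 1, probe_map = NULL,
                         model = replication_model(), noise = noise_model(),
                         w = 0.7, s_range = c(0.1, 0.9), mislabel_rate = 0) {
  if (is.character(preset)) {
    presets <- paper_presets()
    if (!preset %in% names(presets))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    preset <- presets[[preset]]
  }
  stopifnot(inherits(preset, "karyotype_preset"))
  if (is.null(probe_map)) probe_map <- paper_probe_map(seed = seed)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  coh <- simulate_cohort(n_s = n_s, n_g0g1 = n_g0g1, n_g2m = n_g2m,
                         preset = preset, probe_map = probe_map,
                         model = model, noise = noise, w = w,
                         s_range = s_range, mislabel_rate = mislabel_rate,
                         seed = seed)
  write_probe_map(probe_map, file.path(out_dir, "probe_map.tsv"))
  write_karyotype(preset, file.path(out_dir, "karyotype.yaml"))
  cell_dir <- file.path(out_dir, "cells")
  dir.create(cell_dir, showWarnings = FALSE)
  man <- data.frame(cell_id = character(0), phase = character(0),
                    label = character(0), s = numeric(0), file = character(0))
  for (entry in coh) {
    fn <- file.path("cells", paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                         entry$cell$cell_id), ".tsv"))
    tab <- entry$intensities
    write.table(format(data.frame(probe_id = tab$probe_id, test = tab$test,
                                  ref = tab$ref, snr = tab$snr),
                       digits = 17, scientific = FALSE, trim = TRUE),
                file.path(out_dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    man <- rbind(man, data.frame(cell_id = entry$cell$cell_id,
                                 phase = entry$cell$phase,
                                 label = entry$cell$label,
                                 s = entry$cell$s, file = fn,
                                 stringsAsFactors = FALSE))
  }
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(seed = seed, preset = preset$name,
                        n_s = n_s, n_g0g1 = n_g0g1, n_g2m = n_g2m,
                        replication = list(tau = model$tau, link = model$link),
                        noise = unclass(noise), w = w, s_range = s_range,
                        mislabel_rate = mislabel_rate,
                        package_version = as.character(utils::packageVersion("sccgh"))),
                  file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a cohort directory back into memory
#'
#' @param dir A directory written by [run_simulate()].
#' @return A list: `cohort` (`sc_cohort`), `probe_map`, `preset`, `config`.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("no manifest.tsv in ", dir)
  man <- read.delim(man_path, stringsAsFactors = FALSE)
  pm <- read_probe_map(file.path(dir, "probe_map.tsv"))
  preset <- read_karyotype(file.path(dir, "karyotype.yaml"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) stop("missing cell file ", man$file[i])
    raw <- read.delim(path, stringsAsFactors = FALSE)
    if (!identical(raw$probe_id, pm$probe_id))
      stop("cell file ", man$file[i], " does not match the probe map")
    tab <- data.frame(probe_id = pm$probe_id, chrom = pm$chrom,
                      start = pm$start, end = pm$end,
                      test = raw$test, ref = raw$ref, snr = raw$snr,
                      stringsAsFactors = FALSE)
    for (col in c("gc", "timing", "domain", "early"))
      if (col %in% names(pm)) tab[[col]] <- pm[[col]]
    cell <- cell_state(man$cell_id[i], man$phase[i],
                       s = if (man$phase[i] == "S") man$s[i] else NULL,
                       karyotype = preset, label = man$label[i])
    out[[i]] <- list(cell = cell,
                     intensities = structure(tab,
                       class = c("intensity_table", "data.frame"),
                       cell_id = cell$cell_id, phase = cell$phase,
                       s = cell$s, label = cell$label))
  }
  names(out) <- man$cell_id
  list(cohort = structure(out, class = "sc_cohort", preset = preset$name,
                          seed = cfg$seed),
       probe_map = pm, preset = preset, config = cfg)
}

#' Analyze a cohort directory and write call tables
#'
#' Runs the full pipeline (preprocess, phase attribution, detection,
#' summary statistics) on a cohort directory written by [run_simulate()]
#' and writes `region_calls.tsv`, `cell_calls.tsv`, `phase_calls.tsv` and a
#' human-readable `stats.txt` next to it.
#'
#' @param dir Cohort directory.
#' @param config A [detection_config()].
#' @param min_snr,alpha,min_r Passed to [analyze_cohort()].
#' @return The `cohort_analysis`, invisibly.
#' @export
run_analyze <- function(dir, config = detection_config(), min_snr = 2,
                        alpha = 0.01, min_r = 0.2) {
  loaded <- read_cohort(dir)
  res <- analyze_cohort(loaded$cohort, loaded$preset, config,
                        min_snr = min_snr, alpha = alpha, min_r = min_r)
  wt <- function(df, fn) write.table(df, file.path(dir, fn), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wt(res$region_calls, "region_calls.tsv")
  wt(res$cell_calls, "cell_calls.tsv")
  wt(res$phase_calls, "phase_calls.tsv")
  prof_dir <- file.path(dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (entry in loaded$cohort) {
    prof <- cell_profile(entry, min_snr = min_snr)
    write.table(prof[, c("probe_id", "chrom", "start", "end", "log2ratio")],
                file.path(prof_dir,
                          paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                      attr(prof, "cell_id")), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  con <- file(file.path(dir, "stats.txt"), "w")
  sink(con); on.exit({sink(); close(con)})
  print(res$table1b)
  if (length(unique(res$table1a$phase)) > 1) {
    cat(sprintf("Mann-Whitney (passing fractions, all regions): p = %.4f\n",
                phase_comparison(res$table1a)$p.value))
  }
  conc <- concordance_report(res$phase_calls)
  cat(sprintf("Phase-attribution concordance: %.1f%%\n",
              100 * attr(conc, "concordance")))
  invisible(res)
}
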