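# Shared fixtures, built once per test run. Everything is generated in code;
# the only stored data is the packaged per-cell count table.

.fx <- new.env(parent = emptyenv())

# Mid-sized map over the chromosomes the presets touch (plus sex chromosomes)
test_map <- function() {
  if (is.null(.fx$map)) {
    cfg <- map_config(chrom_lengths = c(chr1 = 249e6, chr7 = 159e6,
                                        chr9 = 141e6, chr18 = 78e6,
                                        chr20 = 63e6, chrX = 155e6,
                                        chrY = 59e6),
                      n_probes = 900)
    .fx$map <- generate_timing_track(generate_probe_map(cfg, seed = 3),
                                     timing_config(), seed = 3)
  }
  .fx$map
}

# Autosome-only map: noiseless tests divide by zero on chrY otherwise
autosome_map <- function(n_probes = 600) {
  key <- paste0("aut", n_probes)
  if (is.null(.fx[[key]])) {
    cfg <- map_config(chrom_lengths = c(chr1 = 249e6, chr7 = 159e6,
                                        chr9 = 141e6, chr18 = 78e6,
                                        chr20 = 63e6),
                      n_probes = n_probes)
    .fx[[key]] <- generate_timing_track(generate_probe_map(cfg, seed = 5),
                                        timing_config(), seed = 5)
  }
  .fx[[key]]
}

# The array-matched 3000-probe layout used by the acceptance checks
matched_map <- function() {
  if (is.null(.fx$paper_map)) .fx$paper_map <- paper_probe_map(seed = 1)
  .fx$paper_map
}

no_noise <- function() noise_model(sigma_wga = 0, sigma_hyb = 0,
                                   affinity_sd = 0, background = 0,
                                   snr_meanlog = log(15), snr_sdlog = 0)

diploid_preset <- function(sex = "XX") karyotype_preset("diploid", sex, list())

# Hand-built intensity table for formula-level tests
mk_intensity <- function(test, ref, snr = rep(10, length(test)),
                         chrom = rep("chr1", length(test)),
                         cell_id = "cell1", phase = "G0G1") {
  n <- length(test)
  structure(data.frame(probe_id = sprintf("P%03d", seq_len(n)),
                       chrom = chrom, start = seq_len(n) * 1e6,
                       end = seq_len(n) * 1e6 + 1e5,
                       test = test, ref = ref, snr = snr,
                       stringsAsFactors = FALSE),
            class = c("intensity_table", "data.frame"),
            cell_id = cell_id, phase = phase, s = NA_real_, label = phase)
}

# Hand-built ratio profile on one chromosome, probes 1 Mb apart
mk_profile <- function(L, chrom = "chr1", cell_id = "cell1", phase = "S") {
  n <- length(L)
  structure(data.frame(probe_id = sprintf("P%03d", seq_len(n)),
                       chrom = chrom, start = seq_len(n) * 1e6,
                       end = seq_len(n) * 1e6 + 1e5,
                       log2ratio = L, stringsAsFactors = FALSE),
            class = c("ratio_profile", "data.frame"),
            cell_id = cell_id, phase = phase, s = NA_real_, label = phase)
}
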