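test_that("replication probability follows the logistic firing model", {
  m <- replication_model(tau = 0.1)
  expect_equal(replication_probability(0.5, 0.5, m), 0.5)
  expect_equal(replication_probability(0.3, 0.3, replication_model(tau = 2)),
               0.5)
  expect_equal(replication_probability(0.9, 0.1,
                                       replication_model(tau = 1e-6)), 1)
  expect_equal(replication_probability(0.5, 0.3, m), plogis(2),
               tolerance = 1e-12)
  # monotone in s, antitone in t
  s <- seq(0, 1, 0.05)
  expect_true(all(diff(replication_probability(s, 0.4, m)) > 0))
  expect_true(all(diff(replication_probability(0.4, s, m)) < 0))
  expect_error(replication_model(tau = 0), "positive")
  expect_error(replication_model(tau = -1), "positive")
})

test_that("effective copies are exact in G phases and binomial in S", {
  pm <- autosome_map()
  dip <- diploid_preset()
  g0 <- cell_state("g0", "G0G1", karyotype = dip)
  expect_true(all(simulate_effective_copies(g0, pm, seed = 1) == 2L))
  g2 <- cell_state("g2", "G2M", karyotype = dip)
  expect_true(all(simulate_effective_copies(g2, pm, seed = 1) == 4L))
  # fully replicated S locus: p = 1 everywhere once s clears every timing
  pm_late <- pm
  pm_late$timing <- pmin(pm_late$timing, 0.9)
  sc <- cell_state("s1", "S", s = 0.99, karyotype = dip)
  eff <- simulate_effective_copies(sc, pm_late, replication_model(tau = 1e-6),
                                   seed = 1)
  expect_true(all(eff == 4L))
  expect_error(cell_state("x", "G0G1", s = 0.5, karyotype = dip), "only for")
  expect_error(cell_state("x", "S", karyotype = dip), "requires")
})

test_that("mean effective copies recover the binomial expectation", {
  # flat-timing map so every probe shares one replication probability
  pm <- autosome_map(n_probes = 300)
  pm$timing <- rep(0.5, nrow(pm))
  dip <- diploid_preset()
  m <- replication_model(tau = 0.1)
  n_cells <- 120
  for (s in c(0.3, 0.5, 0.7)) {
    p <- replication_probability(s, 0.5, m)
    cellmeans <- vapply(seq_len(n_cells), function(i) {
      cell <- cell_state(paste0("c", i), "S", s = s, karyotype = dip)
      mean(simulate_effective_copies(cell, pm, m, seed = 1000 + i))
    }, numeric(1))
    se <- sd(cellmeans) / sqrt(n_cells)
    expect_lt(abs(mean(cellmeans) - 2 * (1 + p)), 3 * se + 1e-9)
  }
})

test_that("noiseless intensities give exact copy-number ratios", {
  pm <- autosome_map()
  pre <- paper_presets()$dup7p
  g0 <- cell_state("g0", "G0G1", karyotype = pre)
  copies <- simulate_effective_copies(g0, pm, seed = 1)
  tab <- simulate_intensities(copies, pm, no_noise(), ref_sex = "XY",
                              seed = 1, cell = g0)
  ratio <- tab$test / tab$ref
  mid <- (pm$start + pm$end) / 2
  in_dup <- pm$chrom == "chr7" & mid >= 8840001 & mid <= 34e6
  expect_equal(ratio[in_dup], rep(1.5, sum(in_dup)), tolerance = 1e-12)
  expect_equal(ratio[!in_dup], rep(1, sum(!in_dup)), tolerance = 1e-12)
})

test_that("channel WGA noise adds in quadrature on the log2 ratio", {
  pm <- generate_probe_map(map_config(chrom_lengths = c(chr1 = 3e9),
                                      n_probes = 10000), seed = 4)
  dip <- diploid_preset()
  g0 <- cell_state("g0", "G0G1", karyotype = dip)
  nm <- noise_model(sigma_wga = 0.3, sigma_hyb = 0, affinity_sd = 0,
                    background = 0, snr_sdlog = 0)
  tab <- simulate_intensities(rep(2L, nrow(pm)), pm, nm, seed = 4, cell = g0)
  s <- sd(log2(tab$test / tab$ref))
  expect_lt(abs(s - sqrt(2) * 0.3) / (sqrt(2) * 0.3), 0.15)
})

test_that("cohorts are sized, reproducible and substream-stable", {
  pm <- autosome_map()
  pre <- paper_presets()$dup7p
  coh <- simulate_cohort(n_s = 10, n_g0g1 = 7, preset = pre, probe_map = pm,
                         seed = 5)
  expect_length(coh, 17)
  expect_false(anyDuplicated(names(coh)) > 0)
  phases <- vapply(coh, function(e) e$cell$phase, character(1))
  expect_equal(sum(phases == "S"), 10)
  ss <- vapply(coh[phases == "S"], function(e) e$cell$s, numeric(1))
  expect_true(all(ss >= 0.1 & ss <= 0.9))
  coh2 <- simulate_cohort(n_s = 10, n_g0g1 = 7, preset = pre, probe_map = pm,
                          seed = 5)
  expect_identical(coh[[1]]$intensities$test, coh2[[1]]$intensities$test)
  # adding cells leaves existing cells' draws untouched (per-cell substreams)
  coh3 <- simulate_cohort(n_s = 12, n_g0g1 = 7, preset = pre, probe_map = pm,
                          seed = 5)
  expect_identical(coh3[["S_dup7p_003"]]$intensities$test,
                   coh[["S_dup7p_003"]]$intensities$test)
})

test_that("S-phase oscillation points in the early > late direction", {
  pm <- autosome_map()
  dip <- diploid_preset()
  sc <- cell_state("s", "S", s = 0.5, karyotype = dip)
  copies <- simulate_effective_copies(sc, pm, seed = 6)
  tab <- simulate_intensities(copies, pm, no_noise(), seed = 6, cell = sc)
  prof <- normalize_ratios(tab)
  expect_gt(mean(prof$log2ratio[prof$early]),
            mean(prof$log2ratio[!prof$early]))
})

test_that("uniform G2/M doubling cancels under normalization", {
  pm <- autosome_map()
  pre <- paper_presets()$der18_t9_18
  g0 <- cell_state("a", "G0G1", karyotype = pre)
  g2 <- cell_state("b", "G2M", karyotype = pre)
  p0 <- normalize_ratios(simulate_intensities(
    simulate_effective_copies(g0, pm, seed = 7), pm, no_noise(),
    seed = 7, cell = g0))
  p2 <- normalize_ratios(simulate_intensities(
    simulate_effective_copies(g2, pm, seed = 7), pm, no_noise(),
    seed = 7, cell = g2))
  expect_equal(p2$log2ratio, p0$log2ratio, tolerance = 1e-12)
})
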