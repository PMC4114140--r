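test_that("probe map generation conserves count, order and non-overlap", {
  cfg <- map_config(chrom_lengths = c(chrA = 3e9), n_probes = 3000)
  pm <- generate_probe_map(cfg, seed = 1)
  expect_equal(nrow(pm), 3000)
  expect_true(all(pm$start <= pm$end))
  expect_true(all(diff(pm$start) > 0))
  expect_true(all(pm$end[-nrow(pm)] < pm$start[-1]))  # no overlaps
  expect_true(all(pm$gc >= 0 & pm$gc <= 1))
  pm2 <- generate_probe_map(cfg, seed = 1)
  expect_identical(pm, pm2)
  expect_false(identical(pm, generate_probe_map(cfg, seed = 2)))
})

test_that("terminal bands reach the configured density enrichment", {
  cfg <- map_config(chrom_lengths = c(chrA = 500e6), n_probes = 2000,
                    enrichment = 2)
  pm <- generate_probe_map(cfg, seed = 1)
  L <- 500e6; cen <- 0.4 * L; tf <- 0.1
  wins <- rbind(c(0, tf * cen), c(cen - tf * cen, cen),
                c(cen, cen + tf * (L - cen)), c(L - tf * (L - cen), L))
  mid <- (pm$start + pm$end) / 2
  in_term <- rowSums(outer(mid, wins[, 1], ">") &
                     outer(mid, wins[, 2], "<")) > 0
  term_dens <- sum(in_term) / sum(wins[, 2] - wins[, 1])
  int_dens <- sum(!in_term) / (L - sum(wins[, 2] - wins[, 1]))
  expect_gte(term_dens / int_dens, 2 * 0.9)
  expect_lte(term_dens / int_dens, 2 * 1.1)
})

test_that("an impossible probe count raises an explicit error", {
  cfg <- map_config(chrom_lengths = c(chrA = 1e6), n_probes = 1000,
                    min_spacing = 2e3)
  expect_error(generate_probe_map(cfg, seed = 1), "incompatible")
})

test_that("timing tracks respect domain structure and GC coupling", {
  pm0 <- generate_probe_map(map_config(chrom_lengths = c(chrA = 2e9),
                                       n_probes = 2000), seed = 2)
  # zero jitter: timing exactly constant within each domain
  tr0 <- generate_timing_track(pm0, timing_config(jitter_sd = 0), seed = 2)
  per_dom <- tapply(tr0$timing, tr0$domain, function(x) diff(range(x)))
  expect_true(all(per_dom == 0))
  expect_true(all(tr0$timing >= 0 & tr0$timing <= 1))
  expect_identical(tr0$early, tr0$timing < 0.5)
  # bounded jitter: consecutive probes of one domain within 3 * jitter_sd
  tr <- generate_timing_track(pm0, timing_config(jitter_sd = 0.02), seed = 2)
  d <- abs(diff(tr$timing))
  same_dom <- diff(tr$domain) == 0
  expect_true(all(d[same_dom] <= 3 * 0.02 + 1e-12))
  # GC-earliness coupling lands near the requested rho
  expect_gte(cor(tr$gc, -tr$timing), 0.45)
  expect_lte(cor(tr$gc, -tr$timing), 0.75)
  tr_null <- generate_timing_track(pm0, timing_config(rho = 0), seed = 2)
  expect_lt(abs(cor(tr_null$gc, -tr_null$timing)), 0.15)
})

test_that("the three presets carry the reported aberrations", {
  pr <- paper_presets()
  expect_length(pr, 3)
  expect_length(pr$dup7p$aberrations, 1)
  ab1 <- pr$dup7p$aberrations[[1]]
  expect_equal(ab1$region$size_mb, 25.16, tolerance = 1e-6)
  expect_equal(ab1$cn, 3L)
  sizes2 <- vapply(pr$der18_t9_18$aberrations,
                   function(a) a$region$size_mb, numeric(1))
  dirs2 <- vapply(pr$der18_t9_18$aberrations,
                  function(a) a$region$direction, character(1))
  expect_equal(sizes2, c(24, 8), tolerance = 1e-6)
  expect_equal(dirs2, c("gain", "loss"))
  sizes3 <- vapply(pr$der20_t18_20$aberrations,
                   function(a) a$region$size_mb, numeric(1))
  expect_equal(sizes3, c(9.3, 1.7), tolerance = 1e-6)
  expect_equal(pr$der20_t18_20$sex, "XY")
})

test_that("the matched layout pins the five reported region probe counts", {
  pm <- matched_map()
  rg <- paper_regions()
  counts <- vapply(rg, function(r) nrow(probes_in_region(pm, r)), integer(1))
  expect_equal(unname(counts), c(40L, 42L, 28L, 30L, 8L))
  expect_true(all(diff(pm$start[pm$chrom == "chr18"]) > 0))
})

test_that("region probe lookup is by midpoint, errors when empty, nests monotonically", {
  pm <- test_map()
  whole <- region("all1", "chr1", 1, 249e6, "gain")
  expect_equal(nrow(probes_in_region(pm, whole)),
               sum(pm$chrom == "chr1"))
  # a region squeezed between two probe midpoints holds nothing
  m <- sort((pm$start + pm$end)[pm$chrom == "chr1"] / 2)
  gap <- region("gap", "chr1", floor(m[1]) + 1, ceiling(m[2]) - 1, "gain")
  expect_error(probes_in_region(pm, gap), "no probe")
  expect_error(probes_in_region(pm, region("off", "chr99", 1, 100, "gain")),
               "absent")
  # nested regions: probe count monotone in region length
  set.seed(9)
  for (i in 1:10) {
    a <- sort(runif(2, 1, 249e6))
    inner <- region("in", "chr1", a[1], a[2], "gain")
    outer <- region("out", "chr1", max(1, a[1] - 30e6), a[2] + 30e6, "gain")
    n_in <- tryCatch(nrow(probes_in_region(pm, inner)), error = function(e) 0)
    expect_gte(nrow(probes_in_region(pm, outer)), n_in)
  }
})

test_that("probe maps and karyotypes round-trip through their file formats", {
  pm <- test_map()
  path <- tempfile(fileext = ".tsv")
  write_probe_map(pm, path)
  back <- read_probe_map(path)
  for (col in c("probe_id", "chrom", "start", "end"))
    expect_identical(back[[col]], pm[[col]])
  for (col in c("gc", "timing"))
    expect_equal(back[[col]], pm[[col]], tolerance = 1e-12)
  expect_identical(back$early, pm$early)
  ky <- tempfile(fileext = ".yaml")
  write_karyotype(paper_presets()$der18_t9_18, ky)
  back_k <- read_karyotype(ky)
  expect_equal(back_k, paper_presets()$der18_t9_18)
})

test_that("karyotype invariants are enforced", {
  rg <- paper_regions()
  expect_error(karyotype_preset("bad", "XX",
    list(list(region = rg$dup18p, cn = 3L),
         list(region = rg$del18p, cn = 1L))), "overlap")
  expect_error(karyotype_preset("bad2", "XX",
    list(list(region = rg$dup7p, cn = 1L))), "inconsistent")
  cn <- constitutive_copies(test_map(), paper_presets()$der18_t9_18)
  pm <- test_map()
  expect_true(all(cn[pm$chrom == "chrY"] == 0))        # XX line
  mid <- (pm$start + pm$end) / 2
  in_dup <- pm$chrom == "chr9" & mid <= 24e6
  expect_true(all(cn[in_dup] == 3))
  in_del <- pm$chrom == "chr18" & mid <= 8e6
  expect_true(all(cn[in_del] == 1))
  expect_true(all(cn[pm$chrom == "chr1"] == 2))
})
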