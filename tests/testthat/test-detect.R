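test_that("per-probe calls use strict +/- threshold comparison", {
  prof <- mk_profile(c(0, 0.31, -0.31, 0.30, -0.30, 1.2))
  expect_equal(probe_calls(prof, detection_config()),
               c("neutral", "gain", "loss", "neutral", "neutral", "gain"))
  lax <- detection_config(strict = FALSE)
  expect_equal(probe_calls(prof, lax)[4:5], c("gain", "loss"))
})

test_that("longest_run matches a brute-force scan", {
  brute <- function(x) {
    best <- 0L
    for (i in seq_along(x)) {
      j <- i
      while (j <= length(x) && x[j]) j <- j + 1L
      best <- max(best, j - i)
    }
    best
  }
  set.seed(21)
  for (i in 1:1000) {
    x <- runif(sample(0:30, 1)) < runif(1)
    expect_identical(longest_run(x), as.integer(brute(x)))
  }
})

test_that("region evaluation applies the half-probes and run criteria", {
  reg <- region("r", "chr1", 1, 45e6, "gain")
  # 25/40 passing with a long run: accurate and reliable
  L <- rep(0, 40); L[1:25] <- 0.5
  rc <- evaluate_region(mk_profile(L), reg, detection_config())
  expect_equal(rc$k, 25); expect_equal(rc$n, 40)
  expect_equal(rc$klass, "accurate"); expect_true(rc$reliable)
  # 18/40: below half, above the no-call quarter -> underestimated
  L <- rep(0, 40); L[1:18] <- 0.5
  rc <- evaluate_region(mk_profile(L), reg, detection_config())
  expect_equal(rc$klass, "underestimated"); expect_false(rc$reliable)
  # 21/42 counts as detected (at least half is inclusive)
  reg42 <- region("r42", "chr1", 1, 45e6, "gain")
  L <- rep(0, 42); L[seq(1, 41, 2)] <- 0.5
  rc <- evaluate_region(mk_profile(L), reg42, detection_config())
  expect_equal(rc$k, 21); expect_equal(rc$klass, "accurate")
  # 20/40 passing but longest run 9: k-criterion met, run criterion not
  L <- rep(0, 40); L[1:9] <- 0.5; L[11:19] <- 0.5; L[21:22] <- 0.5
  rc <- evaluate_region(mk_profile(L), reg, detection_config())
  expect_equal(rc$k, 20)
  expect_equal(rc$longest_run, 9L)
  expect_false(rc$reliable)
  expect_equal(rc$klass, "accurate")
  # loss direction, 3/28 passing: rule-based no-call
  regl <- region("rl", "chr1", 1, 30e6, "loss")
  L <- rep(0, 28); L[1:3] <- -0.6
  rc <- evaluate_region(mk_profile(L), regl, detection_config())
  expect_equal(rc$klass, "nocall")
  # external flag overrides the rule in both directions
  rc <- evaluate_region(mk_profile(L), regl, detection_config(),
                        nocall_flag = FALSE)
  expect_equal(rc$klass, "underestimated")
  # small region: run requirement drops to n, flagged below resolution
  reg8 <- region("r8", "chr1", 1, 9e6, "loss")
  L <- rep(-0.5, 8)
  rc <- evaluate_region(mk_profile(L), reg8, detection_config())
  expect_true(rc$reliable); expect_true(rc$below_resolution)
  expect_error(evaluate_region(mk_profile(rep(0, 5)),
                               region("x", "chr9", 1, 1e6, "gain"),
                               detection_config()),
               "no retained probe")
})

test_that("cell classification aggregates regions with no-call dominance", {
  mk_calls <- function(klasses)
    data.frame(cell_id = "c", phase = "S", klass = klasses,
               stringsAsFactors = FALSE)
  expect_equal(classify_cell(mk_calls(c("accurate", "accurate")))$cell_class,
               "accurate")
  cc <- classify_cell(mk_calls(c("accurate", "nocall")))
  expect_equal(cc$cell_class, "false_negative")
  expect_equal(cc$fn_subtype, "no_call")
  cc <- classify_cell(mk_calls(c("accurate", "underestimated")))
  expect_equal(cc$fn_subtype, "underestimation")
  cc <- classify_cell(mk_calls(c("underestimated", "nocall")))
  expect_equal(cc$fn_subtype, "no_call")
})

test_that("passing counts are monotone non-increasing in the threshold", {
  set.seed(22)
  prof <- mk_profile(rnorm(200, 0.2, 0.4))
  reg <- region("r", "chr1", 1, 500e6, "gain")
  ks <- vapply(seq(0.05, 1.5, by = 0.05), function(th)
    evaluate_region(prof, reg, detection_config(threshold = th))$k,
    integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("false-positive probe counts behave at the limits and rise in S", {
  pm <- autosome_map()
  pre2 <- paper_presets()$der18_t9_18   # does not carry dup7p
  dup7p <- paper_regions()$dup7p
  g0 <- cell_state("g", "G0G1", karyotype = pre2)
  prof0 <- cell_profile(list(cell = g0, intensities = simulate_intensities(
    simulate_effective_copies(g0, pm, seed = 30), pm, no_noise(),
    seed = 30, cell = g0)), min_snr = 0)
  expect_equal(false_positive_probe_count(prof0, dup7p, detection_config()),
               0L)
  huge <- detection_config(threshold = 50)
  set.seed(23)
  profr <- mk_profile(rnorm(100, 0, 1))
  expect_equal(false_positive_probe_count(
    profr, region("r", "chr1", 1, 500e6, "gain"), huge), 0L)
  # Monte Carlo: S-phase non-carriers trip more probes than G0/G1 ones
  fp_mean <- function(coh) {
    mean(vapply(coh, function(e)
      false_positive_probe_count(cell_profile(e), dup7p,
                                 detection_config()), integer(1)))
  }
  coh <- simulate_cohort(n_s = 50, n_g0g1 = 50, preset = pre2,
                         probe_map = pm, seed = 31)
  phases <- vapply(coh, function(e) e$cell$phase, character(1))
  expect_gt(fp_mean(coh[phases == "S"]), fp_mean(coh[phases == "G0G1"]))
})
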