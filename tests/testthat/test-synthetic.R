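test_that("read sampling is deterministic given the seed", {
  s <- mef_scenario("WT", seed = 2)
  r1 <- sample_reads(s, "RPI", 500L, seed = 7)
  r2 <- sample_reads(s, "RPI", 500L, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(r1, f1); write_reads_bed(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  r3 <- sample_reads(s, "RPI", 500L, seed = 8)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("zero depth gives an empty but valid read set", {
  s <- mef_scenario("WT", seed = 2)
  r <- sample_reads(s, "RPI", 0L, seed = 1)
  expect_equal(nrow(r), 0L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(r, f)
  expect_equal(nrow(read_reads_bed(f)), 0L)
})

test_that("uniform occupancy with no bias yields near-uniform coverage", {
  cs <- rdna_coords(2000L, 1L)
  sc <- rdna_scenario(list(fac = rep(1, 2000), input = rep(1, 2000)),
                      cs = cs, tss = 500L, bias_range = 1, seed = 3)
  n <- 2e5
  reads <- sample_reads(sc, "fac", n, seed = 13, circular = TRUE)
  cov <- base_coverage(extend_reads(reads, 100L, 2000L, circular = TRUE),
                       2000L)
  v <- unclass(cov)
  mu <- mean(v)
  # per-base coverage is a sum over ~mu fragments; interior bases stay
  # within 4 sd of the Poisson-scale expectation
  expect_true(all(abs(v - mu) < 4 * sqrt(mu)))
})

test_that("unknown presets and factors are rejected with listings", {
  expect_error(mef_scenario("nope"), "available presets")
  s <- mef_scenario("WT", seed = 1)
  expect_error(sample_reads(s, "nosuch", 10L), "unknown factor")
  expect_error(sample_reads(s, "RPI", -1L), "depth")
})

test_that("the WT preset encodes the published ground truth", {
  s <- mef_scenario("WT", seed = 1)
  gt <- s$ground_truth
  expect_equal(gt$half_life_s, 15)
  expect_equal(gt$elongation_rate, 60)
  expect_equal(gt$active_fraction, 0.64)
  # decay half-distance d1/2 = v * t1/2 = 900 bp
  expect_equal(gt$decay_length_bp * log(2), 900)
  # the Rrn3 profile itself decays with that length over the gene body
  rrn3 <- s$profiles$Rrn3
  d <- 2000; ratio <- rrn3[s$tss + 3000] / rrn3[s$tss + 1000]
  expect_equal(ratio, exp(-d / gt$decay_length_bp), tolerance = 1e-6)
})

test_that("deletion presets suppress the expected factors only", {
  wt <- mef_scenario("WT", seed = 1)
  rko <- mef_scenario("Rrn3-KO", seed = 1)
  uko <- mef_scenario("UBF-KO", seed = 1)

  body <- wt$tss:(wt$tss + 13000L)
  expect_lt(mean(rko$profiles$RPI[body]), 0.05 * mean(wt$profiles$RPI[body]))
  expect_equal(rko$profiles$UBF, wt$profiles$UBF)
  expect_equal(rko$profiles$SL1, wt$profiles$SL1)
  expect_equal(rko$profiles$TTF1, wt$profiles$TTF1)

  expect_true(all(uko$profiles$UBF == 0))
  expect_true(all(uko$profiles$RPI == 0))
  expect_true(all(uko$profiles$SL1 == 0))
  expect_equal(uko$profiles$CTCF, wt$profiles$CTCF)
  # fully inactive mixture: histone everywhere
  expect_equal(uko$active_fraction, 0)
})

test_that("ground truth round-trips losslessly through JSON", {
  s <- mef_scenario("WT", seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(s, f)
  gt <- read_ground_truth(f)
  expect_equal(gt$half_life_s, s$ground_truth$half_life_s)
  expect_equal(gt$decay_length_bp, s$ground_truth$decay_length_bp)
  expect_identical(gt$preset, "WT")
})

test_that("write_scenario emits every pipeline input", {
  s <- mef_scenario("WT", seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_scenario(s, dir, factors = "Rrn3", depth = 200L, seed = 5)
  for (p in unlist(paths)) expect_true(file.exists(p))
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(unname(Biostrings::width(fa)), s$length)
  rd <- read_reads_bed(paths$reads_Rrn3)
  expect_equal(nrow(rd), 200L)
})

test_that("bias cancellation: enrichment agrees with and without bias", {
  # same occupancy sampled under a strong shared bias field and under none;
  # input normalization removes the bias up to sampling error
  cs <- rdna_coords(5000L, 1L)
  occ <- c(rep(1, 2000), rep(4, 1000), rep(1, 2000))
  base <- list(fac = occ, input = rep(1, 5000))
  sc_flat <- rdna_scenario(base, cs = cs, tss = 100L, bias_range = 1, seed = 6)
  sc_bias <- rdna_scenario(base, cs = cs, tss = 100L, bias_range = 5, seed = 6)
  expect_gt(max(sc_bias$bias) / min(sc_bias$bias), 2.5)

  enr_of <- function(sc, k) {
    ch <- sample_reads(sc, "fac", 1e5, seed = 70 + k)
    ip <- sample_reads(sc, "input", 1e5, seed = 80 + k)
    enrichment_pipeline(ch, ip, 5000L, circular = TRUE)
  }
  e_flat <- enr_of(sc_flat, 1)
  e_bias <- enr_of(sc_bias, 2)
  mid <- function(e, a, b) mean(unclass(e)[a:b], na.rm = TRUE)
  # plateau-to-background contrast recovered in both
  expect_equal(mid(e_bias, 2200, 2800) / mid(e_bias, 200, 1800),
               mid(e_flat, 2200, 2800) / mid(e_flat, 200, 1800),
               tolerance = 0.05)
})
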