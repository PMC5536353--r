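test_that("feature summaries report mean, max and signal fraction", {
  v <- c(rep(3, 50), rep(0, 50))
  tr <- as_enrichment_track(v)
  s <- summarize_feature(tr, 1L, 50L, "on")
  expect_equal(s$mean, 3)
  expect_equal(s$max, 3)
  expect_equal(s$signal_fraction, 1)
  z <- summarize_feature(tr, 51L, 100L, "off")
  expect_equal(z$mean, 0)
  expect_equal(z$signal_fraction, 0)
  expect_error(summarize_feature(as_enrichment_track(rep(NA_real_, 10)), 1L, 5L),
               "fully masked")
})

test_that("signal fractions over a partition of the reference sum to 1", {
  set.seed(8)
  v <- runif(300)
  tr <- as_enrichment_track(v)
  cuts <- c(1, 80, 150, 222, 300)
  fr <- vapply(seq_len(4), function(i)
    summarize_feature(tr, cuts[i] + (i > 1), cuts[i + 1])$signal_fraction,
    numeric(1))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("wrapped features are summarized across the origin", {
  v <- c(rep(5, 10), rep(0, 80), rep(5, 10))
  tr <- as_enrichment_track(v)
  s <- summarize_feature(tr, 91L, 10L)  # wraps the track end
  expect_equal(s$mean, 5)
  expect_equal(s$n_bases, 20L)
})

test_that("find_peak locates maxima with ties broken toward the anchor", {
  v <- rep(0, 500)
  v[240:260] <- c(1:10, 11, 10:1) / 11
  tr <- as_enrichment_track(v)
  pk <- find_peak(tr, anchor = 226L)
  expect_equal(pk$position, 250L)
  expect_equal(pk$offset, 24L)

  # a source exactly at the anchor gives offset 0
  expect_equal(find_peak(tr, anchor = 250L)$offset, 0L)

  # plateau tie resolves toward the anchor
  flat <- rep(0, 100); flat[40:60] <- 1
  expect_equal(find_peak(as_enrichment_track(flat), anchor = 35L)$position, 40L)
  expect_equal(find_peak(as_enrichment_track(flat), anchor = 80L)$position, 60L)

  expect_error(find_peak(as_enrichment_track(rep(NA_real_, 100)), 50L),
               "masked")
})

test_that("peak offsets are invariant to rescaling and origin displacement", {
  v <- rep(0.1, 400)
  v[200:220] <- 0.1 + stats::dnorm(200:220, 212, 4)
  tr <- as_enrichment_track(v)
  off1 <- find_peak(tr, 205L)$offset
  off2 <- find_peak(as_enrichment_track(100 * v), 205L)$offset
  expect_identical(off1, off2)

  # displacing the coordinate origin moves positions but not offsets
  cs <- rdna_coords(400L, 150L)
  vd <- v[native_position(seq_len(400L), cs)]
  offd <- find_peak(as_enrichment_track(vd), remap_position(205L, cs))$offset
  expect_identical(offd, off1)
})

test_that("two nearby sources are resolved by the multi-peak variant", {
  x <- seq_len(600)
  v <- stats::dnorm(x, 300, 8) + stats::dnorm(x, 337, 8)
  mx <- find_local_maxima(as_enrichment_track(v), anchor = 300L,
                          window = c(-100L, 100L), n = 2L)
  expect_equal(nrow(mx), 2L)
  expect_true(all(abs(sort(mx$position) - c(300, 337)) <= 2))
})

test_that("feature ratios cancel common scale in the paired form", {
  set.seed(4)
  v <- runif(200) + 0.5
  a <- as_enrichment_track(v)
  b <- as_enrichment_track(3.7 * v)
  f1 <- c(10L, 60L); f2 <- c(120L, 180L)
  expect_equal(feature_ratio(a, f1, f2, trackB = a), 1)
  expect_equal(feature_ratio(a, f1, f2, trackB = b), 1, tolerance = 1e-12)
  expect_equal(feature_ratio(a, f1, f1), 1)
  expect_error(feature_ratio(as_enrichment_track(c(rep(1, 100), rep(0, 100))),
                             c(1L, 50L), c(150L, 200L)),
               "zero denominator")
})

test_that("a gene-unit-only factor leaves under 1% of signal in the IGS", {
  # synthetic UBF geography: occupancy across the functional gene unit only
  s <- mef_scenario("WT", seed = 21, bias_range = 1)
  chip <- sample_reads(s, "UBF", 5e4, seed = 31)
  inp <- sample_reads(s, "input", 5e4, seed = 32)
  enr <- enrichment_pipeline(chip, inp, s$length)
  feats <- remap_features(rdna_features(), s$cs)
  igs <- feats[feats$name == "IGS", ]
  gene <- feats[feats$name == "47S", ]
  figs <- summarize_feature(enr, igs$start, igs$end)$signal_fraction
  fgene <- summarize_feature(enr, gene$start, gene$end)$signal_fraction
  expect_lt(figs / fgene, 0.01)
})
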