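test_that("read extension anchors fragments at the 5' end", {
  r <- aligned_reads(c(101L, 101L), c(150L, 150L), c("+", "-"))
  fr <- extend_reads(r, 100L, ref_length = 1000L)
  expect_identical(fr$start, c(101L, 51L))
  expect_identical(fr$end, c(200L, 150L))
  # clipping at the linear bounds
  edge <- extend_reads(aligned_reads(5L, 54L, "-"), 100L, ref_length = 1000L)
  expect_identical(c(edge$start, edge$end), c(1L, 54L))
})

test_that("circular extension wraps and covers the enumerated bases", {
  L <- 500L
  r <- aligned_reads(L - 9L, L, "+")
  fr <- extend_reads(r, 100L, ref_length = L, circular = TRUE)
  cov <- base_coverage(fr, L)
  covered <- which(unclass(cov) > 0)
  expect_setequal(covered, c((L - 9L):L, 1:90))
  expect_equal(sum(unclass(cov)), 100)
})

test_that("unknown strand is rejected with the record named", {
  expect_error(aligned_reads(1L, 10L, "*"), "strand.*record 1")
})

test_that("coverage counts overlapping fragments and conserves read bases", {
  L <- 1000L
  cov1 <- base_coverage(aligned_reads(101L, 200L, "+"), L)
  expect_equal(sum(unclass(cov1) == 1), 100)
  expect_equal(sum(unclass(cov1)), 100)
  cov2 <- base_coverage(aligned_reads(c(101L, 101L), c(200L, 200L), c("+", "+")), L)
  expect_true(all(unclass(cov2)[101:200] == 2))

  set.seed(1)
  s <- sample.int(L - 150L, 1000L, replace = TRUE)
  len <- sample(75:125, 1000L, replace = TRUE)
  r <- aligned_reads(s, s + len - 1L, sample(c("+", "-"), 1000L, TRUE))
  cov <- base_coverage(r, L)
  expect_equal(sum(unclass(cov)), sum(len))
})

test_that("smoothing implements the centred running mean", {
  L <- 400L
  # constant track is invariant in both modes
  const <- base_coverage(aligned_reads(1L, L, "+"), L)
  expect_equal(as.vector(smooth_coverage(const, 25L)), rep(1, L))
  expect_equal(as.vector(smooth_coverage(const, 25L, circular = TRUE)), rep(1, L))

  # an interior spike of 25 spreads to exactly 1.0 over the window
  spike <- base_coverage(
    aligned_reads(rep(200L, 25L), rep(200L, 25L), rep("+", 25L)), L)
  sm <- unclass(smooth_coverage(spike, 25L))
  expect_equal(sm[188:212], rep(1, 25))
  expect_equal(sm[c(187, 213)], c(0, 0))

  # window of 1 is the identity; even windows are rejected
  expect_equal(as.vector(smooth_coverage(spike, 1L)), as.vector(unclass(spike)))
  expect_error(smooth_coverage(spike, 24L), "odd")
})

test_that("circular smoothing conserves the track total exactly", {
  set.seed(3)
  L <- 600L
  s <- sample.int(L, 300L, replace = TRUE)
  r <- extend_reads(aligned_reads(s, s, rep("+", 300L)), 100L, L, circular = TRUE)
  cov <- base_coverage(r, L)
  sm <- smooth_coverage(cov, 25L, circular = TRUE)
  expect_equal(sum(unclass(sm)), sum(unclass(cov)), tolerance = 1e-9)
})

test_that("RPM scaling divides by the library total in millions", {
  L <- 100L
  cov <- base_coverage(aligned_reads(1L, 50L, "+", total_reads = 10L), L)
  v <- unclass(cov)
  expect_equal(unclass(scale_rpm(smooth_coverage(cov, 1L), 1e6))[1], 1)
  expect_equal(unclass(scale_rpm(smooth_coverage(cov, 1L), 2e6))[1], 0.5)
  # conservation: RPM total = raw total * 1e6/total
  expect_equal(sum(unclass(scale_rpm(smooth_coverage(cov, 1L), 12345))),
               sum(v) * 1e6 / 12345)
  expect_error(scale_rpm(cov, 0), "total_reads")
})

test_that("input normalization gives exact ratios and masks input dropout", {
  L <- 300L
  set.seed(5)
  s <- sample.int(L - 100L, 400L, replace = TRUE)
  r <- extend_reads(aligned_reads(s, s, rep("+", 400L)), 100L, L)
  rpmtr <- scale_rpm(smooth_coverage(base_coverage(r, L), 25L))

  self <- normalize_to_input(rpmtr, rpmtr)
  expect_true(all(unclass(self)[!attr(self, "mask")] == 1))

  dbl <- scale_rpm(smooth_coverage(base_coverage(r, L), 25L),
                   attr(rpmtr, "total_reads") / 2)
  ratio <- normalize_to_input(dbl, rpmtr)
  expect_true(all(abs(unclass(ratio)[!attr(ratio, "mask")] - 2) < 1e-12))

  # dropout base is masked, not infinite
  inp <- rpmtr
  inp[1:40] <- 0
  masked <- normalize_to_input(rpmtr, inp)
  expect_true(all(attr(masked, "mask")[1:40]))
  expect_true(all(is.na(unclass(masked)[1:40])))
  expect_false(any(is.infinite(unclass(masked)), na.rm = TRUE))
})

test_that("normalization rejects mismatched or unprepared tracks", {
  a <- scale_rpm(smooth_coverage(base_coverage(aligned_reads(1L, 50L, "+"), 100L), 25L))
  b <- scale_rpm(smooth_coverage(base_coverage(aligned_reads(1L, 50L, "+"), 200L), 25L))
  expect_error(normalize_to_input(a, b), "different lengths")
  raw <- base_coverage(aligned_reads(1L, 50L, "+"), 100L)
  expect_error(normalize_to_input(raw, raw), "smoothed, RPM")
})

test_that("smoothing and RPM scaling commute", {
  set.seed(9)
  L <- 400L
  s <- sample.int(L - 120L, 500L, replace = TRUE)
  r <- extend_reads(aligned_reads(s, s, rep("+", 500L), total_reads = 800L), 100L, L)
  cov <- base_coverage(r, L)
  a <- scale_rpm(smooth_coverage(cov, 25L))
  b <- smooth_coverage(scale_rpm(smooth_coverage(cov, 1L)), 25L)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("reads round-trip through BED with 1-based/0-based conversion", {
  r <- aligned_reads(c(1L, 101L), c(100L, 175L), c("+", "-"), total_reads = 10L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(r, bed)
  # on disk the first record starts at 0 (BED half-open)
  expect_match(readLines(bed)[1], "^rDNA\t0\t100\t")
  back <- read_reads_bed(bed, total_reads = 10L)
  expect_identical(back$start, r$start)
  expect_identical(back$end, r$end)
  expect_identical(back$strand, r$strand)
})

test_that("tracks round-trip through bedGraph with masked bases omitted", {
  v <- c(rep(0, 10), rep(2.5, 20), rep(0.5, 5))
  tr <- as_enrichment_track(c(v, NA, NA))
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_track_bedgraph(tr, bg)
  back <- read_track_bedgraph(bg, 37L)
  expect_equal(back[1:35], v)
  expect_true(all(is.na(back[36:37])))
  maskbed <- withr::local_tempfile(fileext = ".bed")
  write_mask_bed(tr, maskbed)
  m <- read_features_bed(maskbed)
  expect_identical(c(m$start, m$end), c(36L, 37L))
})
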