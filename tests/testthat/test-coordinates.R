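test_that("origin displacement maps the published landmarks", {
  cs <- bk_cs()
  # the initiation site (native 1) lands at 14815 after displacing the
  # origin to the EcoRI site at 30493
  expect_identical(remap_position(1L, cs), 14815L)
  expect_identical(remap_position(30493L, cs), 1L)
  expect_identical(remap_position(45306L, cs), 45306L - 30493L + 1L)
  expect_identical(native_position(14815L, cs), 1L)
})

test_that("remap is a bijection preserving circular distances", {
  cs <- tiny_cs()
  all_pos <- seq_len(cs$length)
  mapped <- remap_position(all_pos, cs)
  expect_setequal(mapped, all_pos)
  expect_identical(native_position(mapped, cs), all_pos)

  circ_dist <- function(a, b, L) {
    d <- abs(a - b)
    pmin(d, L - d)
  }
  set.seed(42)
  a <- sample(cs$length, 50, replace = TRUE)
  b <- sample(cs$length, 50, replace = TRUE)
  expect_equal(circ_dist(remap_position(a, cs), remap_position(b, cs), cs$length),
               circ_dist(a, b, cs$length))
})

test_that("full-length remap is bijective on the published geometry", {
  cs <- bk_cs()
  mapped <- remap_position(seq_len(cs$length), cs)
  expect_identical(sort(mapped), seq_len(cs$length))
})

test_that("positions out of range raise a coordinate error naming the value", {
  cs <- tiny_cs()
  expect_error(remap_position(0L, cs), "coordinate error.*0")
  expect_error(remap_position(201L, cs), "coordinate error.*201")
  expect_error(rdna_coords(100, 101), "origin")
})

test_that("interval remap preserves membership, including across the wrap", {
  cs <- bk_cs()
  # the 47S promoter amplicon wraps the native end of the repeat
  iv <- remap_interval(45133L, 40L, cs)
  member_before <- sort(remap_position(interval_positions(45133L, 40L, cs$length), cs))
  member_after <- sort(interval_positions(iv$start, iv$end, cs$length))
  expect_identical(member_after, member_before)
  expect_false(iv$wraps)  # contiguous in the displaced frame
  expect_identical(iv$end - iv$start + 1L,
                   length(interval_positions(45133L, 40L, cs$length)))

  # identity coordinate system leaves intervals unchanged
  id <- rdna_coords(200, 1)
  expect_identical(remap_interval(20L, 80L, id), list(start = 20L, end = 80L, wraps = FALSE))

  # single-base interval maps to remap_position of that base
  one <- remap_interval(7L, 7L, cs)
  expect_identical(one$start, remap_position(7L, cs))
  expect_identical(one$end, one$start)
})

test_that("feature tables remap and round-trip through TSV and BED", {
  cs <- bk_cs()
  feats <- rdna_features()
  disp <- remap_features(feats, cs)
  # each remapped feature keeps its length counted across the wrap
  for (i in seq_len(nrow(feats))) {
    expect_identical(
      length(interval_positions(disp$start[i], disp$end[i], cs$length)),
      length(interval_positions(feats$start[i], feats$end[i], cs$length)),
      info = feats$name[i])
  }
  back <- remap_features(disp, cs, reverse = TRUE)
  expect_identical(back$start, feats$start)
  expect_identical(back$end, feats$end)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(feats, tsv)
  expect_identical(read_features_tsv(tsv)$start, feats$start)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_features_bed(feats, bed, length = cs$length)
  rd <- read_features_bed(bed)
  # the wrapped 47SPr is split into two records; everything else survives
  expect_true(all(c("47SPr_5p", "47SPr_3p") %in% rd$name))
  expect_identical(rd$start[rd$name == "SpPr"], 43089L)
  expect_identical(rd$end[rd$name == "SpPr"], 43253L)
})

test_that("TSS-relative frame converts through native and displaced", {
  cs <- bk_cs()
  expect_identical(convert_frame(1L, cs, "tss_relative", "displaced"), 14815L)
  expect_identical(convert_frame(-1L, cs, "tss_relative", "native"), 45306L)
  expect_error(convert_frame(0L, cs, "tss_relative", "native"), "no position 0")
  p <- c(5L, 500L, 45000L)
  expect_identical(
    convert_frame(convert_frame(p, cs, "native", "displaced"), cs,
                  "displaced", "native"), p)
})

test_that("GC profile counts windows and handles N correctly", {
  expect_equal(gc_profile(strrep("GGGCCC", 10), window = 50)$values, 100)
  expect_equal(gc_profile(strrep("A", 50), window = 50)$values, 0)
  # 27 G/C of 50
  seqs <- paste0(strrep("G", 27), strrep("A", 23))
  expect_equal(gc_profile(seqs, window = 50)$values, 54)
  # N bases excluded from the denominator; all-N window is NA
  withN <- paste0(strrep("N", 50), strrep("G", 25), strrep("N", 25))
  prof <- gc_profile(withN, window = 50)
  expect_true(is.na(prof$values[1]))
  expect_equal(prof$values[2], 100)
  # truncated tail dropped
  expect_length(gc_profile(strrep("A", 125), window = 50)$values, 2)
  expect_error(gc_profile(""), "empty|shorter")
})

test_that("window-weighted GC values reproduce the total GC percent", {
  seqs <- simulate_repeat_sequence(5000, seed = 7)
  prof <- gc_profile(seqs, window = 50)
  head_len <- length(prof$values) * 50
  base <- strsplit(substr(seqs, 1, head_len), "")[[1]]
  total_gc <- 100 * mean(base %in% c("G", "C"))
  expect_equal(mean(prof$values), total_gc, tolerance = 1e-12)
})
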