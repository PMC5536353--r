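#' rDNA repeat coordinate system with a displaced origin
#'
#' The mouse rDNA repeat (GenBank BK000964v3, 45,306 bp) is numbered from the
#' 47S pre-rRNA initiation site, which puts the upstream regulatory elements
#' (Spacer Promoter, Enhancer repeats, 47S Promoter) at the far end of the
#' sequence. For track display and analysis the origin of the repeat is
#' displaced to the EcoRI site at native position 30,493 so that the whole
#' functional gene unit becomes contiguous; the initiation site then falls at
#' position 14,815. This object records the repeat length and the native
#' position that becomes position 1 of the displaced frame, and drives all
#' conversions between the two frames (the repeat is treated as circular, so
#' the remapping is a bijection on `1..length`).
#'
#' @param length Repeat length in bp (default 45306, BK000964v3).
#' @param origin Native 1-based position that becomes position 1 after
#'   displacement (default 30493, the EcoRI site).
#' @return An object of class `rdna_coords` with fields `length` and `origin`.
#' @examples
#' cs <- rdna_coords()
#' remap_position(1, cs)      # the initiation site lands at 14815
#' native_position(14815, cs) # and back
#' @export
rdna_coords <- function(length = 45306L, origin = 30493L) {
  length <- as.integer(length)
  origin <- as.integer(origin)
  if (is.na(length) || length < 1L)
    stop("repeat length must be a positive integer, got ", length)
  if (is.na(origin) || origin < 1L || origin > length)
    stop("origin must lie in 1..", length, ", got ", origin)
  structure(list(length = length, origin = origin), class = "rdna_coords")
}

#' @export
print.rdna_coords <- function(x, ...) {
  cat("rDNA repeat coordinate system\n")
  cat("  length:", x$length, "bp (circular)\n")
  cat("  origin displaced to native position", x$origin, "\n")
  cat("  native position 1 maps to", remap_position(1L, x), "\n")
  invisible(x)
}

check_positions <- function(p, cs, what = "position") {
  bad <- which(is.na(p) | p < 1L | p > cs$length)
  if (length(bad))
    stop("coordinate error: ", what, " out of range 1..", cs$length,
         ": ", paste(utils::head(p[bad], 3L), collapse = ", "))
  invisible(p)
}

#' Convert native repeat positions to the displaced frame
#'
#' Positions at or beyond the displaced origin shift down to the start of the
#' new frame; positions before it wrap around the circular repeat to the end.
#' The map is a bijection on `1..length`.
#'
#' @param p Integer vector of native 1-based positions.
#' @param cs An [rdna_coords()] object.
#' @return Integer vector of displaced 1-based positions.
#' @seealso [native_position()] for the inverse.
#' @export
remap_position <- function(p, cs) {
  stopifnot(inherits(cs, "rdna_coords"))
  p <- as.integer(p)
  check_positions(p, cs)
  ifelse(p >= cs$origin, p - cs$origin + 1L, p + (cs$length - cs$origin + 1L))
}

#' Convert displaced-frame positions back to native numbering
#'
#' Inverse of [remap_position()].
#'
#' @inheritParams remap_position
#' @param p Integer vector of displaced 1-based positions.
#' @export
native_position <- function(p, cs) {
  stopifnot(inherits(cs, "rdna_coords"))
  p <- as.integer(p)
  check_positions(p, cs)
  shift <- cs$length - cs$origin + 1L
  ifelse(p <= shift, p + cs$origin - 1L, p - shift)
}

#' Convert between native, displaced and TSS-relative frames
#'
#' Native numbering starts at the 47S initiation site (so TSS-relative +1 is
#' native 1); upstream TSS-relative positions are negative and wrap to the far
#' end of the circular repeat (there is no position 0). The displaced frame is
#' the analysis frame produced by [remap_position()].
#'
#' @param p Positions in the `from` frame (signed integers for
#'   `"tss_relative"`).
#' @param cs An [rdna_coords()] object.
#' @param from,to One of `"native"`, `"displaced"`, `"tss_relative"`.
#' @return Positions in the `to` frame.
#' @export
convert_frame <- function(p, cs, from = c("native", "displaced", "tss_relative"),
                          to = c("displaced", "native", "tss_relative")) {
  from <- match.arg(from)
  to <- match.arg(to)
  p <- as.integer(p)
  # normalise to native first
  nat <- switch(from,
    native = check_positions(p, cs),
    displaced = native_position(p, cs),
    tss_relative = {
      if (any(p == 0L, na.rm = TRUE)) stop("coordinate error: TSS-relative frame has no position 0")
      ifelse(p > 0L, p, cs$length + p + 1L)
    })
  check_positions(nat, cs, "converted position")
  switch(to,
    native = nat,
    displaced = remap_position(nat, cs),
    tss_relative = ifelse(nat <= cs$length / 2, nat, nat - cs$length - 1L))
}

#' Expand a (possibly origin-wrapping) interval to its member positions
#'
#' Intervals on the circular repeat are 1-based and inclusive on both ends;
#' `start > end` denotes an interval wrapping the origin (e.g. the 47S
#' Promoter amplicon 45133-40 in native numbering).
#'
#' @param start,end Interval endpoints (1-based, inclusive).
#' @param length Repeat length in bp.
#' @return Integer vector of member positions in interval order.
#' @export
interval_positions <- function(start, end, length) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L ||
      start > length || end > length)
    stop("coordinate error: invalid interval [", start, ", ", end, "] on length ", length)
  if (start <= end) seq.int(start, end) else c(seq.int(start, length), seq.int(1L, end))
}

#' Remap a feature interval into the displaced frame
#'
#' Both endpoints are remapped and the wrap convention (`start > end`)
#' recomputed; the interval keeps the same member positions (counted across
#' the wrap) and hence the same length.
#'
#' @param start,end Interval endpoints in the native frame (wrap allowed).
#' @param cs An [rdna_coords()] object.
#' @param reverse If `TRUE`, map from displaced back to native.
#' @return A list with fields `start`, `end`, `wraps`.
#' @export
remap_interval <- function(start, end, cs, reverse = FALSE) {
  pos <- interval_positions(start, end, cs$length)
  a <- if (reverse) native_position(pos[1L], cs) else remap_position(pos[1L], cs)
  b <- if (reverse) native_position(pos[length(pos)], cs) else remap_position(pos[length(pos)], cs)
  list(start = a, end = b, wraps = a > b)
}

#' Remap a feature annotation table into the displaced frame
#'
#' @param features A data frame with columns `name`, `start`, `end`, `strand`
#'   in native coordinates (wrap allowed, `start > end`).
#' @param cs An [rdna_coords()] object.
#' @param reverse If `TRUE`, map displaced coordinates back to native.
#' @return The table with `start`/`end` remapped and a logical `wraps` column.
#' @export
remap_features <- function(features, cs, reverse = FALSE) {
  stopifnot(is.data.frame(features), all(c("name", "start", "end") %in% names(features)))
  out <- features
  for (i in seq_len(nrow(features))) {
    iv <- remap_interval(features$start[i], features$end[i], cs, reverse = reverse)
    out$start[i] <- iv$start
    out$end[i] <- iv$end
    out$wraps <- if (i == 1L) rep(NA, nrow(out)) else out$wraps
    out$wraps[i] <- iv$wraps
  }
  out
}

#' Default rDNA repeat feature annotations
#'
#' Landmark annotations of the mouse rDNA repeat in native coordinates
#' (numbered from the 47S initiation site): the Spacer Promoter (SpPr) and its
#' adjacent Spacer termination site (Tsp), the Enhancer repeats, the wrapped
#' 47S Promoter, the 47S transcribed region with its ETS/18S/5.8S/28S
#' segments, the T1-T10 terminator cluster, the Intergenic Spacer (IGS) and
#' the CTCF-bound enhancer boundary. The promoter-region amplicon coordinates
#' follow the published ChIP-qPCR amplicons; rRNA-body segment boundaries are
#' conventional approximations and the synthetic generator treats them as
#' ground truth.
#'
#' @return Data frame with columns `name`, `start`, `end`, `strand`.
#' @export
rdna_features <- function() {
  data.frame(
    name = c("47S", "ETS", "18S", "5.8S", "28S", "T1_10", "IGS",
             "IGS3", "CTCF", "SpPr", "Tsp", "Enhancers", "47SPr"),
    start = c(1L, 1L, 4008L, 6878L, 8124L, 13401L, 13701L,
              42646L, 42970L, 43089L, 43267L, 43422L, 45133L),
    end = c(13400L, 4007L, 5877L, 7034L, 12852L, 13700L, 42645L,
            42903L, 43070L, 43253L, 43421L, 45132L, 40L),
    strand = "+",
    stringsAsFactors = FALSE
  )
}

#' Read or write feature tables
#'
#' Feature annotations travel either as a TSV in 1-based native coordinates
#' (columns `name`, `start`, `end`, `strand`; `start > end` marks an interval
#' wrapping the repeat origin) or as BED6 (0-based half-open on disk; wrapped
#' intervals are split into two BED records suffixed `_5p`/`_3p`).
#'
#' @param features Feature data frame as returned by [rdna_features()].
#' @param file Path to read or write.
#' @param length Repeat length, needed to split wrapped intervals for BED.
#' @param chrom Chromosome name used in BED records.
#' @return `read_features_tsv` and `read_features_bed` return a feature data
#'   frame; the writers return the file path invisibly.
#' @name feature_io
NULL

#' @rdname feature_io
#' @export
write_features_tsv <- function(features, file) {
  utils::write.table(features[, c("name", "start", "end", "strand")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname feature_io
#' @export
read_features_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname feature_io
#' @export
write_features_bed <- function(features, file, length, chrom = "rDNA") {
  recs <- list()
  for (i in seq_len(nrow(features))) {
    s <- features$start[i]; e <- features$end[i]
    if (s <= e) {
      recs[[length(recs) + 1L]] <- data.frame(name = features$name[i], start = s, end = e)
    } else {
      recs[[length(recs) + 1L]] <- data.frame(name = paste0(features$name[i], "_5p"), start = s, end = length)
      recs[[length(recs) + 1L]] <- data.frame(name = paste0(features$name[i], "_3p"), start = 1L, end = e)
    }
  }
  recs <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = recs$start, end = recs$end),
    strand = "*", name = recs$name)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname feature_io
#' @export
read_features_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.frame(
    name = if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' GC content in non-overlapping windows
#'
#' Percent G+C per non-overlapping window across a repeat sequence, as used to
#' compare the UBF binding profile with the underlying base composition.
#' Windows are complete only: a truncated tail shorter than `window` is
#' dropped. N bases are excluded from the percentage; an all-N window yields
#' `NA`.
#'
#' @param seq A character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param window Window size in bp (default 50).
#' @return An object of class `gc_profile`: list with `values` (percent GC per
#'   window), `window`, and `start` (first coordinate of the first window).
#' @export
gc_profile <- function(seq, window = 50L) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  L <- length(seq)
  if (L == 0L) stop("empty sequence")
  nwin <- L %/% window
  if (nwin == 0L) stop("sequence shorter than one window")
  v <- Biostrings::Views(seq, start = (seq_len(nwin) - 1L) * window + 1L, width = window)
  freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
  gc <- freq[, "G"] + freq[, "C"]
  acgt <- gc + freq[, "A"] + freq[, "T"]
  vals <- ifelse(acgt > 0L, 100 * gc / acgt, NA_real_)
  structure(list(values = as.numeric(vals), window = window, start = 1L),
            class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat("GC profile:", length(x$values), "windows of", x$window, "bp\n")
  cat("  mean GC:", round(mean(x$values, na.rm = TRUE), 2), "%\n")
  invisible(x)
}

#' Write a GC profile as bedGraph
#'
#' @param gc A [gc_profile()] object.
#' @param file Output path.
#' @param chrom Chromosome name.
#' @export
write_gc_bedgraph <- function(gc, file, chrom = "rDNA") {
  nwin <- length(gc$values)
  keep <- !is.na(gc$values)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = (seq_len(nwin) - 1L) * gc$window + gc$start,
                              width = gc$window)[keep],
    score = gc$values[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}
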