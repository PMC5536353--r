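#' Aligned read sets
#'
#' A light container for aligned read (or fragment) positions on the rDNA
#' repeat chromosome: 1-based inclusive `start`/`end`, strand `+`/`-`, and the
#' total number of aligned reads in the whole library (genome plus rDNA),
#' which is the denominator for reads-per-million scaling.
#'
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param chrom Chromosome name (single value).
#' @param total_reads Total aligned reads in the library; defaults to the
#'   number of records.
#' @return A data frame of class `aligned_reads` with attribute `total_reads`.
#' @export
aligned_reads <- function(start, end, strand, chrom = "rDNA",
                          total_reads = length(start)) {
  start <- as.integer(start); end <- as.integer(end)
  strand <- as.character(strand)
  if (length(start) != length(end) || length(start) != length(strand))
    stop("start, end and strand must have the same length")
  if (any(start > end))
    stop("invalid read interval: start > end at record ",
         which(start > end)[1L])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand '", strand[bad[1L]], "' at record ", bad[1L])
  if (total_reads < length(start))
    stop("total_reads must be at least the number of records")
  structure(
    data.frame(chrom = rep_len(chrom, length(start)), start = start,
               end = end, strand = strand, stringsAsFactors = FALSE),
    total_reads = as.numeric(total_reads),
    class = c("aligned_reads", "data.frame"))
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat("aligned_reads:", nrow(x), "records on",
      if (nrow(x)) x$chrom[1L] else "(empty)",
      "| library total", attr(x, "total_reads"), "reads\n")
  if (nrow(x)) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read and write aligned reads as BED6
#'
#' On-disk BED is 0-based half-open; in memory everything is 1-based
#' inclusive. The BED score column is unused (written as 0).
#'
#' @param reads An [aligned_reads()] object.
#' @param file Path to a BED file.
#' @param total_reads Library total for RPM scaling (defaults to record count
#'   when reading).
#' @return `read_reads_bed` returns an [aligned_reads()] object;
#'   `write_reads_bed` returns the path invisibly.
#' @name reads_io
NULL

#' @rdname reads_io
#' @export
write_reads_bed <- function(reads, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start, end = reads$end),
    strand = reads$strand)
  S4Vectors::mcols(gr)$name <- if (length(gr)) paste0("read", seq_along(gr)) else character(0)
  S4Vectors::mcols(gr)$score <- rep(0L, length(gr))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname reads_io
#' @export
read_reads_bed <- function(file, total_reads = NULL) {
  gr <- rtracklayer::import(file, format = "BED")
  if (is.null(total_reads)) total_reads <- length(gr)
  if (length(gr) == 0L)
    return(aligned_reads(integer(), integer(), character(),
                         total_reads = total_reads))
  aligned_reads(GenomicRanges::start(gr), GenomicRanges::end(gr),
                as.character(GenomicRanges::strand(gr)),
                chrom = as.character(GenomicRanges::seqnames(gr))[1L],
                total_reads = total_reads)
}

new_coverage_track <- function(values, scale, smoothed = FALSE) {
  structure(as.numeric(values), scale = scale, smoothed = smoothed,
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", attr(x, "scale"),
      if (isTRUE(attr(x, "smoothed"))) ", smoothed" else "",
      "): ", length(x), " bases, total ",
      signif(sum(unclass(x)), 6), "\n", sep = "")
  invisible(x)
}

#' Extend aligned reads to a fixed fragment length
#'
#' Single-end reads are extended to the estimated fragment length (default
#' 100 bp; fragment size estimates fall between 75 and 125 bp), anchored at
#' the 5' end: a `+` strand read keeps its start, a `-` strand read keeps its
#' end. Fragments running off the reference are clipped in linear mode or
#' wrapped around the repeat in circular mode (a wrapped fragment is stored
#' with `start > end`).
#'
#' @param reads An [aligned_reads()] object.
#' @param fragment_length Target fragment length in bp (default 100).
#' @param ref_length Reference (repeat) length in bp.
#' @param circular Wrap (`TRUE`) or clip (`FALSE`, default) at the bounds.
#' @return An [aligned_reads()] object of fixed-length fragments.
#' @export
extend_reads <- function(reads, fragment_length = 100L, ref_length,
                         circular = FALSE) {
  stopifnot(inherits(reads, "aligned_reads"))
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < 1L) stop("fragment_length must be >= 1")
  if (nrow(reads) == 0L) return(reads)
  plus <- reads$strand == "+"
  s <- ifelse(plus, reads$start, reads$end - fragment_length + 1L)
  e <- s + fragment_length - 1L
  if (circular) {
    s <- ((s - 1L) %% ref_length) + 1L
    e <- ((e - 1L) %% ref_length) + 1L
    # s > e now denotes a fragment wrapping the origin
  } else {
    s <- pmax(s, 1L)
    e <- pmin(e, ref_length)
  }
  out <- reads
  out$start <- as.integer(s)
  out$end <- as.integer(e)
  attr(out, "total_reads") <- attr(reads, "total_reads")
  attr(out, "circular") <- circular
  class(out) <- class(reads)
  out
}

#' Per-base fragment coverage
#'
#' Counts, for every base of the reference, the number of fragments
#' overlapping it (the raw coverage `j` of the smoothing equation). Fragments
#' stored with `start > end` are interpreted as wrapping the circular repeat.
#'
#' @param reads An [aligned_reads()] object (normally after [extend_reads()]).
#' @param ref_length Reference length in bp.
#' @return A `coverage_track` (scale `"raw_counts"`) of length `ref_length`,
#'   with the library total carried along as attribute `total_reads`.
#' @export
base_coverage <- function(reads, ref_length) {
  stopifnot(inherits(reads, "aligned_reads"))
  ref_length <- as.integer(ref_length)
  delta <- numeric(ref_length + 1L)
  if (nrow(reads)) {
    s <- reads$start; e <- reads$end
    if (any(s < 1L | e > ref_length))
      stop("read interval outside reference 1..", ref_length)
    wrap <- s > e
    # plain intervals
    if (any(!wrap)) {
      t1 <- tabulate(s[!wrap], nbins = ref_length + 1L)
      t2 <- tabulate(e[!wrap] + 1L, nbins = ref_length + 1L)
      delta <- delta + t1 - t2
    }
    # wrapped intervals cover [s, L] and [1, e]
    if (any(wrap)) {
      t1 <- tabulate(s[wrap], nbins = ref_length + 1L)
      delta <- delta + t1
      delta[1L] <- delta[1L] + sum(wrap)
      t2 <- tabulate(e[wrap] + 1L, nbins = ref_length + 1L)
      delta <- delta - t2
      # the [s, L] part ends at L; its closing -1 falls off the array
    }
  }
  j <- cumsum(delta[seq_len(ref_length)])
  out <- new_coverage_track(j, "raw_counts")
  attr(out, "total_reads") <- attr(reads, "total_reads")
  out
}

#' Smooth a coverage track with a centred window
#'
#' Running mean over an odd window (default 25 bp):
#' `J(n) = (1/w) * sum(j[n-k .. n+k])` with `k = (w-1)/2`. In linear mode the
#' window is truncated at the track ends and the divisor reduced to the
#' number of in-range bases; in circular mode the window wraps, which
#' conserves the track total exactly.
#'
#' @param track A `coverage_track`.
#' @param window Odd window width in bp (default 25).
#' @param circular Wrap the window around the repeat ends.
#' @return A smoothed `coverage_track`.
#' @export
smooth_coverage <- function(track, window = 25L, circular = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be an odd integer >= 1, got ", window)
  x <- unclass(track)
  L <- length(x)
  if (window == 1L) {
    J <- x
  } else if (circular) {
    J <- as.numeric(stats::filter(x, rep(1 / window, window), circular = TRUE))
  } else {
    k <- (window - 1L) %/% 2L
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(L) - k, 1L)
    hi <- pmin(seq_len(L) + k, L)
    J <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out <- new_coverage_track(J, attr(track, "scale"), smoothed = TRUE)
  if (attr(track, "scale") == "raw_counts") attr(out, "scale") <- "smoothed"
  attr(out, "total_reads") <- attr(track, "total_reads")
  out
}

#' Scale a coverage track to reads per million
#'
#' Multiplies every value by `1e6 / total_reads`, where `total_reads` is the
#' total number of aligned reads in the library (not just those on the rDNA
#' chromosome), making ChIP and input tracks comparable across depths.
#'
#' @param track A `coverage_track`.
#' @param total_reads Library total; defaults to the track's `total_reads`
#'   attribute.
#' @return A `coverage_track` with scale `"rpm"`.
#' @export
scale_rpm <- function(track, total_reads = attr(track, "total_reads")) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(total_reads) || is.na(total_reads) || total_reads <= 0)
    stop("total_reads must be > 0 for RPM scaling")
  out <- new_coverage_track(unclass(track) * 1e6 / total_reads, "rpm",
                            smoothed = isTRUE(attr(track, "smoothed")))
  attr(out, "total_reads") <- total_reads
  out
}

#' Input-normalized enrichment track
#'
#' Per-base ratio `Jnorm = Jchip / Jinput` of smoothed, RPM-scaled ChIP and
#' input coverage. The ratio is undefined where input coverage drops out, so
#' bases where the smoothed input RPM falls below a floor (by default 5% of
#' the input track's median) are masked (`NA`) rather than producing inflated
#' or infinite enrichment.
#'
#' @param chip,input Smoothed, RPM-scaled `coverage_track`s of equal length.
#' @param floor_frac Floor as a fraction of the input track median
#'   (default 0.05); ignored when `input_floor` is given.
#' @param input_floor Absolute floor on smoothed input RPM.
#' @return An `enrichment_track`: numeric vector with `NA` at masked bases and
#'   attributes `mask` (logical) and `input_floor`.
#' @export
normalize_to_input <- function(chip, input, floor_frac = 0.05,
                               input_floor = NULL) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (length(chip) != length(input))
    stop("chip and input tracks have different lengths (",
         length(chip), " vs ", length(input), ")")
  for (tr in list(chip, input))
    if (attr(tr, "scale") != "rpm" || !isTRUE(attr(tr, "smoothed")))
      stop("enrichment requires smoothed, RPM-scaled tracks; got scale '",
           attr(tr, "scale"), "'",
           if (!isTRUE(attr(tr, "smoothed"))) " (unsmoothed)" else "")
  iv <- unclass(input)
  if (is.null(input_floor)) input_floor <- floor_frac * stats::median(iv)
  mask <- iv < input_floor | iv <= 0
  values <- ifelse(mask, NA_real_, unclass(chip) / iv)
  structure(values, mask = mask, input_floor = input_floor,
            class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  v <- unclass(x)
  cat("enrichment_track: ", length(v), " bases, ",
      sum(attr(x, "mask")), " masked (input floor ",
      signif(attr(x, "input_floor"), 4), ")\n", sep = "")
  cat("  enrichment range: ", signif(min(v, na.rm = TRUE), 4), " .. ",
      signif(max(v, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Full read-to-enrichment pipeline
#'
#' Runs the fixed stage order extend -> coverage -> smooth -> RPM -> input
#' ratio for one ChIP library against its matched input.
#'
#' @param chip_reads,input_reads [aligned_reads()] objects.
#' @param ref_length Repeat length in bp.
#' @param fragment_length Extension length (default 100 bp).
#' @param window Smoothing window (default 25 bp, odd).
#' @param circular Treat the repeat as circular (default linear, matching a
#'   single-copy extra chromosome in a genome reference).
#' @param floor_frac Input floor fraction for [normalize_to_input()].
#' @return An `enrichment_track`.
#' @export
enrichment_pipeline <- function(chip_reads, input_reads, ref_length,
                                fragment_length = 100L, window = 25L,
                                circular = FALSE, floor_frac = 0.05) {
  one <- function(reads) {
    fr <- extend_reads(reads, fragment_length, ref_length, circular = circular)
    cov <- base_coverage(fr, ref_length)
    sm <- smooth_coverage(cov, window, circular = circular)
    scale_rpm(sm)
  }
  normalize_to_input(one(chip_reads), one(input_reads), floor_frac = floor_frac)
}

#' Write a per-base track as bedGraph
#'
#' Consecutive equal values are collapsed into single bedGraph intervals;
#' masked (`NA`) bases are omitted from the bedGraph and can be emitted as a
#' companion BED of masked intervals with `write_mask_bed`.
#'
#' @param track A `coverage_track` or `enrichment_track` (or plain numeric).
#' @param file Output path.
#' @param chrom Chromosome name.
#' @return The path, invisibly.
#' @export
write_track_bedgraph <- function(track, file, chrom = "rDNA") {
  v <- as.numeric(unclass(track))
  r <- rle(ifelse(is.na(v), Inf, v))  # Inf sentinel keeps NA runs distinct
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- is.finite(r$values)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_track_bedgraph
#' @export
write_mask_bed <- function(track, file, chrom = "rDNA") {
  stopifnot(inherits(track, "enrichment_track"))
  m <- attr(track, "mask")
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    # empty BED
    file.create(file)
    return(invisible(file))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Read a bedGraph into a per-base track vector
#'
#' Bases not covered by any bedGraph interval are returned as `NA`.
#'
#' @param file A bedGraph path.
#' @param ref_length Reference length in bp.
#' @return Numeric vector of length `ref_length`.
#' @export
read_track_bedgraph <- function(file, ref_length) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  v <- rep(NA_real_, ref_length)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) v[s[i]:e[i]] <- gr$score[i]
  v
}

#' Coerce a numeric vector to an enrichment track
#'
#' Mainly for constructing noiseless ground-truth enrichment profiles; `NA`
#' values become masked bases.
#'
#' @param values Numeric vector of per-base enrichment (NA = masked).
#' @return An `enrichment_track`.
#' @export
as_enrichment_track <- function(values) {
  structure(as.numeric(values), mask = is.na(values), input_floor = 0,
            class = "enrichment_track")
}
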