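#' Summarize enrichment over an annotated feature
#'
#' Mean and maximum input-normalized enrichment over the unmasked bases of a
#' feature interval, plus the feature's share of the total reference signal
#' (sum of enrichment over the feature divided by the sum over the whole
#' track). Intervals with `start > end` wrap the repeat origin.
#'
#' @param enrichment An `enrichment_track`.
#' @param start,end Feature interval in track coordinates (1-based,
#'   inclusive; `start > end` wraps).
#' @param name Optional feature name carried into the result.
#' @return A one-row data frame with `name`, `mean`, `max`,
#'   `signal_fraction`, `n_bases`, `n_masked`.
#' @export
summarize_feature <- function(enrichment, start, end, name = NA_character_) {
  v <- as.numeric(unclass(enrichment))
  pos <- interval_positions(start, end, length(v))
  y <- v[pos]
  if (all(is.na(y)))
    stop("feature ", if (!is.na(name)) name else paste0(start, "-", end),
         " is fully masked")
  tot <- sum(v, na.rm = TRUE)
  data.frame(
    name = name,
    mean = mean(y, na.rm = TRUE),
    max = max(y, na.rm = TRUE),
    signal_fraction = if (tot > 0) sum(y, na.rm = TRUE) / tot else NA_real_,
    n_bases = length(y),
    n_masked = sum(is.na(y)),
    stringsAsFactors = FALSE)
}

#' Summarize enrichment over a feature table
#'
#' @param enrichment An `enrichment_track` in the displaced frame.
#' @param features A feature data frame in native coordinates (see
#'   [rdna_features()]).
#' @param cs An [rdna_coords()] object used to remap the features onto the
#'   track; pass `NULL` if `features` is already in track coordinates.
#' @return A data frame with one row per feature.
#' @export
feature_summary_table <- function(enrichment, features, cs = NULL) {
  if (!is.null(cs)) features <- remap_features(features, cs)
  do.call(rbind, lapply(seq_len(nrow(features)), function(i)
    summarize_feature(enrichment, features$start[i], features$end[i],
                      name = features$name[i])))
}

#' Locate an enrichment peak near an anchor position
#'
#' Returns the position of the maximum of the (already smoothed) enrichment
#' within a bounded window around a named anchor, with ties broken toward the
#' anchor. Offsets are signed: positive values are downstream of the anchor.
#' No sub-bp interpolation is attempted.
#'
#' @param enrichment An `enrichment_track`.
#' @param anchor 1-based anchor position (e.g. an initiation site).
#' @param window Two-element window around the anchor in bp
#'   (default `c(-200, 200)`).
#' @return An object of class `peak_call`: list with `position`, `offset`,
#'   `height`, `anchor`.
#' @export
find_peak <- function(enrichment, anchor, window = c(-200L, 200L)) {
  v <- as.numeric(unclass(enrichment))
  pos <- anchor + seq.int(window[1L], window[2L])
  pos <- pos[pos >= 1L & pos <= length(v)]
  if (!length(pos)) stop("peak search window is empty")
  y <- v[pos]
  if (all(is.na(y))) stop("peak search window is fully masked")
  m <- max(y, na.rm = TRUE)
  cand <- pos[!is.na(y) & y == m]
  # ties broken toward the anchor; the residual two-way tie (symmetric
  # candidates) resolves to the upstream one for determinism
  cand <- cand[order(abs(cand - anchor), cand - anchor)]
  p <- cand[1L]
  structure(list(position = p, offset = p - anchor, height = m,
                 anchor = anchor, window = window), class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("peak at position %d (offset %+d bp from anchor %d), height %.4g\n",
              x$position, x$offset, x$anchor, x$height))
  invisible(x)
}

#' Locate multiple local maxima near an anchor
#'
#' Finds strict local maxima of the enrichment in the window (a point higher
#' than its immediate neighbours, with plateaus reduced to their
#' anchor-nearest base) and returns the `n` highest.
#'
#' @inheritParams find_peak
#' @param n Maximum number of peaks to return.
#' @param min_separation Minimum distance between reported peaks in bp.
#' @return A data frame with `position`, `offset`, `height`, ordered by
#'   height.
#' @export
find_local_maxima <- function(enrichment, anchor, window = c(-200L, 200L),
                              n = 2L, min_separation = 10L) {
  v <- as.numeric(unclass(enrichment))
  pos <- anchor + seq.int(window[1L], window[2L])
  pos <- pos[pos >= 2L & pos <= length(v) - 1L]
  y <- v[pos]
  left <- v[pos - 1L]; right <- v[pos + 1L]
  is_max <- !is.na(y) & !is.na(left) & !is.na(right) & y >= left & y >= right &
    (y > left | y > right)
  cand <- data.frame(position = pos[is_max], height = y[is_max])
  cand <- cand[order(-cand$height, abs(cand$position - anchor)), ]
  picked <- integer()
  for (i in seq_len(nrow(cand))) {
    if (all(abs(cand$position[i] - picked) >= min_separation)) {
      picked <- c(picked, cand$position[i])
      if (length(picked) >= n) break
    }
  }
  out <- cand[match(picked, cand$position), ]
  out$offset <- out$position - anchor
  rownames(out) <- NULL
  out[, c("position", "offset", "height")]
}

#' Enrichment ratio between two features
#'
#' Single-track form: `mean(track over f1) / mean(track over f2)`, e.g. the
#' histone H3 gene-body to IGS ratio. Paired form (when `trackB` is given):
#' `(mean A over f1 / mean B over f1) / (mean A over f2 / mean B over f2)`,
#' e.g. the Rrn3:RPI ratio at the Spacer Promoter relative to the 47S
#' promoter; any common scale factor between the tracks cancels.
#'
#' @param trackA An `enrichment_track`.
#' @param f1,f2 Feature intervals as `c(start, end)` in track coordinates
#'   (wrap allowed).
#' @param trackB Optional second `enrichment_track` for the paired form.
#' @return A single ratio.
#' @export
feature_ratio <- function(trackA, f1, f2, trackB = NULL) {
  m <- function(tr, f) summarize_feature(tr, f[1L], f[2L])$mean
  a1 <- m(trackA, f1); a2 <- m(trackA, f2)
  if (is.null(trackB)) {
    if (a2 == 0) stop("zero denominator: second feature has zero mean enrichment")
    return(a1 / a2)
  }
  b1 <- m(trackB, f1); b2 <- m(trackB, f2)
  if (b1 == 0 || a2 == 0 || b2 == 0)
    stop("zero denominator in paired feature ratio")
  (a1 / b1) / (a2 / b2)
}
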