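#' Synthetic rDNA ChIP-Seq scenarios with known ground truth
#'
#' A scenario fixes everything the pipeline consumes: the repeat length and
#' coordinate system, per-factor ground-truth occupancy profiles over the
#' displaced frame, a positive sequence-derived bias field shared by ChIP and
#' matched input libraries, the active/inactive repeat mixture for histone
#' tracks, the fragment-length range, and a synthetic repeat sequence whose
#' windowed GC content generates the bias. Factor profiles are built from
#' piecewise-constant segments, Gaussian point sources with a footprint
#' width, and exponential decay segments.
#'
#' @param profiles Named list of occupancy profiles: each either a numeric
#'   vector of length `length`, or a list with `active`, `inactive` numeric
#'   profiles for per-read mixture sampling.
#' @param cs An [rdna_coords()] object.
#' @param tss Displaced-frame position of the 47S initiation site.
#' @param spacer_tss Displaced-frame position of the Spacer Promoter
#'   initiation site.
#' @param features Feature table in native coordinates.
#' @param sequence Repeat sequence (character); generated if `NULL`.
#' @param bias Positive per-base bias field; derived from the sequence GC
#'   content when `NULL`.
#' @param bias_range Approximate fold-range of the sequence bias field
#'   (default 3; set 1 for no bias).
#' @param active_fraction Mixture weight of active repeats in `[0, 1]`.
#' @param fragment_range Fragment length range sampled uniformly
#'   (default 75-125 bp).
#' @param chrom Chromosome name used in emitted BED files.
#' @param seed Seed used for sequence generation.
#' @param ground_truth Named list of true parameter values carried along for
#'   assertions.
#' @return An object of class `rdna_scenario`.
#' @seealso [mef_scenario()] for the preset MEF scenarios,
#'   [sample_reads()], [simulate_gel_trace()].
#' @export
rdna_scenario <- function(profiles, cs = rdna_coords(), tss = 14815L,
                          spacer_tss = NULL, features = rdna_features(),
                          sequence = NULL, bias = NULL, bias_range = 3,
                          active_fraction = 0.64,
                          fragment_range = c(75L, 125L), chrom = "rDNA",
                          seed = NULL, ground_truth = list()) {
  L <- cs$length
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    vs <- if (is.list(p)) p else list(p)
    for (v in vs) {
      if (length(v) != L) stop("profile '", nm, "' has length ", length(v),
                               ", expected ", L)
      if (any(v < 0)) stop("profile '", nm, "' has negative occupancy")
    }
  }
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0, 1]")
  if (is.null(sequence))
    sequence <- simulate_repeat_sequence(L, seed = seed)
  if (is.null(bias))
    bias <- bias_from_sequence(sequence, fold_range = bias_range)
  if (length(bias) != L || any(bias <= 0))
    stop("bias field must be positive and of reference length")
  structure(list(
    cs = cs, length = L, tss = as.integer(tss),
    spacer_tss = if (is.null(spacer_tss)) NA_integer_ else as.integer(spacer_tss),
    features = features, profiles = profiles, sequence = sequence,
    bias = bias, active_fraction = active_fraction,
    fragment_range = as.integer(fragment_range), chrom = chrom,
    ground_truth = ground_truth), class = "rdna_scenario")
}

#' @export
print.rdna_scenario <- function(x, ...) {
  cat("Synthetic rDNA scenario\n")
  cat("  repeat:", x$length, "bp; TSS at", x$tss,
      "(displaced frame); active fraction", x$active_fraction, "\n")
  cat("  factors:", paste(names(x$profiles), collapse = ", "), "\n")
  cat("  bias field range:",
      signif(max(x$bias) / min(x$bias), 3), "fold\n")
  invisible(x)
}

#' Gaussian point-source occupancy profile
#'
#' Footprint-width point source used for bound factors (TTF1, stalled
#' polymerase, CTCF, promoter complexes): a Gaussian density whose standard
#' deviation is a quarter of the footprint width, so about 95% of crosslinks
#' fall within the footprint.
#'
#' @param length Profile length in bp.
#' @param center Source position.
#' @param footprint Footprint width in bp (default 50).
#' @param weight Integrated occupancy mass of the source.
#' @return Numeric profile of length `length`.
#' @export
point_source_profile <- function(length, center, footprint = 50, weight = 1) {
  s <- footprint / 4
  x <- seq_len(length)
  weight * exp(-(x - center)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

#' Synthetic repeat sequence with a windowed GC design
#'
#' Samples a random sequence whose per-base GC probability follows a smooth
#' target profile: a baseline plus a raised-GC plateau over the gene-body
#' segment and a long-period sinusoidal modulation (the mouse rDNA gene body
#' is GC-rich relative to the IGS). The resulting 50-bp windowed GC profile
#' correlates with the UBF-bound domain the way the real repeat's does.
#'
#' @param length Sequence length (bp).
#' @param gc_base Baseline GC probability (default 0.45).
#' @param gc_gene_boost Extra GC probability over the gene-body segment
#'   (default 0.12).
#' @param gene_body Displaced-frame interval of the gene-rich segment.
#' @param wave_amp,wave_period Sinusoidal modulation amplitude and period.
#' @param seed Optional integer seed.
#' @return A character string over A/C/G/T.
#' @export
simulate_repeat_sequence <- function(length, gc_base = 0.45,
                                     gc_gene_boost = 0.12,
                                     gene_body = c(14815L, 28214L),
                                     wave_amp = 0.05, wave_period = 2000,
                                     seed = NULL) {
  with_seed(seed, {
    x <- seq_len(length)
    p <- gc_base + wave_amp * sin(2 * pi * x / wave_period)
    body <- x >= gene_body[1L] & x <= min(gene_body[2L], length)
    p[body] <- p[body] + gc_gene_boost
    p <- pmin(pmax(p, 0.05), 0.95)
    isgc <- stats::rbinom(length, 1L, p) == 1L
    b <- character(length)
    b[isgc] <- sample(c("G", "C"), sum(isgc), replace = TRUE)
    b[!isgc] <- sample(c("A", "T"), sum(!isgc), replace = TRUE)
    paste(b, collapse = "")
  })
}

#' Sequence-derived multiplicative coverage bias field
#'
#' Real rDNA libraries show strong but reproducible sequence-dependent
#' coverage bias shared between ChIP and input samples. This emulates it as a
#' smooth positive field driven by local GC content: the windowed GC profile
#' is smoothed, standardized, and mapped through an exponential so the field
#' spans roughly `fold_range` between its low and high ends.
#'
#' @param sequence Repeat sequence (character).
#' @param fold_range Approximate max/min ratio of the field (default 3);
#'   1 gives a flat field.
#' @param smooth_window Smoothing window for the per-base GC signal (bp).
#' @return Positive numeric vector of per-base bias.
#' @export
bias_from_sequence <- function(sequence, fold_range = 3, smooth_window = 201L) {
  L <- nchar(sequence)
  if (fold_range <= 1) return(rep(1, L))
  base <- strsplit(sequence, "")[[1L]]
  gc <- as.numeric(base %in% c("G", "C"))
  sm <- as.numeric(stats::filter(gc, rep(1 / smooth_window, smooth_window),
                                 circular = TRUE))
  z <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12)
  z <- pmin(pmax(z, -2), 2)
  exp(z * log(fold_range) / 4)
}

#' Preset MEF scenarios
#'
#' Builds a fully specified scenario for the wild-type (`"WT"`) MEF state or
#' the factor-deletion states (`"Rrn3-KO"`, `"UBF-KO"`), encoding the
#' occupancy geography of the mouse rDNA repeat:
#'
#' * RPI: uniform across the 47S transcribed region ending at the T1-T10
#'   terminators, a pre-initiation peak at the 47S promoter, and a stalled
#'   point source 24 bp downstream of the Spacer Promoter initiation site.
#' * Rrn3: exponential release decay downstream of the 47S TSS with
#'   ground-truth half-life 15 s at an elongation rate of 60 nt/s (decay
#'   length `15 * 60 / ln 2` = 1298.3 bp), a PIC peak at the promoter, and a
#'   ten-fold-reduced presence at the stalled Spacer Promoter polymerase.
#' * TTF1: point sources at the Spacer terminator Tsp (13 bp downstream of
#'   the stalled RPI peak), at T0 near the 47S promoter, and at the T1-T10
#'   cluster with a preference for T1/T2.
#' * UBF: continuous occupancy from the Spacer Promoter through the gene
#'   body up to the first terminators; none over the IGS.
#' * SL1: pre-initiation complex peaks at both promoters.
#' * H3 (and H3K9me3 alike): a per-read active/inactive mixture. Active
#'   repeats (weight `active_fraction`, default 0.64) carry histone only over
#'   the IGS; inactive repeats are nucleosomal throughout.
#' * CTCF: a boundary point source upstream of the Spacer Promoter, retained
#'   in every preset.
#' * input: uniform occupancy (the bias field alone shapes its coverage).
#'
#' `"Rrn3-KO"` suppresses RPI and Rrn3 to a 2% remnant (escaper cells) while
#' leaving UBF, SL1 and TTF1 unchanged. `"UBF-KO"` removes UBF, RPI, Rrn3
#' and SL1, suppresses TTF1 at the upstream Tsp/T0 sites while retaining the
#' terminator cluster, keeps CTCF, and makes the histone mixture fully
#' inactive (nucleosomal throughout).
#'
#' @param preset One of `"WT"`, `"Rrn3-KO"`, `"UBF-KO"`.
#' @param half_life Ground-truth Rrn3 release half-life in seconds
#'   (default 15).
#' @param elongation_rate Elongation rate in nt/s (default 60).
#' @param active_fraction Active repeat fraction (default 0.64; forced to 0
#'   by `"UBF-KO"`).
#' @param footprint Point-source footprint width in bp (default 50).
#' @param bias_range Fold-range of the shared sequence bias field
#'   (default 3; 1 disables bias).
#' @param cs Coordinate system (default the BK000964v3 geometry).
#' @param seed Seed for sequence generation.
#' @return An `rdna_scenario`.
#' @export
mef_scenario <- function(preset = c("WT", "Rrn3-KO", "UBF-KO"),
                         half_life = 15, elongation_rate = 60,
                         active_fraction = 0.64, footprint = 50,
                         bias_range = 3, cs = rdna_coords(), seed = NULL) {
  preset <- tryCatch(match.arg(preset), error = function(e)
    stop("unknown preset '", preset[1L],
         "'; available presets: WT, Rrn3-KO, UBF-KO"))
  L <- cs$length
  d <- function(native) remap_position(((native - 1L) %% L) + 1L, cs)

  tss <- d(1L)              # 14815 in the default geometry
  sp_tss <- d(43200L)       # Spacer Promoter initiation site (synthetic)
  sp_rpi <- sp_tss + 24L    # stalled polymerase peak
  sp_ttf <- sp_rpi + 13L    # Tsp TTF1 peak
  body_end <- d(13400L)     # last base of the 47S transcribed region
  ubf_start <- d(43089L)    # SpPr start
  ctcf <- d(43020L)
  t0 <- d(45120L)
  t_sites <- vapply(13417L + 30L * (0:9), d, integer(1L))  # T1..T10
  igs <- c(d(13701L), d(42645L))  # displaced-frame interval (may wrap)

  Lc <- half_life * elongation_rate / log(2)
  x <- seq_len(L)
  seg <- function(from, to) as.numeric(x >= from & x <= to)
  ps <- function(center, weight = 1)
    point_source_profile(L, center, footprint = footprint, weight = weight)

  body <- seg(tss, body_end)

  rpi <- body + ps(tss, weight = 30) + ps(sp_rpi, weight = 150)
  rrn3 <- ifelse(body > 0, exp(-(x - tss) / Lc), 0) +
    ps(tss, weight = 30) + ps(sp_rpi, weight = 15)
  ubf <- if (ubf_start <= body_end) seg(ubf_start, body_end)
         else seg(ubf_start, L) + seg(1L, body_end)
  sl1 <- ps(tss, weight = 40) + ps(sp_tss, weight = 40)
  ttf1 <- ps(sp_ttf, weight = 60) + ps(t0, weight = 40) +
    Reduce(`+`, Map(function(p, w) ps(p, weight = w), as.list(t_sites),
                    as.list(c(60, 50, rep(25, 8)))))
  ctcf_p <- ps(ctcf, weight = 60)
  igs_prof <- if (igs[1L] <= igs[2L]) seg(igs[1L], igs[2L])
              else seg(igs[1L], L) + seg(1L, igs[2L])
  h3 <- list(active = igs_prof, inactive = rep(1, L))

  if (preset == "Rrn3-KO") {
    rpi <- 0.02 * rpi
    rrn3 <- 0.02 * rrn3
  } else if (preset == "UBF-KO") {
    rpi <- rpi * 0; rrn3 <- rrn3 * 0; ubf <- ubf * 0; sl1 <- sl1 * 0
    ttf1 <- Reduce(`+`, Map(function(p, w) ps(p, weight = w),
                            as.list(t_sites),
                            as.list(c(30, 25, rep(30, 8)))))
    active_fraction <- 0
  }

  profiles <- list(RPI = rpi, Rrn3 = rrn3, UBF = ubf, SL1 = sl1,
                   TTF1 = ttf1, CTCF = ctcf_p, H3 = h3,
                   input = rep(1, L))

  rdna_scenario(
    profiles = profiles, cs = cs, tss = tss, spacer_tss = sp_tss,
    sequence = NULL, bias_range = bias_range,
    active_fraction = active_fraction, seed = seed,
    ground_truth = list(
      preset = preset, half_life_s = half_life,
      elongation_rate = elongation_rate, decay_length_bp = Lc,
      active_fraction = active_fraction,
      tss = tss, spacer_tss = sp_tss,
      spacer_rpi_offset = 24L, spacer_ttf1_offset = 37L,
      footprint = footprint, bias_range = bias_range))
}

#' Sample a seeded synthetic read library from a scenario
#'
#' For each read a crosslink position is drawn with probability proportional
#' to `occupancy * bias` (for the input library, to the bias field alone),
#' a fragment length is drawn uniformly from the scenario's range, and the
#' fragment is placed uniformly among the positions covering the crosslink
#' point. Strands are Bernoulli(1/2); the BED record stores the fragment and
#' its strand, whose 5' end the pipeline later re-extends. Mixture factors
#' (histones) draw each read from the active or inactive repeat profile with
#' probability `active_fraction`. Sampling is deterministic given the seed.
#'
#' @param scenario An `rdna_scenario`.
#' @param factor Name of a scenario profile, or `"input"`.
#' @param depth Number of reads to draw (>= 0).
#' @param seed Optional integer seed.
#' @param total_reads Library total used for RPM (defaults to `depth`,
#'   i.e. a library aligning entirely to the rDNA chromosome).
#' @param circular Wrap fragments around the repeat ends (`TRUE`) or clip
#'   them at the reference bounds (`FALSE`, default, matching alignment to a
#'   linear extra chromosome). Wrapped fragments are stored with
#'   `start > end`.
#' @return An [aligned_reads()] object.
#' @export
sample_reads <- function(scenario, factor, depth, seed = NULL,
                         total_reads = depth, circular = FALSE) {
  stopifnot(inherits(scenario, "rdna_scenario"))
  if (!factor %in% names(scenario$profiles))
    stop("unknown factor '", factor, "'; scenario has: ",
         paste(names(scenario$profiles), collapse = ", "))
  depth <- as.integer(depth)
  if (depth < 0L) stop("depth must be >= 0")
  L <- scenario$length
  if (depth == 0L)
    return(aligned_reads(integer(), integer(), character(),
                         chrom = scenario$chrom, total_reads = total_reads))
  prof <- scenario$profiles[[factor]]
  with_seed(seed, {
    if (is.list(prof)) {
      wa <- prof$active * scenario$bias
      wi <- prof$inactive * scenario$bias
      if (sum(wa) <= 0 && scenario$active_fraction > 0 ||
          sum(wi) <= 0 && scenario$active_fraction < 1)
        stop("all-zero sampling weights for mixture factor '", factor, "'")
      # a read is a fragment of occupancy-bound DNA, so the chance it comes
      # from an active repeat is the active fraction weighted by that state's
      # total occupancy-bias mass (sampling from the population-average
      # profile active_fraction*phi_a + (1-active_fraction)*phi_i)
      pa <- scenario$active_fraction * sum(wa) /
        (scenario$active_fraction * sum(wa) +
           (1 - scenario$active_fraction) * sum(wi))
      na <- stats::rbinom(1L, depth, pa)
      cross <- c(
        if (na > 0L) sample.int(L, na, replace = TRUE, prob = wa),
        if (depth - na > 0L) sample.int(L, depth - na, replace = TRUE, prob = wi))
      cross <- sample(cross)  # shuffle so record order carries no state label
    } else {
      w <- prof * scenario$bias
      if (sum(w) <= 0)
        stop("all-zero sampling weights for factor '", factor, "'")
      cross <- sample.int(L, depth, replace = TRUE, prob = w)
    }
    len <- sample(seq.int(scenario$fragment_range[1L],
                          scenario$fragment_range[2L]),
                  depth, replace = TRUE)
    offset <- floor(stats::runif(depth) * len)  # uniform over covering placements
    start <- cross - offset
    end <- start + len - 1L
    if (circular) {
      start <- ((start - 1L) %% L) + 1L
      end <- ((end - 1L) %% L) + 1L
    } else {
      start <- pmax(start, 1L)
      end <- pmin(end, L)
    }
    strand <- ifelse(stats::runif(depth) < 0.5, "+", "-")
    reads <- aligned_reads(pmin(start, end), pmax(start, end), strand,
                           chrom = scenario$chrom, total_reads = total_reads)
    if (circular) {
      # restore the wrap convention destroyed by the pmin/pmax validity check
      reads$start <- as.integer(start)
      reads$end <- as.integer(end)
    }
    reads
  })
}

#' Simulate a psoralen gel lane trace
#'
#' Two Gaussian bands with area ratio `active : (1 - active)`, the
#' low-mobility (smaller migration coordinate) band being the active one,
#' plus a sloping linear baseline and seeded Gaussian intensity noise scaled
#' to the clean profile maximum.
#'
#' @param active_fraction Ground-truth active fraction in `[0, 1]`.
#' @param n_points Number of trace samples (default 300).
#' @param centers Migration centers of the active and inactive bands
#'   (default 0.40 and 0.60 on a 0..1 axis; 4 sigma apart at the default
#'   width).
#' @param sigma Common band width (default 0.05).
#' @param total_area Total band area (default 1).
#' @param baseline Intercept and slope of the linear background.
#' @param noise_sd Gaussian noise SD as a fraction of the clean profile
#'   maximum (default 0.02, i.e. 2% intensity noise).
#' @param seed Optional integer seed.
#' @return A data frame with `position` and `intensity`.
#' @export
simulate_gel_trace <- function(active_fraction, n_points = 300L,
                               centers = c(0.40, 0.60), sigma = 0.05,
                               total_area = 1, baseline = c(0.2, 0.3),
                               noise_sd = 0.02, seed = NULL) {
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  x <- seq(0, 1, length.out = n_points)
  clean <- baseline[1L] + baseline[2L] * x +
    total_area * active_fraction * stats::dnorm(x, centers[1L], sigma) +
    total_area * (1 - active_fraction) * stats::dnorm(x, centers[2L], sigma)
  noise <- with_seed(seed,
    stats::rnorm(n_points, sd = noise_sd * max(clean)))
  data.frame(position = x, intensity = clean + noise)
}

#' Persist and reload scenario ground truth
#'
#' The scenario's ground-truth parameters round-trip losslessly through JSON
#' so that generated datasets can be checked against them later.
#'
#' @param scenario An `rdna_scenario`.
#' @param file JSON path.
#' @return `read_ground_truth` returns the named list; the writer returns the
#'   path invisibly.
#' @export
write_ground_truth <- function(scenario, file) {
  jsonlite::write_json(scenario$ground_truth, file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Write every input a pipeline run needs from a scenario
#'
#' Emits the repeat FASTA, the feature table (TSV, native coordinates, and
#' BED6), per-factor read BED files, a matched input BED, and the
#' ground-truth JSON.
#'
#' @param scenario An `rdna_scenario`.
#' @param dir Output directory (created if needed).
#' @param factors Which factor libraries to emit (default all non-input).
#' @param depth Reads per library.
#' @param seed Integer seed; library `k` uses `seed + k`.
#' @return Named list of written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir, factors = NULL, depth = 50000L,
                           seed = 1L) {
  stopifnot(inherits(scenario, "rdna_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(factors))
    factors <- setdiff(names(scenario$profiles), "input")
  paths <- list()
  fa <- Biostrings::DNAStringSet(scenario$sequence)
  names(fa) <- scenario$chrom
  paths$fasta <- file.path(dir, "repeat.fa")
  Biostrings::writeXStringSet(fa, paths$fasta)
  paths$features_tsv <- write_features_tsv(scenario$features,
                                           file.path(dir, "features.tsv"))
  paths$features_bed <- write_features_bed(scenario$features,
                                           file.path(dir, "features.bed"),
                                           length = scenario$length,
                                           chrom = scenario$chrom)
  for (k in seq_along(factors)) {
    f <- factors[k]
    reads <- sample_reads(scenario, f, depth, seed = seed + k)
    paths[[paste0("reads_", f)]] <-
      write_reads_bed(reads, file.path(dir, paste0(f, ".bed")))
  }
  input <- sample_reads(scenario, "input", depth,
                        seed = seed + length(factors) + 1L)
  paths$reads_input <- write_reads_bed(input, file.path(dir, "input.bed"))
  paths$ground_truth <- write_ground_truth(scenario,
                                           file.path(dir, "ground_truth.json"))
  invisible(paths)
}
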