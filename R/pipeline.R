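#' Validated pipeline run configuration
#'
#' Collects the paths and parameters of a full occupancy-mapping run and
#' validates them before any compute: missing files and out-of-range
#' parameters (e.g. an even smoothing window) are rejected here. The
#' configuration round-trips through YAML, and every numeric that influences
#' the outputs is an explicit field, so a run report is fully traceable.
#'
#' @param reads Path to the ChIP read BED file.
#' @param input Path to the matched input BED file.
#' @param out_dir Output directory.
#' @param features Optional feature TSV (native coordinates); `NULL` uses
#'   [rdna_features()].
#' @param ref_length Repeat length in bp.
#' @param origin Displaced-origin native position.
#' @param fragment_length Read extension length (bp).
#' @param window Smoothing window (odd, bp).
#' @param input_floor_frac Input mask floor as fraction of input median.
#' @param circular Treat the repeat as circular.
#' @param tss Displaced-frame TSS for the kinetics fit; `NA` skips kinetics.
#' @param fit_start,fit_end Kinetics fit window (bp downstream of TSS).
#' @param elongation_rate Elongation rate (nt/s) for the half-life.
#' @param chip_total,input_total Library totals for RPM; `NULL` uses the
#'   read counts.
#' @param chrom Chromosome name for emitted tracks.
#' @param seed Run seed recorded in the report.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(reads, input, out_dir, features = NULL,
                            ref_length = 45306L, origin = 30493L,
                            fragment_length = 100L, window = 25L,
                            input_floor_frac = 0.05, circular = FALSE,
                            tss = 14815L, fit_start = 200L, fit_end = 6000L,
                            elongation_rate = 60, chip_total = NULL,
                            input_total = NULL, chrom = "rDNA", seed = 1L) {
  for (f in c(reads, input, features))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  if (window %% 2L == 0L || window < 1L)
    stop("smoothing window must be an odd integer >= 1, got ", window)
  if (fragment_length < 1L) stop("fragment_length must be >= 1")
  if (input_floor_frac < 0) stop("input_floor_frac must be >= 0")
  if (!is.na(tss)) {
    if (tss < 1L || tss > ref_length) stop("tss outside reference")
    if (fit_start >= fit_end) stop("fit_start must be < fit_end")
    if (elongation_rate <= 0) stop("elongation_rate must be > 0")
  }
  structure(list(
    reads = reads, input = input, out_dir = out_dir, features = features,
    ref_length = as.integer(ref_length), origin = as.integer(origin),
    fragment_length = as.integer(fragment_length), window = as.integer(window),
    input_floor_frac = input_floor_frac, circular = circular,
    tss = as.integer(tss), fit_start = as.integer(fit_start),
    fit_end = as.integer(fit_end), elongation_rate = elongation_rate,
    chip_total = chip_total, input_total = input_total,
    chrom = chrom, seed = as.integer(seed)), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("rdnamap run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(v)) "(default)" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param file YAML path.
#' @return `read_config` returns a validated `run_config`; the writer returns
#'   the path invisibly.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1L))]
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(pipeline_config, x)
}

#' Run the full occupancy-mapping pipeline
#'
#' Executes the fixed stage order (extend -> coverage -> smooth -> RPM ->
#' input normalization) for a ChIP library against its matched input, writes
#' raw/smoothed/RPM/enrichment bedGraphs plus a mask BED, summarizes
#' enrichment per annotated feature, optionally fits the exponential release
#' kinetics downstream of the TSS, and writes a JSON run report listing every
#' artifact together with the parameters that produced it. Identical
#' configuration and inputs give byte-identical outputs.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, the run report as a named list (also written to
#'   `report.json` in the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  L <- config$ref_length
  chip <- read_reads_bed(config$reads, total_reads = config$chip_total)
  input <- read_reads_bed(config$input, total_reads = config$input_total)

  stage <- function(reads) {
    fr <- extend_reads(reads, config$fragment_length, L,
                       circular = config$circular)
    cov <- base_coverage(fr, L)
    sm <- smooth_coverage(cov, config$window, circular = config$circular)
    list(raw = cov, smoothed = sm, rpm = scale_rpm(sm))
  }
  ch <- stage(chip)
  inp <- stage(input)
  enr <- normalize_to_input(ch$rpm, inp$rpm,
                            floor_frac = config$input_floor_frac)

  out <- function(name) file.path(config$out_dir, name)
  files <- list(
    chip_raw = write_track_bedgraph(ch$raw, out("chip_raw.bedgraph"), config$chrom),
    chip_smoothed = write_track_bedgraph(ch$smoothed, out("chip_smoothed.bedgraph"), config$chrom),
    chip_rpm = write_track_bedgraph(ch$rpm, out("chip_rpm.bedgraph"), config$chrom),
    input_rpm = write_track_bedgraph(inp$rpm, out("input_rpm.bedgraph"), config$chrom),
    enrichment = write_track_bedgraph(enr, out("enrichment.bedgraph"), config$chrom),
    mask = write_mask_bed(enr, out("mask.bed"), config$chrom))

  cs <- rdna_coords(L, config$origin)
  feats <- if (is.null(config$features)) rdna_features()
           else read_features_tsv(config$features)
  summ <- feature_summary_table(enr, feats, cs)
  files$feature_summary <- out("feature_summary.tsv")
  utils::write.table(summ, files$feature_summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  kin <- NULL
  if (!is.na(config$tss)) {
    fit <- fit_release_kinetics(enr, config$tss, config$fit_start,
                                config$fit_end)
    kin <- list(amplitude = fit$amplitude, decay_length_bp = fit$decay_length,
                baseline = fit$baseline, residual_rms = fit$residual_rms,
                no_decay = fit$no_decay)
    if (!fit$no_decay) {
      est <- half_life(fit, config$elongation_rate)
      kin$half_life_s <- est$half_life_s
      kin$half_distance_bp <- est$half_distance_bp
    }
    files$kinetics <- out("kinetics.json")
    jsonlite::write_json(kin, files$kinetics, auto_unbox = TRUE, digits = NA)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("rdnamap")),
    parameters = unclass(config)[c("ref_length", "origin", "fragment_length",
                                   "window", "input_floor_frac", "circular",
                                   "tss", "fit_start", "fit_end",
                                   "elongation_rate", "seed")],
    inputs = list(reads = config$reads, input = config$input,
                  chip_records = nrow(chip), input_records = nrow(input),
                  chip_total = attr(chip, "total_reads"),
                  input_total = attr(input, "total_reads")),
    masked_bases = sum(attr(enr, "mask")),
    kinetics = kin,
    artifacts = files)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
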