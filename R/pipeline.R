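# End-to-end pipeline wiring: configuration validation, the
# count -> normalize -> segment -> z-score chain, and report output.
# The command-line entry point (exec/plasmacnv) is a thin wrapper over
# these functions.

#' Validate a pipeline configuration
#'
#' @param config Named list (or path to a flat key-value JSON file)
#'   with: `reference` (FASTA), `windows` (windows BED from
#'   [write_windows()]), `sample` (SAM/BAM), `controls` (character
#'   vector of SAM/BAM paths), `out_dir`, and optional parameters
#'   `span`, `alpha`, `n_permutations`, `min_mapq`, `seed`, `bin_size`,
#'   `sex`, `sample_id`.
#' @return The validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(span = 0.3, alpha = 0.01, n_permutations = 10000L,
                   min_mapq = 0L, seed = 1L, bin_size = 1e6,
                   sex = NA_character_, sample_id = "sample")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("reference", "windows", "sample", "controls", "out_dir"))
    if (is.null(config[[nm]])) stop("pipeline config missing '", nm, "'")
  for (f in c(config$reference, config$windows, config$sample,
              config$controls))
    if (!file.exists(f)) stop("pipeline input not found: ", f)
  if (length(config$controls) < 4)
    stop("need at least 4 controls (leave-one-out scoring)")
  config
}

#' Run the full plasma copy-number pipeline on one sample
#'
#' Counts reads per window for the sample and every control,
#' GC-corrects all profiles, builds the control baseline, computes the
#' control-relative log2 ratios, segments them by CBS, and scores the
#' sample with segmental and genome-wide z statistics. Writes
#' `ratios.tsv`, `segments.tsv`, `zscores.tsv` and `summary.json` into
#' `out_dir`.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with `profile`, `baseline`, `segmentation`,
#'   `segment_z`, `score` and the output paths.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  windows <- read_windows(config$windows)

  profile_of <- function(path, id) {
    aln <- read_alignments(path)
    cnt <- count_reads(aln, windows, min_mapq = config$min_mapq,
                       sample_id = id, sex = config$sex)
    gc_correct(cnt, span = config$span)
  }
  controls <- lapply(seq_along(config$controls), function(i)
    profile_of(config$controls[i], sprintf("control%02d", i)))
  sample <- profile_of(config$sample, config$sample_id)

  baseline <- build_baseline(controls, sex = config$sex)
  sample <- to_log2_ratio(sample, baseline)
  seg <- cbs_segment(sample, cbs_params(alpha = config$alpha,
                                        n_permutations = config$n_permutations,
                                        seed = config$seed))
  segz <- segmental_z(sample, seg, baseline$ratios)

  bins <- bin_ratios(windows, cbind(sample$ratio, baseline$ratios),
                     bin_size = config$bin_size)
  score <- aneuploidy_score(bins$ratio[, 1], bins$ratio[, -1, drop = FALSE])

  ratios_tsv <- file.path(config$out_dir, "ratios.tsv")
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, ratio = sample$ratio,
                    log2ratio = sample$log2ratio)
  write.table(out, ratios_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  seg_tsv <- file.path(config$out_dir, "segments.tsv")
  write.table(segz, seg_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  z_tsv <- file.path(config$out_dir, "zscores.tsv")
  write.table(data.frame(bins$bins, z = score$z), z_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(sample = config$sample_id,
                            seed = config$seed,
                            n_windows = nrow(windows),
                            n_bins = score$n_windows,
                            n_segments = nrow(segz),
                            S = score$S,
                            genome_wide_z = score$genome_wide_z,
                            fraction_normal = score$fraction_normal,
                            n_significant_bins = score$n_significant,
                            params = config[c("span", "alpha",
                                              "n_permutations", "min_mapq",
                                              "seed", "bin_size")]),
                       summary_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(profile = sample, baseline = baseline, segmentation = seg,
                 segment_z = segz, score = score,
                 paths = c(ratios = ratios_tsv, segments = seg_tsv,
                           zscores = z_tsv, summary = summary_json)))
}
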