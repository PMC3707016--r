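# Synthetic end-to-end fixtures: reference genome, PAR BED, control and
# case SAM files with planted copy-number aberrations, GC bias,
# fusion-spanning reads, and a machine-readable truth file.

#' Synthesize a random reference genome
#'
#' Base composition follows a smooth per-block GC target (random walk,
#' reflected into `gc_range`), so windows built on the genome span a
#' realistic GC gradient for the LOWESS correction to work against.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc_range Range the per-block GC target is kept within.
#' @param block Block size (bp) over which the GC target is constant.
#' @return A named [Biostrings::DNAStringSet].
#' @export
synth_genome <- function(chrom_lengths, gc_range = c(0.3, 0.65),
                         block = 5000L) {
  seqs <- character(length(chrom_lengths))
  gc <- mean(gc_range)
  for (ci in seq_along(chrom_lengths)) {
    n <- chrom_lengths[ci]
    nblock <- ceiling(n / block)
    gcs <- numeric(nblock)
    for (b in seq_len(nblock)) {
      gc <- gc + rnorm(1, 0, 0.03)
      if (gc < gc_range[1]) gc <- 2 * gc_range[1] - gc
      if (gc > gc_range[2]) gc <- 2 * gc_range[2] - gc
      gcs[b] <- gc
    }
    sizes <- diff(unique(pmin(seq(0L, nblock) * block, n)))
    parts <- vapply(seq_along(sizes), function(b) {
      p <- gcs[b]
      paste(sample(c("A", "T", "G", "C"), sizes[b], replace = TRUE,
                   prob = c((1 - p) / 2, (1 - p) / 2, p / 2, p / 2)),
            collapse = "")
    }, character(1))
    seqs[ci] <- paste(parts, collapse = "")
  }
  names(seqs) <- names(chrom_lengths)
  as_genome(seqs)
}

#' Fixture configuration
#'
#' Defines the synthetic dataset: genome, window grid, sequencing depth,
#' GC bias, control cohort, and the planted aberrations of the tumor
#' cases. Defaults emulate, at desk scale, a prostate-cancer-like plasma
#' sample: 8p-like loss, 8q-like gain, a high-level AR-like gain on the
#' X analogue, and a focal deletion on the chr21 analogue that can carry
#' a fusion junction.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @param read_length Read (and virtual-read) length in bp.
#' @param n_windows Equal-mappability windows over the genome.
#' @param n_reads Mapped reads simulated per sample.
#' @param n_controls Healthy controls in the cohort.
#' @param gc_bias Strength of the smooth multiplicative GC bias injected
#'   into expected counts (0 = none).
#' @param cna Data.frame (`chrom`, `start`, `end`, `ratio`) of planted
#'   copy-number events for the tumor, or `NULL` for the default
#'   prostate-like set.
#' @param lambda Tumor-DNA fraction of the case samples.
#' @param n_cases Number of tumor case samples.
#' @param fusion `NULL`, or a list `list(chrom, del_start, del_end,
#'   n_spanning, n_background)` describing a deletion whose junction is
#'   covered by split reads in the case FASTQ.
#' @param sex Sex label recorded for all samples.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(chrom_lengths = NULL, read_length = 150L,
                           n_windows = 250L, n_reads = 200000L,
                           n_controls = 10L, gc_bias = 0.6, cna = NULL,
                           lambda = 1, n_cases = 1L, fusion = NULL,
                           sex = "male") {
  if (is.null(chrom_lengths))
    chrom_lengths <- c(chr1 = 180000L, chr2 = 180000L, chr3 = 160000L,
                       chr8 = 160000L, chr21 = 140000L, chrX = 140000L)
  if (is.null(cna)) {
    # default prostate-like events on whichever hallmark chromosomes the
    # genome provides; none of them present -> no planted events
    cna <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), ratio = numeric(0),
                      stringsAsFactors = FALSE)
    add <- function(chrom, f0, f1, ratio) {
      if (!chrom %in% names(chrom_lengths)) return()
      len <- chrom_lengths[[chrom]]
      cna <<- rbind(cna, data.frame(chrom = chrom,
                                    start = as.integer(round(len * f0)),
                                    end = as.integer(round(len * f1)),
                                    ratio = ratio))
    }
    add("chr8", 0, 0.5, 0.5)
    add("chr8", 0.5, 1, 1.5)
    add("chrX", 0.4, 0.7, 2.0)
    add("chr21", 0.55, 0.75, 0.5)
  }
  for (r in seq_len(nrow(cna))) {
    if (!cna$chrom[r] %in% names(chrom_lengths) ||
        cna$start[r] < 0 || cna$end[r] > chrom_lengths[[cna$chrom[r]]] ||
        cna$start[r] >= cna$end[r])
      stop("planted CNA outside the genome: ", cna$chrom[r], ":",
           cna$start[r], "-", cna$end[r])
  }
  if (!is.null(fusion)) {
    if (!fusion$chrom %in% names(chrom_lengths) ||
        fusion$del_start < 0 ||
        fusion$del_end > chrom_lengths[[fusion$chrom]] ||
        fusion$del_start >= fusion$del_end)
      stop("fusion deletion outside the genome")
    if (is.null(fusion$n_spanning)) fusion$n_spanning <- 10L
    if (is.null(fusion$n_background)) fusion$n_background <- 500L
  }
  structure(list(chrom_lengths = chrom_lengths,
                 read_length = as.integer(read_length),
                 n_windows = as.integer(n_windows),
                 n_reads = as.integer(n_reads),
                 n_controls = as.integer(n_controls),
                 gc_bias = gc_bias, cna = cna, lambda = lambda,
                 n_cases = as.integer(n_cases), fusion = fusion, sex = sex),
            class = "fixture_config")
}

# smooth multiplicative GC bias applied to expected window counts
.gc_bias_factor <- function(gc, strength) {
  f <- 1 + strength * (gc - 0.5) - strength * 1.2 * (gc - 0.5)^2
  pmax(f, 0.05)
}

.write_sam <- function(path, chrom_lengths, chroms, starts, read_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       chrom_lengths)), con)
  if (length(chroms) > 0)
    writeLines(sprintf("r%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_along(chroms), chroms, starts + 1L, read_length),
               con)
  invisible(path)
}

# Sample per-window read counts (multinomial over bias-scaled weights)
# and uniform positions among each window's mappable positions.
.sample_read_positions <- function(windows, mappable_pos, n_reads, weights) {
  counts <- as.integer(rmultinom(1, n_reads, weights))
  chroms <- character(0); starts <- integer(0)
  slice_end <- unlist(lapply(split(windows$n_mappable, windows$chrom)[
    unique(windows$chrom)], cumsum), use.names = FALSE)
  slice_start <- slice_end - windows$n_mappable + 1L
  for (w in which(counts > 0)) {
    pos_pool <- mappable_pos[[windows$chrom[w]]][slice_start[w]:slice_end[w]]
    pick <- pos_pool[sample.int(length(pos_pool), counts[w], replace = TRUE)]
    chroms <- c(chroms, rep(windows$chrom[w], counts[w]))
    starts <- c(starts, pick)
  }
  ord <- sample.int(length(starts))
  list(chrom = chroms[ord], start = starts[ord])
}

#' Generate a complete synthetic dataset
#'
#' Writes a reference FASTA, a PAR-style BED of masked intervals (empty
#' by default), one SAM per control and per case, a windows BED, a case
#' FASTQ with fusion-spanning reads when a fusion is configured, and a
#' `truth.json` recording every planted event.
#'
#' Read positions are drawn from the mappable positions of each window
#' with expected counts proportional to `n_mappable x GC-bias x (diluted
#' copy ratio)`, i.e. cases carry the configured aberrations attenuated
#' by `lambda`.
#'
#' @param config A `fixture_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @return Invisibly, a list with file paths and the in-memory `genome`,
#'   `windows`, `track` and `truth` objects.
#' @export
generate_fixture <- function(config = fixture_config(), out_dir, seed = 1L) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  genome <- synth_genome(config$chrom_lengths)
  fasta <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(genome, fasta)
  par_bed <- file.path(out_dir, "par.bed")
  writeLines(character(0), par_bed)

  track <- mappability_track(genome, config$read_length)
  windows <- window_gc(genome, build_windows(track, config$n_windows))
  write_windows(windows, file.path(out_dir, "windows.bed"))
  mappable_pos <- lapply(track$mappable, function(v) which(v) - 1L)

  bias <- .gc_bias_factor(windows$gc, config$gc_bias)
  base_w <- windows$n_mappable * bias

  samples <- list()
  for (i in seq_len(config$n_controls)) {
    id <- sprintf("control%02d", i)
    rp <- .sample_read_positions(windows, mappable_pos, config$n_reads, base_w)
    path <- file.path(out_dir, paste0(id, ".sam"))
    .write_sam(path, config$chrom_lengths, rp$chrom, rp$start,
               config$read_length)
    samples[[id]] <- list(path = path, role = "control")
  }
  tumor_ratio <- profile_from_segments(config$cna, windows)
  case_w <- base_w * dilute(tumor_ratio, config$lambda)
  for (i in seq_len(config$n_cases)) {
    id <- sprintf("case%02d", i)
    rp <- .sample_read_positions(windows, mappable_pos, config$n_reads, case_w)
    path <- file.path(out_dir, paste0(id, ".sam"))
    .write_sam(path, config$chrom_lengths, rp$chrom, rp$start,
               config$read_length)
    samples[[id]] <- list(path = path, role = "case")
  }

  truth <- list(seed = seed, lambda = config$lambda, cna = config$cna,
                n_reads = config$n_reads, sex = config$sex,
                samples = lapply(samples, `[[`, "role"))
  fastq <- NULL
  if (!is.null(config$fusion)) {
    fastq <- file.path(out_dir, "case_fusion.fastq")
    junction <- .fusion_reads(genome, config$fusion, config$read_length)
    .write_fastq(fastq, c(junction,
                          .background_reads(genome, config$fusion$n_background,
                                            config$read_length)))
    truth$fusion <- list(chrom = config$fusion$chrom,
                         posA = config$fusion$del_start - 1L,
                         posB = config$fusion$del_end,
                         n_spanning = config$fusion$n_spanning)
  }
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, fasta = fasta, par_bed = par_bed,
                 windows = windows, track = track, genome = genome,
                 samples = samples, fastq = fastq, truth = truth))
}

# reads spanning the deletion junction: left flank ends at del_start - 1,
# right flank starts at del_end; junction offset inside the read varies
# so both 60 bp fragments fall on opposite sides
.fusion_reads <- function(genome, fusion, read_length) {
  chrom <- as.character(genome[[fusion$chrom]])
  n <- fusion$n_spanning
  gap <- read_length - 2 * 60L
  # left-part length: both 60 bp fragments must clear the junction, so
  # it ranges over [60, 60 + gap]
  offs <- 60L + (seq_len(n) - 1L) %% (gap + 1L)
  vapply(offs, function(off) {
    left <- substr(chrom, fusion$del_start - off + 1, fusion$del_start)
    right <- substr(chrom, fusion$del_end + 1,
                    fusion$del_end + read_length - off)
    paste0(left, right)
  }, character(1))
}

.background_reads <- function(genome, n, read_length) {
  chars <- .genome_chars(genome)
  lens <- nchar(chars)
  ci <- sample.int(length(chars), n, replace = TRUE,
                   prob = lens / sum(lens))
  vapply(seq_len(n), function(i) {
    p <- sample.int(lens[ci[i]] - read_length, 1)
    substr(chars[[ci[i]]], p, p + read_length - 1)
  }, character(1))
}

.write_fastq <- function(path, reads) {
  qual <- strrep("I", nchar(reads))
  writeLines(as.vector(rbind(sprintf("@read%06d", seq_along(reads)),
                             reads, "+", qual)), path)
  invisible(path)
}
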