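# Read counting per window and normalization into GC-corrected ratio /
# log2 ratio profiles.

#' Read alignments from a SAM or BAM file
#'
#' SAM input is converted to BAM internally via Rsamtools. Positions are
#' returned 0-based to match the package's coordinate convention.
#'
#' @param path SAM (text) or BAM file.
#' @return A data.frame with columns `chrom`, `pos` (0-based leftmost),
#'   `mapq`, `unmapped`, `duplicate`, `secondary`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq", "flag"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (!is_bam) unlink(paste0(bam, c("", ".bai")))
  flag <- x$flag
  data.frame(chrom = as.character(x$rname),
             pos = x$pos - 1L,
             mapq = x$mapq,
             unmapped = bitwAnd(flag, 4L) > 0L,
             duplicate = bitwAnd(flag, 1024L) > 0L,
             secondary = bitwAnd(flag, 256L) > 0L,
             stringsAsFactors = FALSE)
}

#' Count reads per window
#'
#' Each retained alignment (mapped, not duplicate, not secondary, mapping
#' quality at least `min_mapq`) increments the window containing its
#' leftmost aligned base. Reads falling between window spans, or on
#' chromosomes without windows, contribute to `total_reads` only.
#'
#' @param alignments Data.frame from [read_alignments()] (columns `chrom`,
#'   `pos`; optional `mapq`, `unmapped`, `duplicate`, `secondary`).
#' @param windows A `window_set`.
#' @param min_mapq Minimum mapping quality (default 0, i.e. no floor).
#' @param strict Error (instead of warn + skip) on alignments naming a
#'   chromosome absent from the windows.
#' @param sample_id,sex Labels carried through to downstream tables.
#' @return A `window_counts` object: list with `windows`, integer vector
#'   `counts`, `total_reads`, `sample_id`, `sex`.
#' @export
count_reads <- function(alignments, windows, min_mapq = 0, strict = FALSE,
                        sample_id = "sample", sex = NA_character_) {
  .check_windows(windows)
  aln <- alignments
  keep <- rep(TRUE, nrow(aln))
  if ("unmapped" %in% names(aln)) keep <- keep & !aln$unmapped
  if ("duplicate" %in% names(aln)) keep <- keep & !aln$duplicate
  if ("secondary" %in% names(aln)) keep <- keep & !aln$secondary
  if ("mapq" %in% names(aln) && min_mapq > 0)
    keep <- keep & !is.na(aln$mapq) & aln$mapq >= min_mapq
  aln <- aln[keep, , drop = FALSE]

  known <- unique(windows$chrom)
  unknown <- setdiff(unique(aln$chrom), known)
  if (length(unknown) > 0) {
    msg <- paste("alignments on chromosomes without windows:",
                 paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }

  counts <- integer(nrow(windows))
  for (chrom in known) {
    widx <- which(windows$chrom == chrom)
    pos <- aln$pos[aln$chrom == chrom]
    if (length(pos) == 0) next
    iv <- findInterval(pos, windows$start[widx])
    inside <- iv >= 1 & pos < windows$end[widx][pmax(iv, 1)]
    tab <- tabulate(iv[inside], nbins = length(widx))
    counts[widx] <- counts[widx] + tab
  }
  structure(list(windows = windows, counts = counts,
                 total_reads = nrow(aln), sample_id = sample_id, sex = sex),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts:", x$sample_id, "-", sum(x$counts), "reads in",
      length(x$counts), "windows (", x$total_reads, "retained total )\n")
  invisible(x)
}

# Fitted LOWESS GC-bias curve evaluated at each window's GC, by linear
# interpolation of the smoothed fit (constant beyond the fitted range).
.lowess_gc_fit <- function(gc, norm_counts, span, iter = 1L) {
  ok <- is.finite(gc) & is.finite(norm_counts)
  fit <- lowess(gc[ok], norm_counts[ok], f = span, iter = iter)
  approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
}

#' GC-correct window counts into read-count ratios
#'
#' Window counts are first scaled by their mean, then divided by the
#' LOWESS fit of normalized count on GC fraction (multiplicative bias
#' model), and finally rescaled so that the mean ratio over usable
#' windows is exactly 1. Windows with missing GC, or where the fitted
#' bias curve is non-positive, are set to `NA`.
#'
#' @param counts A `window_counts` object.
#' @param span LOWESS span as a fraction of the data (default 0.3).
#' @param iter Number of robustifying LOWESS iterations (default 1).
#' @return A `ratio_profile`: list with `windows`, numeric `ratio`
#'   (mean 1 over non-missing windows), `log2ratio` (NULL until
#'   [to_log2_ratio()]), `sample_id`, `sex`.
#' @export
gc_correct <- function(counts, span = 0.3, iter = 1L) {
  stopifnot(inherits(counts, "window_counts"))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  gc <- counts$windows$gc
  n_distinct <- length(unique(gc[is.finite(gc)]))
  if (n_distinct < 20)
    stop("need at least 20 windows with distinct GC fractions")
  cnt <- as.numeric(counts$counts)
  if (all(cnt == 0)) stop("all window counts are zero; cannot normalize")
  norm <- cnt / mean(cnt)
  f <- .lowess_gc_fit(gc, norm, span, iter)
  ratio <- ifelse(is.finite(gc) & is.finite(f) & f > 0, norm / f, NA_real_)
  ratio <- ratio / mean(ratio, na.rm = TRUE)
  structure(list(windows = counts$windows, ratio = ratio, log2ratio = NULL,
                 sample_id = counts$sample_id, sex = counts$sex),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat("ratio_profile:", x$sample_id, "-", length(x$ratio), "windows, mean ratio",
      round(mean(x$ratio, na.rm = TRUE), 4), "\n")
  invisible(x)
}

.same_windows <- function(a, b) {
  isTRUE(all.equal(a[, c("chrom", "start", "end")],
                   b[, c("chrom", "start", "end")],
                   check.attributes = FALSE))
}

#' Build a control baseline from healthy-control ratio profiles
#'
#' Per-window mean and sample standard deviation of the GC-corrected
#' ratios across controls. All controls must share the window set and
#' the sex label: X/Y windows have sex-dependent coverage, so baselines
#' are built per sex.
#'
#' @param profiles List of `ratio_profile` objects (>= 2).
#' @param sex Expected sex label; profiles with a conflicting non-NA sex
#'   label are rejected.
#' @return A `control_baseline`: list with `windows`, `mean`, `sd`,
#'   `n_controls`, `sex`, and the control ratio matrix `ratios`
#'   (windows x controls).
#' @export
build_baseline <- function(profiles, sex = NA_character_) {
  if (length(profiles) < 2) stop("need at least 2 control profiles")
  sexes <- vapply(profiles, function(p) as.character(p$sex), character(1))
  known <- sexes[!is.na(sexes)]
  if (length(unique(known)) > 1)
    stop("controls of mixed sex: ", paste(unique(known), collapse = ", "))
  if (!is.na(sex) && length(known) > 0 && any(known != sex))
    stop("control sex labels conflict with requested sex '", sex, "'")
  w <- profiles[[1]]$windows
  for (p in profiles[-1])
    if (!.same_windows(w, p$windows)) stop("controls use different window sets")
  mat <- vapply(profiles, function(p) p$ratio, numeric(nrow(w)))
  structure(list(windows = w,
                 mean = rowMeans(mat),
                 sd = apply(mat, 1, sd),
                 ratios = mat,
                 n_controls = length(profiles),
                 sex = if (!is.na(sex)) sex else
                   if (length(known) > 0) known[1] else NA_character_),
            class = "control_baseline")
}

#' Convert a ratio profile to control-relative log2 ratios
#'
#' `log2ratio_i = log2(ratio_i / baseline_mean_i)`. Windows where the
#' sample ratio or the baseline mean is missing or non-positive are `NA`.
#'
#' @param sample A `ratio_profile`.
#' @param baseline A `control_baseline` on the same window set.
#' @return The profile with its `log2ratio` filled in.
#' @export
to_log2_ratio <- function(sample, baseline) {
  stopifnot(inherits(sample, "ratio_profile"),
            inherits(baseline, "control_baseline"))
  if (!.same_windows(sample$windows, baseline$windows))
    stop("sample and baseline window sets differ")
  ok <- is.finite(sample$ratio) & is.finite(baseline$mean) & baseline$mean > 0 &
    sample$ratio > 0
  sample$log2ratio <- ifelse(ok, log2(sample$ratio / baseline$mean), NA_real_)
  sample
}

#' Write / read per-window value tables as TSV
#'
#' Four tab-separated columns with a header: chrom, start, end, value.
#'
#' @param windows A `window_set`.
#' @param values Numeric vector, one value per window.
#' @param path Output path.
#' @param value_name Header name of the value column.
#' @return `path` invisibly; `read_window_values` returns a data.frame.
#' @export
write_window_values <- function(windows, values, path, value_name = "value") {
  .check_windows(windows)
  stopifnot(length(values) == nrow(windows))
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, value = values)
  names(out)[4] <- value_name
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_values
#' @export
read_window_values <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
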