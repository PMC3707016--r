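# The z-score battery: per-1-Mbp-window z with leave-one-out
# cross-validation of controls, segmental z, gene-region z, the S-score
# (sum of squared z) and genome-wide z, plus hierarchical clustering of
# z profiles.

#' Aggregate equal-mappability windows into fixed-size bins
#'
#' Each window is assigned to the bin containing its midpoint; the bin
#' value is the mean GC-corrected ratio of its windows (windows hold
#' equal mappable-position counts, so the mean is proportional to the
#' read count in the bin). Bins receiving no window are dropped.
#'
#' @param windows A `window_set`.
#' @param ratio Numeric vector of per-window ratios (NA = missing), or a
#'   matrix with one column per sample.
#' @param bin_size Bin size in bp (default 1 Mbp).
#' @return List with `bins` (data.frame chrom, start, end) and `ratio`
#'   (vector or matrix of bin means, NAs ignored).
#' @export
bin_ratios <- function(windows, ratio, bin_size = 1e6) {
  if (!all(c("chrom", "start", "end") %in% names(windows)))
    stop("windows must have chrom, start, end columns")
  mid <- (windows$start + windows$end) / 2
  bin_id <- paste(windows$chrom, floor(mid / bin_size), sep = ":")
  keys <- unique(bin_id)
  mat <- as.matrix(ratio)
  stopifnot(nrow(mat) == nrow(windows))
  agg <- apply(mat, 2, function(v)
    vapply(split(v, factor(bin_id, levels = keys)),
           function(x) mean(x, na.rm = TRUE), numeric(1)))
  agg[is.nan(agg)] <- NA_real_
  parts <- do.call(rbind, strsplit(keys, ":"))
  bins <- data.frame(chrom = parts[, 1],
                     start = as.numeric(parts[, 2]) * bin_size,
                     end = (as.numeric(parts[, 2]) + 1) * bin_size,
                     stringsAsFactors = FALSE)
  if (is.null(dim(ratio))) agg <- drop(agg)
  list(bins = bins, ratio = agg)
}

#' Per-window z-scores against a control cohort
#'
#' `z_i = (x_i - mean(controls_i)) / sd(controls_i)`. When the sample is
#' itself one of the controls, pass its column index as `leave_out`: its
#' own values are then excluded from the mean and SD (leave-one-out
#' cross-validation), so controls never serve as their own controls.
#' Windows where the control SD is 0 or not finite get `NA`.
#'
#' @param sample Numeric vector of per-bin ratios.
#' @param controls Matrix of control ratios, bins x controls (>= 3).
#' @param leave_out Column index of `sample` within `controls`, or `NULL`
#'   for an independent sample.
#' @return Numeric z vector.
#' @export
window_z <- function(sample, controls, leave_out = NULL) {
  controls <- as.matrix(controls)
  if (ncol(controls) < 3) stop("need at least 3 controls")
  if (length(sample) != nrow(controls))
    stop("sample and controls have different numbers of windows")
  if (!is.null(leave_out)) {
    if (leave_out < 1 || leave_out > ncol(controls))
      stop("leave_out outside the control cohort")
    controls <- controls[, -leave_out, drop = FALSE]
  }
  ms <- .row_mean_sd(controls)
  ifelse(is.finite(ms$sd) & ms$sd > 0, (sample - ms$mean) / ms$sd, NA_real_)
}

# vectorized row-wise mean and sample SD
.row_mean_sd <- function(mat) {
  n <- ncol(mat)
  m <- rowMeans(mat)
  v <- (rowSums(mat^2) - n * m^2) / (n - 1)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Cross-validated z matrix for a control cohort
#'
#' Scores every control against the remaining controls (leave-one-out).
#'
#' @param controls Matrix of control ratios, bins x controls (>= 4).
#' @return Matrix of z-scores, same shape as `controls`, with attribute
#'   `n_reference` (= ncol - 1).
#' @export
control_z_matrix <- function(controls) {
  controls <- as.matrix(controls)
  n <- ncol(controls)
  if (n < 4) stop("need at least 4 controls for cross-validation")
  # leave-one-out means/SDs from the row totals (no per-column rescan)
  T_ <- rowSums(controls)
  Q_ <- rowSums(controls^2)
  m_loo <- (T_ - controls) / (n - 1)
  v_loo <- (Q_ - controls^2 - (n - 1) * m_loo^2) / (n - 2)
  s_loo <- sqrt(pmax(v_loo, 0))
  z <- (controls - m_loo) / s_loo
  z[!is.finite(z)] <- NA_real_
  attr(z, "n_reference") <- n - 1L
  z
}

#' Fraction of windows with normal representation
#'
#' A window is significantly aberrant when its z-score is more than
#' `threshold` SDs from the control mean (|z| > threshold, default 3).
#'
#' @param z Numeric z vector (NAs ignored).
#' @param threshold SD threshold (default 3).
#' @return List with `fraction_normal` (|z| <= threshold among non-NA
#'   windows) and `n_significant` (count with z <= -threshold or >=
#'   threshold).
#' @export
significant_fraction <- function(z, threshold = 3) {
  ok <- is.finite(z)
  n_sig <- sum(z[ok] <= -threshold | z[ok] >= threshold)
  list(fraction_normal = if (any(ok)) 1 - n_sig / sum(ok) else NA_real_,
       n_significant = n_sig)
}

#' Segmental z-scores
#'
#' For each CBS segment, the sum of the sample's GC-corrected window
#' ratios over the segment is standardized against the distribution of
#' the same sum across controls:
#' `z = (sum_sample - mean(sum_controls)) / sd(sum_controls)`.
#'
#' @param profile A `ratio_profile` for the sample.
#' @param result A `cbs_result` from [cbs_segment()] on that profile.
#' @param controls Matrix of control GC-corrected ratios (windows x
#'   controls, >= 3), e.g. `baseline$ratios`.
#' @return The segment data.frame with columns `sum_ratio_controls_mean`,
#'   `sum_ratio_controls_sd` and `z` appended; segments with control SD 0
#'   get `NA` z.
#' @export
segmental_z <- function(profile, result, controls) {
  stopifnot(inherits(profile, "ratio_profile"), inherits(result, "cbs_result"))
  controls <- as.matrix(controls)
  if (ncol(controls) < 3) stop("need at least 3 controls")
  if (nrow(controls) != nrow(profile$windows))
    stop("controls and profile use different window sets")
  seg <- result$segments
  zs <- ms <- ss <- numeric(nrow(seg))
  for (s in seq_len(nrow(seg))) {
    rows <- seg$first_window[s]:seg$last_window[s]
    sums <- colSums(controls[rows, , drop = FALSE], na.rm = TRUE)
    ms[s] <- mean(sums)
    ss[s] <- sd(sums)
    zs[s] <- if (is.finite(ss[s]) && ss[s] > 0)
      (seg$sum_ratio[s] - ms[s]) / ss[s] else NA_real_
  }
  seg$sum_ratio_controls_mean <- ms
  seg$sum_ratio_controls_sd <- ss
  seg$z <- zs
  seg
}

#' Expected read count and ratio for a genomic region
#'
#' `reads_expected = length_region / length_genome * reads_total`;
#' `ratio = reads_region / reads_expected`.
#'
#' @param reads_region Reads counted in the region.
#' @param reads_total Total reads for the sample.
#' @param length_region,length_genome Region and genome lengths in bp.
#'   The genome length should be the span covered by the window grid
#'   (the mappable-spanned genome).
#' @return List with `reads_expected` and `ratio`.
#' @export
region_ratio <- function(reads_region, reads_total, length_region,
                         length_genome) {
  if (length_region <= 0 || length_genome <= 0)
    stop("region and genome lengths must be positive")
  expected <- length_region / length_genome * reads_total
  if (expected <= 0) stop("zero expected reads in region")
  list(reads_expected = expected, ratio = reads_region / expected)
}

#' Count reads falling in arbitrary regions
#'
#' @param alignments Data.frame with `chrom` and 0-based `pos` (see
#'   [read_alignments()]); standard flag filters are applied as in
#'   [count_reads()].
#' @param regions Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param min_mapq Minimum mapping quality (default 0).
#' @return Integer vector of counts, one per region, with attribute
#'   `total_reads` (all retained alignments).
#' @export
count_in_regions <- function(alignments, regions, min_mapq = 0) {
  aln <- alignments
  keep <- rep(TRUE, nrow(aln))
  for (col in c("unmapped", "duplicate", "secondary"))
    if (col %in% names(aln)) keep <- keep & !aln[[col]]
  if ("mapq" %in% names(aln) && min_mapq > 0)
    keep <- keep & !is.na(aln$mapq) & aln$mapq >= min_mapq
  aln <- aln[keep, , drop = FALSE]
  counts <- integer(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    counts[r] <- sum(aln$chrom == regions$chrom[r] &
                       aln$pos >= regions$start[r] &
                       aln$pos < regions$end[r])
  }
  attr(counts, "total_reads") <- nrow(aln)
  counts
}

#' Region (gene-specific) z-scores
#'
#' For each region the sample's read-count ratio relative to expectation
#' is standardized against the control ratios for the same region:
#' `z = (ratio_sample - mean(ratio_controls)) / sd(ratio_controls)`.
#'
#' @param regions Data.frame with `chrom`, `start`, `end`, optional
#'   `name`.
#' @param sample_counts Integer vector from [count_in_regions()] for the
#'   sample (with `total_reads` attribute), or a list
#'   `list(counts, total)`.
#' @param control_counts List of such vectors, one per control (>= 3).
#' @param length_genome Genome length used for the expectation (bp).
#' @return Data.frame: region columns plus `reads_region`,
#'   `reads_expected`, `ratio` and `z`.
#' @export
region_z <- function(regions, sample_counts, control_counts, length_genome) {
  if (length(control_counts) < 3) stop("need at least 3 controls")
  get <- function(x) {
    if (is.list(x)) list(counts = x$counts, total = x$total)
    else list(counts = as.numeric(x), total = attr(x, "total_reads"))
  }
  smp <- get(sample_counts)
  ctl <- lapply(control_counts, get)
  out <- regions
  lens <- regions$end - regions$start
  rr <- vapply(seq_len(nrow(regions)), function(r)
    unlist(region_ratio(smp$counts[r], smp$total, lens[r], length_genome)),
    numeric(2))
  ctl_ratio <- vapply(ctl, function(cc)
    vapply(seq_len(nrow(regions)), function(r)
      region_ratio(cc$counts[r], cc$total, lens[r], length_genome)$ratio,
      numeric(1)),
    numeric(nrow(regions)))
  ctl_ratio <- matrix(ctl_ratio, nrow = nrow(regions))
  m <- rowMeans(ctl_ratio)
  s <- apply(ctl_ratio, 1, sd)
  out$reads_region <- smp$counts
  out$reads_expected <- rr[1, ]
  out$ratio <- rr[2, ]
  out$z <- ifelse(is.finite(s) & s > 0, (out$ratio - m) / s, NA_real_)
  out
}

#' S-score: sum of squared z-scores
#'
#' @param z Numeric z vector; NAs are ignored.
#' @return `S = sum(z^2)` over non-missing windows.
#' @export
s_score <- function(z) sum(z^2, na.rm = TRUE)

#' Genome-wide z-score from S-scores
#'
#' Standardizes a sample's S-score against the S-scores of
#' cross-validated controls:
#' `genome_wide_z = (S - mean(control_S)) / sd(control_S)`.
#'
#' @param S Sample S-score.
#' @param control_S Numeric vector of control S-scores (>= 3).
#' @return The genome-wide z-score.
#' @export
genome_wide_z <- function(S, control_S) {
  if (length(control_S) < 3) stop("need at least 3 control S values")
  s <- sd(control_S)
  if (!is.finite(s) || s == 0) stop("control S-scores have zero SD")
  (S - mean(control_S)) / s
}

# Expected squared z of an independent draw scored against k reference
# controls whose per-window values are i.i.d. normal: the z is
# sqrt(1 + 1/k) times a t variate with k - 1 degrees of freedom, so
# E[z^2] = (1 + 1/k) (k - 1) / (k - 3). Needs k >= 4.
.expected_z2 <- function(k) {
  if (k < 4) return(NA_real_)
  (1 + 1 / k) * (k - 1) / (k - 3)
}

#' Precompute a control reference for genome-wide scoring
#'
#' Holds the control ratio matrix together with the leave-one-out
#' cross-validated S-scores of the controls, so that scoring many
#' samples against one cohort does not redo the cross-validation.
#'
#' @param controls Matrix of control per-bin ratios (bins x controls,
#'   >= 4; >= 5 for the scale adjustment).
#' @param df_adjust Apply the finite-cohort scale adjustment (see
#'   [aneuploidy_score()]).
#' @return List of class `control_reference`: `controls`, `control_S`
#'   (adjusted when requested), `n_controls`, `df_adjust`.
#' @export
control_reference <- function(controls, df_adjust = TRUE) {
  controls <- as.matrix(controls)
  n <- ncol(controls)
  zc <- control_z_matrix(controls)
  control_S <- apply(zc, 2, s_score)
  if (df_adjust) {
    e_ctl <- .expected_z2(n - 1L)
    if (is.na(e_ctl)) {
      warning("too few controls for the scale adjustment; using raw S")
      df_adjust <- FALSE
    } else control_S <- control_S / e_ctl
  }
  structure(list(controls = controls, control_S = control_S,
                 n_controls = n, df_adjust = df_adjust),
            class = "control_reference")
}

#' Aneuploidy scoring of a sample against a control cohort
#'
#' Computes the sample's per-bin z-scores against the full cohort, its
#' S-score, the leave-one-out cross-validated S-scores of the controls,
#' and the genome-wide z. Because a cross-validated control z uses one
#' reference control fewer than a held-out sample z, the raw S-scores of
#' the two sit on slightly different scales; with
#' `df_adjust = TRUE` (default) each S is divided by its theoretical
#' null expectation per window before standardization, putting sample
#' and control S on a common scale.
#'
#' @param sample Numeric per-bin ratio vector, or the column index of a
#'   control to score (scored leave-one-out).
#' @param controls Matrix of control per-bin ratios (bins x controls,
#'   >= 5 for the adjustment), or a [control_reference()].
#' @param df_adjust Apply the finite-cohort scale adjustment (ignored
#'   when `controls` is already a `control_reference`).
#' @param threshold SD threshold for [significant_fraction()] (default 3).
#' @return List of class `aneuploidy_score`: `z`, `S`, `genome_wide_z`,
#'   `control_S`, `n_windows`, `fraction_normal`, `n_significant`.
#' @export
aneuploidy_score <- function(sample, controls, df_adjust = TRUE,
                             threshold = 3) {
  ref <- if (inherits(controls, "control_reference")) controls
         else control_reference(controls, df_adjust)
  n <- ref$n_controls
  if (length(sample) == 1 && is.numeric(sample) && sample == round(sample) &&
      sample >= 1 && sample <= n) {
    z <- window_z(controls_of(ref)[, sample], controls_of(ref),
                  leave_out = sample)
    k_sample <- n - 1L
  } else {
    z <- window_z(sample, controls_of(ref))
    k_sample <- n
  }
  S <- s_score(z)
  if (ref$df_adjust) S <- S / .expected_z2(k_sample)
  sig <- significant_fraction(z, threshold)
  structure(list(z = z, S = S, control_S = ref$control_S,
                 genome_wide_z = genome_wide_z(S, ref$control_S),
                 n_windows = sum(is.finite(z)),
                 fraction_normal = sig$fraction_normal,
                 n_significant = sig$n_significant),
            class = "aneuploidy_score")
}

#' @rdname control_reference
#' @param ref A `control_reference`.
#' @export
controls_of <- function(ref) ref$controls

#' @export
print.aneuploidy_score <- function(x, ...) {
  cat("aneuploidy_score: genome-wide z =", round(x$genome_wide_z, 2),
      "( S =", round(x$S, 1), ",", x$n_windows, "windows,",
      round(100 * x$fraction_normal, 1), "% normal )\n")
  invisible(x)
}

#' Hierarchically cluster samples by their z profiles
#'
#' Pairwise Manhattan distance (sum over windows of |z_a - z_b|)
#' followed by agglomerative clustering.
#'
#' @param zmat Matrix of z-scores, samples x windows, with sample row
#'   names.
#' @param method Linkage: "complete" (default), "average" or "single".
#' @return An [stats::hclust] tree.
#' @export
cluster_samples <- function(zmat, method = c("complete", "average", "single")) {
  method <- match.arg(method)
  zmat <- as.matrix(zmat)
  if (nrow(zmat) < 2) stop("need at least 2 samples to cluster")
  if (anyNA(zmat))
    warning("missing z-scores: pairwise-complete Manhattan distances ",
            "(rescaled by the number of usable windows)")
  hclust(dist(zmat, method = "manhattan"), method = method)
}

#' Write an hclust tree in Newick format
#'
#' @param hc An [stats::hclust] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
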