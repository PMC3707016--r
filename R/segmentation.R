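# Circular binary segmentation of log2 ratio profiles. The change-point
# statistic is the two-sample t comparing an arc of windows against its
# complement; significance is assessed by permutation.

#' CBS parameters
#'
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_permutations Permutations per test (default 10000).
#' @param min_width Minimum windows per arc and complement (default 2).
#' @param seed Integer seed controlling the permutation stream.
#' @param early_stop Stop permuting once enough exceedances guarantee
#'   `p >= alpha` (default `TRUE`; the accept/reject decision and the
#'   segmentation are unchanged, only the reported p for clearly
#'   non-significant splits is the running estimate).
#' @param undo_sd Optional post-hoc merge: adjacent segments whose means
#'   differ by less than `undo_sd` residual SDs are merged (default
#'   `NULL`, off).
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 10000L, min_width = 2L,
                       seed = 1L, early_stop = TRUE, undo_sd = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (min_width < 1) stop("min_width must be >= 1")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_width = as.integer(min_width), seed = as.integer(seed),
                 early_stop = isTRUE(early_stop), undo_sd = undo_sd),
            class = "cbs_params")
}

#' Maximal arc t statistic
#'
#' Scans all arcs `[i, j)` with arc and complement at least `min_width`
#' windows and returns the arc maximizing the absolute two-sample t
#' statistic of arc versus complement. Ties are broken toward the
#' smallest `i`, then the smallest `j`. Zero within-group variance is
#' capped at a large sentinel value. Indices are 0-based half-open.
#'
#' @param values Numeric vector (no NAs).
#' @param min_width Minimum arc/complement width (default 2).
#' @return List with `i`, `j`, `stat` (signed t, arc minus complement)
#'   and `degenerate` (`TRUE` for constant input, where no arc exists).
#' @export
circular_max_stat <- function(values, min_width = 2L) {
  if (anyNA(values)) stop("values must not contain NA")
  if (length(values) < 2 * min_width && length(values) >= 2 &&
      !all(values == values[1]))
    stop("need at least 2 * min_width values")
  .cbs_max_stat(as.numeric(values), as.integer(min_width))
}

#' Permutation p-value for an observed arc statistic
#'
#' `p = (1 + #\{permutations with max |T| >= |T_obs|\}) / (n_permutations
#' + 1)`, with the permutation stream drawn from R's RNG so results are
#' reproducible under `set.seed`.
#'
#' @param values Numeric vector the statistic was computed on.
#' @param t_obs Observed statistic (signed or absolute).
#' @param params A `cbs_params` object; its `seed` is applied before
#'   permuting.
#' @return Numeric p-value in (0, 1].
#' @export
permutation_p <- function(values, t_obs, params = cbs_params()) {
  set.seed(params$seed)
  res <- .cbs_perm_count(as.numeric(values), abs(t_obs),
                         params$n_permutations, params$min_width,
                         early_stop = 0L)
  (1 + res$count) / (params$n_permutations + 1)
}

# One permutation test inside the recursion (shares the caller's RNG
# stream; optionally stops early once non-significance is certain).
.perm_test <- function(values, t_obs_abs, params) {
  stop_at <- if (params$early_stop)
    as.integer(ceiling(params$alpha * (params$n_permutations + 1))) else 0L
  res <- .cbs_perm_count(as.numeric(values), t_obs_abs,
                         params$n_permutations, params$min_width, stop_at)
  (1 + res$count) / (res$n_done + 1)
}

# Recursive ternary splitting on a vector of values; returns sorted
# 0-based half-open boundaries (relative to the vector) of accepted cuts.
.cbs_recurse <- function(values, offset, params) {
  n <- length(values)
  if (n < 2 * params$min_width) return(integer(0))
  ms <- .cbs_max_stat(as.numeric(values), params$min_width)
  if (isTRUE(ms$degenerate)) return(integer(0))
  p <- .perm_test(values, abs(ms$stat), params)
  if (p >= params$alpha) return(integer(0))
  i <- ms$i; j <- ms$j
  cuts <- integer(0)
  if (i > 0) cuts <- c(cuts, offset + i)
  if (j < n) cuts <- c(cuts, offset + j)
  left <- if (i > 0) .cbs_recurse(values[seq_len(i)], offset, params)
          else integer(0)
  mid <- .cbs_recurse(values[(i + 1):j], offset + i, params)
  right <- if (j < n) .cbs_recurse(values[(j + 1):n], offset + j, params)
           else integer(0)
  sort(unique(c(cuts, left, mid, right)))
}

#' Segment a log2 ratio profile by circular binary segmentation
#'
#' Per chromosome, the maximal arc statistic is computed on the
#' non-missing log2 ratios; if its permutation p-value is below `alpha`
#' the arc boundaries are accepted and the three resulting pieces are
#' segmented recursively. Missing windows are skipped in all statistics
#' but remain inside the enclosing segment's coordinates, so segments
#' tile each chromosome without gaps.
#'
#' @param profile A `ratio_profile` with `log2ratio` set (see
#'   [to_log2_ratio()]).
#' @param params A `cbs_params` object.
#' @return A `cbs_result`: list with `segments` (data.frame: chrom,
#'   start, end, first_window, last_window, n_windows, n_used,
#'   mean_log2, sum_ratio) and `params`. Window indices are 1-based
#'   inclusive rows of the profile's window set.
#' @export
cbs_segment <- function(profile, params = cbs_params()) {
  stopifnot(inherits(profile, "ratio_profile"))
  if (is.null(profile$log2ratio))
    stop("profile has no log2 ratios; run to_log2_ratio() first")
  win <- profile$windows
  segs <- list()
  for (chrom in unique(win$chrom)) {
    # per-chromosome seed derived from the chromosome name, so results
    # do not depend on chromosome iteration order
    set.seed((params$seed + sum(utf8ToInt(chrom)) * 131L) %% .Machine$integer.max)
    widx <- which(win$chrom == chrom)
    vals <- profile$log2ratio[widx]
    use <- which(is.finite(vals))
    if (length(use) < 2 * params$min_width) {
      if (length(use) < params$min_width)
        warning("chromosome ", chrom, " has fewer than min_width usable ",
                "windows; single segment")
      cuts <- integer(0)
    } else {
      cuts <- .cbs_recurse(vals[use], 0L, params)
    }
    # cut positions are within the non-missing subsequence; map back to
    # window rows so missing windows stay inside the enclosing segment
    bounds <- c(0L, cuts, length(use))
    for (s in seq_len(length(bounds) - 1)) {
      lo <- bounds[s] + 1L
      hi <- bounds[s + 1L]
      # segments tile the chromosome: the first/last segment extends to
      # the chromosome ends; missing windows between accepted boundaries
      # attach to the following segment
      first_row <- if (s == 1) 1L else use[lo - 1L] + 1L
      last_row <- if (s == length(bounds) - 1L) length(widx) else use[hi]
      rows <- widx[first_row:last_row]
      used <- rows[is.finite(profile$log2ratio[rows])]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = chrom,
        start = win$start[rows[1]],
        end = win$end[rows[length(rows)]],
        first_window = rows[1],
        last_window = rows[length(rows)],
        n_windows = length(rows),
        n_used = length(used),
        mean_log2 = if (length(used)) mean(profile$log2ratio[used]) else NA_real_,
        sum_ratio = sum(profile$ratio[rows], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  result <- structure(list(segments = segments, params = params,
                           sample_id = profile$sample_id),
                      class = "cbs_result")
  if (!is.null(params$undo_sd)) result <- .undo_splits(result, profile, params)
  result
}

# Optional merge of adjacent segments whose means are closer than
# undo_sd residual SDs (off by default).
.undo_splits <- function(result, profile, params) {
  seg <- result$segments
  resid_sd <- sd(unlist(lapply(seq_len(nrow(seg)), function(s) {
    rows <- seg$first_window[s]:seg$last_window[s]
    v <- profile$log2ratio[rows]
    v[is.finite(v)] - seg$mean_log2[s]
  })), na.rm = TRUE)
  if (!is.finite(resid_sd) || resid_sd == 0) return(result)
  repeat {
    merged <- FALSE
    s <- 1
    while (s < nrow(seg)) {
      same_chr <- seg$chrom[s] == seg$chrom[s + 1]
      if (same_chr &&
          abs(seg$mean_log2[s] - seg$mean_log2[s + 1]) <
            params$undo_sd * resid_sd) {
        rows <- seg$first_window[s]:seg$last_window[s + 1]
        v <- profile$log2ratio[rows]
        seg$end[s] <- seg$end[s + 1]
        seg$last_window[s] <- seg$last_window[s + 1]
        seg$n_windows[s] <- length(rows)
        seg$n_used[s] <- sum(is.finite(v))
        seg$mean_log2[s] <- mean(v, na.rm = TRUE)
        seg$sum_ratio[s] <- seg$sum_ratio[s] + seg$sum_ratio[s + 1]
        seg <- seg[-(s + 1), , drop = FALSE]
        merged <- TRUE
      } else s <- s + 1
    }
    if (!merged) break
  }
  rownames(seg) <- NULL
  result$segments <- seg
  result
}

#' @export
print.cbs_result <- function(x, ...) {
  cat("cbs_result:", x$sample_id, "-", nrow(x$segments), "segments on",
      length(unique(x$segments$chrom)), "chromosomes\n")
  invisible(x)
}

#' Write segments as TSV (and optionally BED5)
#'
#' @param result A `cbs_result`.
#' @param path Output TSV path (chrom, start, end, n_windows, mean_log2,
#'   sum_ratio; header line).
#' @param bed_path Optional BED5 output (name = sample id, score =
#'   1000 * |mean_log2| capped).
#' @return `path`, invisibly.
#' @export
write_segments <- function(result, path, bed_path = NULL) {
  stopifnot(inherits(result, "cbs_result"))
  seg <- result$segments
  out <- seg[, c("chrom", "start", "end", "n_windows", "mean_log2",
                 "sum_ratio")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(seg$chrom, seg$start, seg$end, result$sample_id,
                      pmin(round(1000 * abs(seg$mean_log2)), 1000))
    write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
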