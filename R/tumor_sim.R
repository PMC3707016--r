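# In-silico dilution and detection-limit analysis: simulated control
# cohorts, tumor-profile overlays, ROC curves, and synthetic
# prostate-like tumor profiles.

#' Simulate a control ratio profile
#'
#' One draw per window from `Normal(mean_i, sd_i)`, truncated at 0
#' (ratios cannot be negative).
#'
#' @param mean,sd Numeric vectors of per-window means and SDs.
#' @return Numeric ratio vector.
#' @export
simulate_control <- function(mean, sd) {
  stopifnot(length(mean) == length(sd), all(sd >= 0))
  pmax(rnorm(length(mean), mean, sd), 0)
}

#' In-silico dilution of a tumor profile
#'
#' `diluted_i = 1 - lambda + lambda * ratio_i`, where `lambda` is the
#' fraction of tumor DNA. At `lambda = 0` the profile is flat (pure
#' normal DNA); at `lambda = 1` it is the undiluted tumor.
#'
#' @param ratio Per-window tumor copy-number ratios (1 = diploid).
#' @param lambda Tumor-DNA fraction in \[0, 1\].
#' @return The diluted per-window expected ratios.
#' @export
dilute <- function(ratio, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (any(ratio < 0, na.rm = TRUE)) stop("tumor ratios must be >= 0")
  1 - lambda + lambda * ratio
}

#' Simulate a tumor-bearing case profile
#'
#' The control mean is multiplied by the diluted tumor copy-number ratio
#' and noise is drawn as in [simulate_control()].
#'
#' @param tumor Per-window tumor copy-number ratios.
#' @param lambda Tumor-DNA fraction in \[0, 1\].
#' @param mean,sd Control baseline per-window mean and SD.
#' @return Numeric ratio vector.
#' @export
simulate_case <- function(tumor, lambda, mean, sd) {
  stopifnot(length(tumor) == length(mean))
  simulate_control(mean * dilute(tumor, lambda), sd)
}

#' ROC analysis of case versus control scores
#'
#' Sweeps thresholds over the pooled scores; at threshold t, sensitivity
#' is the fraction of cases with score >= t and specificity the fraction
#' of controls with score < t. The AUC is the trapezoid area, equal to
#' the Mann-Whitney pair statistic with half-credit for ties. The
#' operating point maximizes the Youden index (sensitivity +
#' specificity - 1); ties go to the higher specificity.
#'
#' @param cases,controls Numeric score vectors (higher = more aberrant).
#' @return A `roc_result`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, and `operating` (threshold, sensitivity,
#'   specificity, youden).
#' @export
roc <- function(cases, controls) {
  stopifnot(length(cases) > 0, length(controls) > 0)
  thr <- c(-Inf, sort(unique(c(cases, controls))), Inf)
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(controls < t), numeric(1))
  # Mann-Whitney AUC with half-credit for ties
  cmp <- outer(cases, controls, function(a, b)
    (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 operating = list(threshold = thr[best],
                                  sensitivity = sens[best],
                                  specificity = spec[best],
                                  youden = youden[best])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f; Youden point sens %.3f / spec %.3f\n",
              x$auc, x$operating$sensitivity, x$operating$specificity))
  invisible(x)
}

#' Expand a segment table to per-window copy-number ratios
#'
#' @param segments Data.frame with `chrom`, `start`, `end`, `ratio`
#'   (copy-number ratio, 1 = diploid). Windows not covered by any
#'   segment get ratio 1.
#' @param windows A `window_set` or any data.frame with `chrom`,
#'   `start`, `end`; windows are matched by their midpoints.
#' @return Numeric ratio vector, one per window.
#' @export
profile_from_segments <- function(segments, windows) {
  mid <- (windows$start + windows$end) / 2
  ratio <- rep(1, nrow(windows))
  for (s in seq_len(nrow(segments))) {
    hit <- windows$chrom == segments$chrom[s] &
      mid >= segments$start[s] & mid < segments$end[s]
    ratio[hit] <- segments$ratio[s]
  }
  ratio
}

#' Read / write tumor profile segment tables
#'
#' TSV with header: chrom, start, end, ratio.
#'
#' @param path File path.
#' @return Data.frame with those columns.
#' @export
read_tumor_segments <- function(path) {
  seg <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "ratio")
  if (!all(need %in% names(seg)))
    stop("tumor segment table needs columns: ", paste(need, collapse = ", "))
  seg[, need]
}

#' @rdname read_tumor_segments
#' @param segments Data.frame to write.
#' @export
write_tumor_segments <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate prostate-cancer-like tumor profiles
#'
#' Each profile carries the hallmark arm-level events of metastatic
#' prostate cancer with their approximate published frequencies - 8p
#' loss, 8q gain, AR (X) gain - plus the TMPRSS2-ERG-like focal deletion
#' and additional random arm-level gains/losses, expressed as
#' copy-number ratios over the supplied windows. Chromosome-arm
#' boundaries are taken as the midpoint of each chromosome.
#'
#' @param n_profiles Number of profiles.
#' @param windows Data.frame with `chrom`, `start`, `end` (window or bin
#'   grid the profiles are expressed on).
#' @param p_events Named numeric vector of event probabilities
#'   (`loss_8p`, `gain_8q`, `gain_ar`, `del_tmprss2`, `extra`).
#' @param n_extra Mean number of additional random arm-level events.
#' @return Matrix of copy-number ratios, windows x profiles.
#' @export
simulate_tumor_profiles <- function(n_profiles, windows,
                                    p_events = c(loss_8p = 0.4, gain_8q = 0.35,
                                                 gain_ar = 0.33,
                                                 del_tmprss2 = 0.5,
                                                 extra = 1),
                                    n_extra = 3) {
  chroms <- unique(windows$chrom)
  mid <- (windows$start + windows$end) / 2
  arm <- function(chrom, which) {
    rows <- which(windows$chrom == chrom)
    if (length(rows) == 0) return(integer(0))
    lim <- mean(range(mid[rows]))
    if (which == "p") rows[mid[rows] <= lim] else rows[mid[rows] > lim]
  }
  # map hallmark loci onto the available chromosomes (synthetic genomes
  # use their own names; fall back to positional analogues)
  chr8 <- if ("chr8" %in% chroms) "chr8" else chroms[min(2, length(chroms))]
  chrX <- if ("chrX" %in% chroms) "chrX" else chroms[length(chroms)]
  chr21 <- if ("chr21" %in% chroms) "chr21" else
    chroms[max(1, length(chroms) - 1)]
  out <- matrix(1, nrow = nrow(windows), ncol = n_profiles)
  for (j in seq_len(n_profiles)) {
    r <- rep(1, nrow(windows))
    if (runif(1) < p_events[["loss_8p"]]) r[arm(chr8, "p")] <- 0.5
    if (runif(1) < p_events[["gain_8q"]]) r[arm(chr8, "q")] <- 1.5
    if (runif(1) < p_events[["gain_ar"]]) {
      rows <- arm(chrX, "q")
      if (length(rows) > 0) {
        span <- rows[seq_len(max(1, length(rows) %/% 3))]
        r[span] <- 2
      }
    }
    if (runif(1) < p_events[["del_tmprss2"]]) {
      rows <- arm(chr21, "q")
      if (length(rows) > 0) {
        span <- rows[seq_len(max(1, length(rows) %/% 4))]
        r[span] <- 0.5
      }
    }
    n_ev <- rbinom(1, 2 * n_extra, 0.5)
    for (e in seq_len(n_ev)) {
      chrom <- sample(chroms, 1)
      side <- sample(c("p", "q"), 1)
      rows <- arm(chrom, side)
      if (length(rows) == 0) next
      r[rows] <- if (runif(1) < 0.5) 0.5 else 1.5
    }
    out[, j] <- r
  }
  out
}

#' Heavily aberrant synthetic tumor profile
#'
#' A deterministic, massively aneuploid copy-number profile in the
#' spirit of the HT29 colorectal cancer cell line: whole-chromosome and
#' arm-level gains and losses over roughly two-thirds of the genome,
#' plus focal high-level amplifications. Intended for detection-limit
#' experiments at very low tumor fractions; it is a synthetic analogue,
#' not the measured HT29 karyotype.
#'
#' @param bins Data.frame with `chrom`, `start`, `end` (see
#'   [genome_bins()]).
#' @return Numeric copy-number ratio vector, one per bin.
#' @export
aberrant_profile <- function(bins) {
  r <- rep(1, nrow(bins))
  mid <- (bins$start + bins$end) / 2
  half <- function(ch, which) {
    rows <- which(bins$chrom == ch)
    if (length(rows) == 0) return(integer(0))
    lim <- mean(range(mid[rows]))
    if (which == "p") rows[mid[rows] <= lim] else rows[mid[rows] > lim]
  }
  whole <- function(ch) which(bins$chrom == ch)
  gain <- c("chr7", "chr13", "chr19", "chr20", "chr16")
  loss <- c("chr4", "chr18", "chr21", "chr14", "chr6")
  for (ch in intersect(gain, bins$chrom)) r[whole(ch)] <- 1.5
  for (ch in intersect(loss, bins$chrom)) r[whole(ch)] <- 0.5
  r[half("chr8", "p")] <- 0.5
  r[half("chr8", "q")] <- 2
  r[half("chr17", "p")] <- 0.5
  r[half("chr10", "q")] <- 1.5
  r[half("chr5", "q")] <- 1.5
  r[half("chr9", "p")] <- 0.5
  # focal high-level amplifications
  for (ch in intersect(c("chr8", "chr20", "chr5"), bins$chrom)) {
    rows <- half(ch, "q")
    if (length(rows) >= 10) r[rows[seq_len(10)]] <- 3
  }
  r
}

#' Detection-limit analysis over a dilution grid
#'
#' For each tumor-DNA fraction `lambda`, simulates a control cohort from
#' the baseline, then `n_controls` held-out controls and one case per
#' tumor profile (diluted at `lambda`), scores every sample with the
#' genome-wide z-score against the cohort, and summarizes case/control
#' separation by ROC.
#'
#' @param tumors Matrix of tumor copy-number ratios (windows x
#'   profiles), e.g. from [simulate_tumor_profiles()].
#' @param lambdas Numeric vector of tumor-DNA fractions.
#' @param mean,sd Baseline per-window mean and SD of control ratios.
#' @param n_controls Held-out controls per lambda (default 100).
#' @param n_cohort Reference-cohort size (default 10, scored
#'   leave-one-out internally).
#' @param seed Integer seed.
#' @return A data.frame with one row per lambda: `lambda`, `auc`,
#'   `sensitivity`, `specificity` (at the Youden point), `n_cases`,
#'   `n_controls`, plus attribute `scores` (list of per-lambda score
#'   lists).
#' @export
detection_limit <- function(tumors, lambdas, mean, sd, n_controls = 100,
                            n_cohort = 10, seed = 1) {
  tumors <- as.matrix(tumors)
  stopifnot(nrow(tumors) == length(mean), length(mean) == length(sd))
  set.seed(seed)
  rows <- vector("list", length(lambdas))
  scores <- vector("list", length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    cohort <- vapply(seq_len(n_cohort), function(i) simulate_control(mean, sd),
                     numeric(length(mean)))
    ref <- control_reference(cohort)
    ctl_z <- vapply(seq_len(n_controls), function(i) {
      x <- simulate_control(mean, sd)
      aneuploidy_score(x, ref)$genome_wide_z
    }, numeric(1))
    case_z <- vapply(seq_len(ncol(tumors)), function(j) {
      x <- simulate_case(tumors[, j], lam, mean, sd)
      aneuploidy_score(x, ref)$genome_wide_z
    }, numeric(1))
    rc <- roc(case_z, ctl_z)
    rows[[li]] <- data.frame(lambda = lam, auc = rc$auc,
                             sensitivity = rc$operating$sensitivity,
                             specificity = rc$operating$specificity,
                             n_cases = ncol(tumors),
                             n_controls = n_controls)
    scores[[li]] <- list(cases = case_z, controls = ctl_z)
  }
  out <- do.call(rbind, rows)
  attr(out, "scores") <- scores
  out
}

#' Fixed-size bin grid over a genome
#'
#' The default chromosome lengths approximate GRCh37 (Mb resolution),
#' giving a grid comparable to the roughly 2,900 one-megabase windows a
#' male genome yields after mappability filtering.
#'
#' @param chrom_lengths Named chromosome lengths in bp (default:
#'   approximate GRCh37 autosomes plus X).
#' @param bin_size Bin size in bp (default 1 Mbp).
#' @return Data.frame with `chrom`, `start`, `end`.
#' @export
genome_bins <- function(chrom_lengths = NULL, bin_size = 1e6) {
  if (is.null(chrom_lengths)) {
    mb <- c(chr1 = 249, chr2 = 243, chr3 = 198, chr4 = 191, chr5 = 181,
            chr6 = 171, chr7 = 159, chr8 = 146, chr9 = 141, chr10 = 136,
            chr11 = 135, chr12 = 134, chr13 = 115, chr14 = 107,
            chr15 = 103, chr16 = 90, chr17 = 81, chr18 = 78, chr19 = 59,
            chr20 = 63, chr21 = 48, chr22 = 51, chrX = 155)
    chrom_lengths <- mb * 1e6
  }
  rows <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - bin_size, by = bin_size)
    data.frame(chrom = ch, start = starts, end = starts + bin_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Null calibration of the genome-wide z-score
#'
#' Simulates held-out null (healthy) samples and scores each with the
#' genome-wide z against a simulated control cohort. Samples are scored
#' in batches, each batch against an independently simulated cohort, so
#' the summary averages over cohort draws rather than conditioning on a
#' single one.
#'
#' @param mean,sd Baseline per-bin mean and SD.
#' @param n_samples Total held-out null samples (default 500).
#' @param n_cohort Controls per cohort (default 10).
#' @param n_batches Number of independent cohorts (default 20).
#' @param seed Integer seed.
#' @return Numeric vector of `n_samples` genome-wide z-scores.
#' @export
null_calibration <- function(mean, sd, n_samples = 500, n_cohort = 10,
                             n_batches = 20, seed = 1) {
  set.seed(seed)
  per <- ceiling(n_samples / n_batches)
  gz <- numeric(0)
  for (b in seq_len(n_batches)) {
    cohort <- vapply(seq_len(n_cohort),
                     function(i) simulate_control(mean, sd),
                     numeric(length(mean)))
    ref <- control_reference(cohort)
    gz <- c(gz, vapply(seq_len(min(per, n_samples - length(gz))), function(i)
      aneuploidy_score(simulate_control(mean, sd), ref)$genome_wide_z,
      numeric(1)))
    if (length(gz) >= n_samples) break
  }
  gz
}

#' Per-window baseline noise at a given sequencing depth
#'
#' Counting noise for shallow WGS: with `reads` reads spread over
#' `n_windows` equal windows the per-window count is approximately
#' Poisson, so the ratio SD is `1 / sqrt(reads / n_windows)`. Used to
#' parameterize simulated cohorts at a target depth (e.g. 3 million
#' reads, the assay's typical yield).
#'
#' @param reads Total mapped reads.
#' @param n_windows Number of windows the reads are spread over.
#' @return The per-window ratio SD.
#' @export
depth_noise_sd <- function(reads, n_windows) {
  sqrt(n_windows / reads)
}
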