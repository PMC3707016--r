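# Reference preparation: PAR masking, read-length mappability, and the
# equal-mappability window grid that all downstream counting uses.

#' Read a reference genome from FASTA
#'
#' Sequences are upper-cased and names truncated at the first whitespace.
#' Any IUPAC ambiguity code other than A/C/G/T is converted to N, so the
#' working alphabet downstream is always \{A, C, G, T, N\}.
#'
#' @param path Path to a (possibly multi-sequence) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  as_genome(genome)
}

#' Coerce to a validated reference genome
#'
#' Accepts a named [Biostrings::DNAStringSet] or a named character vector
#' and returns a `DNAStringSet` with unique chromosome names and alphabet
#' restricted to A/C/G/T/N (other letters become N).
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @return A named [Biostrings::DNAStringSet].
#' @export
as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or named character vector")
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(genome)))
    stop("chromosome names must be unique")
  chars <- as.character(genome)
  cleaned <- chartr("RYSWKMBDHVryswkmbdhv", strrep("N", 20), toupper(chars))
  if (!identical(cleaned, chars)) genome <- Biostrings::DNAStringSet(cleaned)
  genome
}

.genome_chars <- function(genome) {
  out <- as.character(genome)
  names(out) <- names(genome)
  out
}

#' Read genomic intervals from a BED file
#'
#' Plain 3+ column BED (0-based, half-open). A fourth column, when
#' present, is kept as `name`.
#'
#' @param path BED file path.
#' @return A data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  bed <- read.table(text = lines, sep = "\t", header = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = bed[[1]],
                    start = as.numeric(bed[[2]]),
                    end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4) out$name <- bed[[4]]
  if (any(!is.finite(out$start)) || any(!is.finite(out$end)))
    stop("non-numeric coordinates in BED file: ", path)
  out
}

#' Mask intervals of a reference genome with N
#'
#' Used to mask the pseudo-autosomal region (PAR) of the Y chromosome so
#' that PAR sequence is represented only once and reads from it map
#' uniquely to X. Overlapping intervals are masked as their union.
#'
#' @param genome Reference genome (see [as_genome()]).
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open), e.g. from [read_bed()]. May have zero rows.
#' @return The genome with the intervals replaced by N; lengths unchanged.
#' @export
mask_par <- function(genome, intervals) {
  genome <- as_genome(genome)
  if (is.null(intervals) || nrow(intervals) == 0) return(genome)
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  for (r in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[r]
    s <- intervals$start[r]; e <- intervals$end[r]
    if (!chrom %in% names(genome))
      stop("interval on unknown chromosome: ", chrom, ":", s, "-", e)
    if (s < 0 || e > lens[[chrom]] || s >= e)
      stop("interval outside chromosome bounds: ", chrom, ":", s, "-", e)
  }
  chars <- .genome_chars(genome)
  for (r in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[r]
    s <- intervals$start[r]; e <- intervals$end[r]
    substr(chars[[chrom]], s + 1, e) <- strrep("N", e - s)
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(genome)
  out
}

#' Compute the read-length mappability track
#'
#' A position is mappable when the `read_length`-mer starting there
#' contains no N and occurs exactly once in the genome. By default
#' occurrences on either strand count, i.e. a k-mer whose reverse
#' complement appears elsewhere is not unique. This emulates unique
#' alignability of virtual reads of the sequencing read length (150 bp
#' for the assay this package targets).
#'
#' @param genome Reference genome.
#' @param read_length Virtual read length in bp (default 150).
#' @param both_strands Count reverse-complement occurrences as hits
#'   (default `TRUE`).
#' @return An object of class `mappability_track`: a list with `mappable`
#'   (named list of logical vectors over start positions) and
#'   `read_length`.
#' @export
mappability_track <- function(genome, read_length = 150L, both_strands = TRUE) {
  genome <- as_genome(genome)
  read_length <- as.integer(read_length)
  if (read_length < 1) stop("read_length must be >= 1")
  lens <- Biostrings::width(genome)
  if (read_length > max(lens)) {
    warning("read_length exceeds the longest chromosome; track is all-false")
    mappable <- lapply(lens, function(n) rep(FALSE, n))
    names(mappable) <- names(genome)
  } else {
    mappable <- .kmer_unique_positions(.genome_chars(genome), read_length,
                                       both_strands)
  }
  structure(list(mappable = mappable, read_length = read_length),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  tot <- sum(vapply(x$mappable, sum, numeric(1)))
  cat("mappability_track:", length(x$mappable), "chromosomes,",
      format(tot, big.mark = ","), "mappable positions (read length",
      x$read_length, "bp)\n")
  invisible(x)
}

# Apportion n_windows across chromosomes so that every window holds
# floor(total/n) or floor(total/n)+1 mappable positions while never
# crossing a chromosome boundary. Feasible whenever every chromosome's
# mappable count is large relative to the window quota; otherwise fall
# back to at least one window per non-empty chromosome with a warning.
.apportion_windows <- function(m_per_chrom, n_windows) {
  total <- sum(m_per_chrom)
  q <- total %/% n_windows
  nonzero <- m_per_chrom > 0
  k_min <- ifelse(nonzero, ceiling(m_per_chrom / (q + 1)), 0)
  k_max <- ifelse(nonzero, pmax(floor(m_per_chrom / q), 1), 0)
  if (sum(k_min) <= n_windows && n_windows <= sum(k_max)) {
    k <- k_min
    left <- n_windows - sum(k)
    for (i in seq_along(k)) {
      if (left <= 0) break
      add <- min(left, k_max[i] - k[i])
      k[i] <- k[i] + add
      left <- left - add
    }
  } else {
    warning("cannot hold every window to floor(total/n) (+1) mappable ",
            "positions without crossing a chromosome; using proportional ",
            "apportionment")
    k <- pmax(round(n_windows * m_per_chrom / total), as.integer(nonzero))
    while (sum(k) > n_windows) k[which.max(k)] <- k[which.max(k)] - 1
    while (sum(k) < n_windows) {
      i <- which.max(m_per_chrom / pmax(k, 1))
      k[i] <- k[i] + 1
    }
  }
  k
}

#' Build equal-mappability windows
#'
#' Partitions the genome's mappable positions, in genomic order, into
#' `n_windows` windows holding `floor(total/n)` or `floor(total/n) + 1`
#' positions each. Windows never cross chromosome boundaries; within a
#' chromosome the larger windows are placed last. Each window spans from
#' its first mappable position to one past its last, so spans of adjacent
#' windows may leave unmappable gaps between them.
#'
#' @param track A `mappability_track` from [mappability_track()].
#' @param n_windows Number of windows over the whole genome.
#' @return A `window_set`: data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open span), `n_mappable` and `gc` (NA until
#'   [window_gc()] is run), with the read length as an attribute.
#' @export
build_windows <- function(track, n_windows) {
  stopifnot(inherits(track, "mappability_track"))
  n_windows <- as.integer(n_windows)
  if (n_windows < 1) stop("n_windows must be >= 1")
  m_per_chrom <- vapply(track$mappable, sum, numeric(1))
  total <- sum(m_per_chrom)
  if (total < n_windows)
    stop("n_windows (", n_windows, ") exceeds total mappable positions (",
         total, ")")
  k <- .apportion_windows(m_per_chrom, n_windows)
  rows <- vector("list", length(track$mappable))
  for (ci in seq_along(track$mappable)) {
    if (k[ci] == 0) next
    pos <- which(track$mappable[[ci]]) - 1L   # 0-based
    m <- length(pos)
    base <- m %/% k[ci]
    extra <- m %% k[ci]
    sizes <- c(rep(base, k[ci] - extra), rep(base + 1L, extra))
    ends_idx <- cumsum(sizes)
    starts_idx <- c(0L, head(ends_idx, -1)) + 1L
    rows[[ci]] <- data.frame(
      chrom = names(track$mappable)[ci],
      start = pos[starts_idx],
      end = pos[ends_idx] + 1L,
      n_mappable = sizes,
      stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, rows)
  rownames(win) <- NULL
  win$gc <- NA_real_
  structure(win, class = c("window_set", "data.frame"),
            read_length = track$read_length)
}

#' Annotate windows with GC content
#'
#' GC fraction of the window span, computed as (G+C)/(A+C+G+T); N bases
#' are excluded from the denominator. Windows whose span is entirely N
#' get `NA`.
#'
#' @param genome Reference genome the windows were built on.
#' @param windows A `window_set`.
#' @return The `window_set` with its `gc` column filled in.
#' @export
window_gc <- function(genome, windows) {
  genome <- as_genome(genome)
  .check_windows(windows)
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  gc <- rep(NA_real_, nrow(windows))
  for (chrom in unique(windows$chrom)) {
    if (!chrom %in% names(genome))
      stop("windows on unknown chromosome: ", chrom)
    idx <- which(windows$chrom == chrom)
    if (any(windows$start[idx] < 0) || any(windows$end[idx] > lens[[chrom]]))
      stop("window outside chromosome bounds on ", chrom)
    v <- Biostrings::Views(genome[[chrom]], start = windows$start[idx] + 1,
                           end = windows$end[idx])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    g_c <- freq[, "G"] + freq[, "C"]
    gc[idx] <- ifelse(acgt > 0, g_c / acgt, NA_real_)
  }
  windows$gc <- gc
  windows
}

.check_windows <- function(windows) {
  if (!is.data.frame(windows) ||
      !all(c("chrom", "start", "end", "n_mappable") %in% names(windows)))
    stop("windows must be a window_set data.frame ",
         "(chrom, start, end, n_mappable, gc)")
  invisible(windows)
}

#' Write / read a window set as BED-like TSV
#'
#' Five tab-separated columns: chrom, start, end, n_mappable, gc_fraction.
#'
#' @param windows A `window_set`.
#' @param path Output path.
#' @param header Write a header line (default `FALSE`, plain BED-like).
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path, header = FALSE) {
  .check_windows(windows)
  out <- windows[, c("chrom", "start", "end", "n_mappable", "gc")]
  names(out)[5] <- "gc_fraction"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^chrom\t", first)
  win <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (!has_header)
    names(win) <- c("chrom", "start", "end", "n_mappable", "gc_fraction")
  names(win)[names(win) == "gc_fraction"] <- "gc"
  structure(win[, c("chrom", "start", "end", "n_mappable", "gc")],
            class = c("window_set", "data.frame"))
}
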