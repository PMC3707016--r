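# Split-read mapping of rearrangement breakpoints in fragmented cfDNA:
# each 150 bp read is split into its first and last 60 bp (30 bp gap),
# the halves are aligned independently, discordant pairs are filtered
# and classified, and junctions are refined to base-pair resolution.

#' Split a read into head and tail fragments
#'
#' Head = first 60 bp, tail = last 60 bp; for a 150 bp read this leaves
#' a 30 bp gap between the fragments. Reads shorter than 120 bp are
#' rejected (`NULL`), since head and tail would overlap.
#'
#' @param read Read sequence (single character string).
#' @param frag_length Fragment length (default 60).
#' @return List with `head`, `tail`, `gap` (bp between the fragments)
#'   and `read`, or `NULL` for reads shorter than `2 * frag_length`.
#' @export
split_read <- function(read, frag_length = 60L) {
  n <- nchar(read)
  if (n < 2 * frag_length) return(NULL)
  list(head = substr(read, 1L, frag_length),
       tail = substr(read, n - frag_length + 1L, n),
       gap = n - 2L * frag_length,
       read = read)
}

#' Build a seed index for the built-in fragment aligner
#'
#' Exact k-mer positions over the reference; used by [align_fragments()]
#' for exact-seed + ungapped-extension alignment. Sufficient for
#' synthetic fixtures and small references; pre-aligned SAM input can be
#' supplied instead for real data.
#'
#' @param genome Reference genome (see [as_genome()]).
#' @param k Seed length (default 20; must be in 4..31).
#' @return An opaque index object of class `seed_index`.
#' @export
seed_index <- function(genome, k = 20L) {
  genome <- as_genome(genome)
  idx <- .seed_index_build(.genome_chars(genome), as.integer(k))
  structure(list(ptr = idx, k = as.integer(k), chroms = names(genome)),
            class = "seed_index")
}

#' Align fragments with the built-in exact-seed aligner
#'
#' Seeds are exact k-mers at offsets 0, k, 2k, ... of the fragment (and
#' of its reverse complement); candidate loci are scored by ungapped
#' match count over the full fragment. A unique best hit gets mapping
#' quality 60; multiple equally good hits get 0 and `unique = FALSE`.
#'
#' @param index A `seed_index`.
#' @param fragments Character vector of fragment sequences.
#' @param min_identity Minimum fraction of matching bases for a hit to
#'   be reported (default 0.9).
#' @return Data.frame with one row per fragment: `chrom`, `pos`
#'   (0-based leftmost), `strand`, `mapq`, `score`, `n_best`, `mapped`,
#'   `unique`.
#' @export
align_fragments <- function(index, fragments, min_identity = 0.9) {
  stopifnot(inherits(index, "seed_index"))
  .seed_align(index$ptr, as.character(fragments), min_identity)
}

#' Split and align reads, pairing head and tail alignments
#'
#' @param reads Character vector of read sequences (named, or names are
#'   generated); reads shorter than 120 bp are skipped and counted.
#' @param index A `seed_index` on the reference.
#' @param frag_length Fragment length for [split_read()] (default 60).
#' @return Data.frame of aligned pairs: read id, sequence, and
#'   head_/tail_ columns from [align_fragments()]; attribute
#'   `n_skipped` counts too-short reads.
#' @export
align_split_reads <- function(reads, index, frag_length = 60L) {
  reads <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  ok <- nchar(reads) >= 2 * frag_length
  n_skipped <- sum(!ok)
  reads <- reads[ok]; ids <- ids[ok]
  n <- nchar(reads)
  heads <- substr(reads, 1L, frag_length)
  tails <- substr(reads, n - frag_length + 1L, n)
  ha <- align_fragments(index, heads)
  ta <- align_fragments(index, tails)
  out <- data.frame(id = ids, read = reads, stringsAsFactors = FALSE)
  names(ha) <- paste0("head_", names(ha))
  names(ta) <- paste0("tail_", names(ta))
  out <- cbind(out, ha, ta)
  attr(out, "n_skipped") <- n_skipped
  out
}

# is a (chrom, pos) inside any repeat interval?
.in_repeats <- function(chrom, pos, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(repeats))) {
    hit <- hit | (chrom == repeats$chrom[r] & pos >= repeats$start[r] &
                    pos < repeats$end[r])
  }
  hit
}

#' Identify discordantly mapped split-read pairs
#'
#' Pairs where either half is unmapped, maps with quality below
#' `min_mapq`, or falls inside a supplied repeat interval are dropped.
#' The rest are classified by the implied geometry: on the same
#' chromosome and strand, a gap between the fragments within
#' `[0, max_concordant_gap]` is concordant (dropped); a larger gap is a
#' deletion candidate; a negative gap is insertion-like; a strand
#' mismatch is an inversion candidate; different chromosomes are
#' interchromosomal.
#'
#' @param pairs Data.frame from [align_split_reads()].
#' @param min_mapq Minimum mapping quality per half (default 25).
#' @param repeats Optional repeat intervals (`chrom`, `start`, `end`).
#' @param max_concordant_gap Largest same-strand genomic gap still
#'   treated as concordant (default 1000 bp).
#' @param frag_length Fragment length used in the split (default 60).
#' @return Data.frame of candidates: pair columns plus `class`
#'   (deletion / insertion-like / inversion / interchromosomal) and
#'   `implied_span` (bp; NA when not applicable).
#' @export
find_discordant <- function(pairs, min_mapq = 25, repeats = NULL,
                            max_concordant_gap = 1000L, frag_length = 60L) {
  p <- pairs
  keep <- p$head_mapped & p$tail_mapped &
    !is.na(p$head_mapq) & !is.na(p$tail_mapq) &
    p$head_mapq >= min_mapq & p$tail_mapq >= min_mapq
  p <- p[keep, , drop = FALSE]
  if (nrow(p) > 0 && !is.null(repeats)) {
    bad <- .in_repeats(p$head_chrom, p$head_pos, repeats) |
      .in_repeats(p$tail_chrom, p$tail_pos, repeats)
    p <- p[!bad, , drop = FALSE]
  }
  if (nrow(p) == 0) {
    p$class <- character(0); p$implied_span <- numeric(0)
    return(p)
  }
  read_len <- nchar(p$read)
  # expected distance between head and tail leftmost positions when the
  # read is contiguous on the reference
  expect <- read_len - frag_length
  gap <- ifelse(p$head_strand == "+",
                p$tail_pos - p$head_pos - expect,
                p$head_pos - p$tail_pos - expect)
  same_chrom <- p$head_chrom == p$tail_chrom
  same_strand <- p$head_strand == p$tail_strand
  cls <- rep(NA_character_, nrow(p))
  cls[!same_chrom] <- "interchromosomal"
  cls[same_chrom & !same_strand] <- "inversion"
  cls[same_chrom & same_strand & gap > max_concordant_gap] <- "deletion"
  cls[same_chrom & same_strand & gap < 0] <- "insertion-like"
  p$class <- cls
  p$implied_span <- ifelse(same_chrom & same_strand, gap, NA_real_)
  p[!is.na(cls), , drop = FALSE]
}

#' Refine a discordant candidate to a base-pair breakpoint
#'
#' Scans every split position of the full read: the left part is
#' anchored by the head alignment, the right part by the tail
#' alignment, and the split maximizing the total number of matching
#' bases is chosen. Ties (microhomology at the junction) are resolved
#' to the leftmost coordinate on the head chromosome, and the
#' microhomology length is the number of tying splits minus one. If no
#' split reaches `min_identity` on both sides the candidate is returned
#' unrefined.
#'
#' Only same-strand candidates are refined; `+/-` (inversion)
#' candidates are reported at fragment resolution.
#'
#' @param candidate One row of [find_discordant()] output.
#' @param genome Reference genome.
#' @param min_identity Per-side identity required (default 0.9).
#' @param frag_length Fragment length used in the split (default 60).
#' @return List: `chromA`, `posA` (0-based last base before the
#'   junction), `chromB`, `posB` (0-based first base after), `orientation`,
#'   `microhomology`, `refined`, `class`, `id`.
#' @export
refine_breakpoint <- function(candidate, genome, min_identity = 0.9,
                              frag_length = 60L) {
  genome <- as_genome(genome)
  cand <- as.list(candidate)
  read <- cand$read
  n <- nchar(read)
  unrefined <- list(chromA = cand$head_chrom,
                    posA = cand$head_pos + frag_length - 1L,
                    chromB = cand$tail_chrom, posB = cand$tail_pos,
                    orientation = paste0(cand$head_strand, cand$tail_strand),
                    microhomology = NA_integer_, refined = FALSE,
                    class = cand$class, id = cand$id)
  if (cand$head_strand != cand$tail_strand) return(unrefined)
  if (cand$head_strand == "-") {
    # normalize to the plus strand: reverse-complement the read and swap
    # the fragment roles, so the left side is again the head anchor
    read <- .revcomp(read)
    tmp <- cand
    cand$head_chrom <- tmp$tail_chrom; cand$head_pos <- tmp$tail_pos
    cand$tail_chrom <- tmp$head_chrom; cand$tail_pos <- tmp$head_pos
  }
  left_ref <- as.character(genome[[cand$head_chrom]])
  right_ref <- as.character(genome[[cand$tail_chrom]])
  left_start <- cand$head_pos              # 0-based start of read base 1
  right_end <- cand$tail_pos + frag_length # 0-based one-past read end
  if (cand$head_chrom == cand$tail_chrom && right_end - left_start == n)
    return(unrefined)                      # contiguous: nothing to refine
  rchars <- strsplit(read, "")[[1]]
  lref <- substr(left_ref, left_start + 1L, left_start + n)
  lmatch <- cumsum(strsplit(lref, "")[[1]] == rchars[seq_len(nchar(lref))])
  rref <- substr(right_ref, right_end - n + 1L, right_end)
  roff <- n - nchar(rref)
  rm_ <- rev(cumsum(rev(strsplit(rref, "")[[1]] ==
                          rchars[(roff + 1):n])))
  best_total <- -1L; best_splits <- integer(0)
  for (s in seq_len(n - 1)) {                 # left part = read[1..s]
    lm <- if (s <= length(lmatch)) lmatch[s] else NA_integer_
    ri <- s + 1L - roff                       # index into rm_
    rmv <- if (ri >= 1 && ri <= length(rm_)) rm_[ri] else NA_integer_
    if (is.na(lm) || is.na(rmv)) next
    if (lm < min_identity * s || rmv < min_identity * (n - s)) next
    tot <- lm + rmv
    if (tot > best_total) { best_total <- tot; best_splits <- s }
    else if (tot == best_total) best_splits <- c(best_splits, s)
  }
  if (best_total < 0) return(unrefined)
  s <- min(best_splits)
  list(chromA = cand$head_chrom, posA = left_start + s - 1L,
       chromB = cand$tail_chrom, posB = right_end - (n - s),
       orientation = "++",
       microhomology = length(best_splits) - 1L, refined = TRUE,
       class = cand$class, id = cand$id)
}

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Cluster refined candidates into fusion calls
#'
#' Candidates whose breakpoints agree within `tolerance` bp (same
#' chromosomes and orientation) form one call; support is the cluster
#' size. Calls are sorted by support (descending), then coordinate.
#'
#' @param refined List of results from [refine_breakpoint()].
#' @param tolerance Maximum bp distance within a cluster (default 10).
#' @return Data.frame: `chromA`, `posA`, `chromB`, `posB`,
#'   `orientation`, `support`, `microhomology` (modal value), `refined`
#'   (fraction of supporting reads refined).
#' @export
call_fusions <- function(refined, tolerance = 10L) {
  empty <- data.frame(chromA = character(0), posA = integer(0),
                      chromB = character(0), posB = integer(0),
                      orientation = character(0), support = integer(0),
                      microhomology = integer(0), refined = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(refined) == 0) return(empty)
  df <- do.call(rbind, lapply(refined, function(r)
    data.frame(chromA = r$chromA, posA = r$posA, chromB = r$chromB,
               posB = r$posB, orientation = r$orientation,
               microhomology = r$microhomology,
               refined = r$refined, stringsAsFactors = FALSE)))
  df <- df[order(df$chromA, df$posA, df$chromB, df$posB), , drop = FALSE]
  cluster <- integer(nrow(df))
  cl <- 0L
  for (i in seq_len(nrow(df))) {
    if (i == 1) { cl <- 1L; cluster[i] <- cl; next }
    prev <- max(which(cluster[seq_len(i - 1)] == cl))
    same <- df$chromA[i] == df$chromA[prev] &&
      df$chromB[i] == df$chromB[prev] &&
      df$orientation[i] == df$orientation[prev] &&
      abs(df$posA[i] - df$posA[prev]) <= tolerance &&
      abs(df$posB[i] - df$posB[prev]) <= tolerance
    if (!same) cl <- cl + 1L
    cluster[i] <- cl
  }
  calls <- do.call(rbind, lapply(split(df, cluster), function(g) {
    mh <- g$microhomology[!is.na(g$microhomology)]
    data.frame(chromA = g$chromA[1],
               posA = as.integer(round(median(g$posA))),
               chromB = g$chromB[1],
               posB = as.integer(round(median(g$posB))),
               orientation = g$orientation[1],
               support = nrow(g),
               microhomology = if (length(mh)) as.integer(names(sort(
                 table(mh), decreasing = TRUE))[1]) else NA_integer_,
               refined = mean(g$refined),
               stringsAsFactors = FALSE)
  }))
  calls <- calls[order(-calls$support, calls$chromA, calls$posA), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' End-to-end split-read fusion detection
#'
#' Splits reads, aligns the halves with the built-in aligner, filters
#' and classifies discordant pairs, refines breakpoints and clusters
#' them into calls.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param genome Reference genome (object or FASTA path).
#' @param min_mapq,repeats,max_concordant_gap See [find_discordant()].
#' @param min_support Minimum supporting reads per reported call
#'   (default 1).
#' @param tolerance Clustering tolerance in bp (default 10).
#' @return Data.frame of calls as in [call_fusions()].
#' @export
detect_fusions <- function(reads, genome, min_mapq = 25, repeats = NULL,
                           max_concordant_gap = 1000L, min_support = 1L,
                           tolerance = 10L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_reference(genome)
  genome <- as_genome(genome)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  idx <- seed_index(genome)
  pairs <- align_split_reads(reads, idx)
  cands <- find_discordant(pairs, min_mapq = min_mapq, repeats = repeats,
                           max_concordant_gap = max_concordant_gap)
  refined <- lapply(seq_len(nrow(cands)), function(i)
    refine_breakpoint(cands[i, , drop = FALSE], genome))
  calls <- call_fusions(refined, tolerance = tolerance)
  calls[calls$support >= min_support, , drop = FALSE]
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write fusion calls as TSV and optional VCF-style BND records
#'
#' @param calls Data.frame from [call_fusions()].
#' @param path TSV output path.
#' @param vcf_path Optional path for a minimal VCF with BND ALT alleles.
#' @param genome Reference genome (needed for VCF REF bases).
#' @return `path`, invisibly.
#' @export
write_fusion_calls <- function(calls, path, vcf_path = NULL, genome = NULL) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting split reads\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    recs <- character(0)
    for (i in seq_len(nrow(calls))) {
      ref <- if (!is.null(genome))
        substr(as.character(as_genome(genome)[[calls$chromA[i]]]),
               calls$posA[i] + 1, calls$posA[i] + 1) else "N"
      alt <- sprintf("%s[%s:%d[", ref, calls$chromB[i], calls$posB[i] + 1L)
      recs <- c(recs, sprintf("%s\t%d\tbnd_%d\t%s\t%s\t.\tPASS\tSVTYPE=BND;SUPPORT=%d",
                              calls$chromA[i], calls$posA[i] + 1L, i, ref,
                              alt, calls$support[i]))
    }
    writeLines(c(hdr, recs), vcf_path)
  }
  invisible(path)
}
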