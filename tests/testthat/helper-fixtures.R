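# Shared builders for the test suite. Everything is generated in code;
# the end-to-end dataset is built once per session and reused.

toy_windows <- function(n, width = 1000, chrom = "c1", gc = 0.5,
                        n_mappable = 100) {
  w <- data.frame(chrom = chrom,
                  start = seq(0, by = width, length.out = n),
                  end = seq(width, by = width, length.out = n),
                  n_mappable = n_mappable,
                  gc = rep_len(gc, n),
                  stringsAsFactors = FALSE)
  structure(w, class = c("window_set", "data.frame"))
}

make_profile <- function(windows, ratio, log2ratio = NULL, id = "s",
                         sex = "male") {
  structure(list(windows = windows, ratio = ratio, log2ratio = log2ratio,
                 sample_id = id, sex = sex), class = "ratio_profile")
}

make_counts <- function(windows, counts, id = "s", sex = "male") {
  structure(list(windows = windows, counts = as.integer(counts),
                 total_reads = sum(counts), sample_id = id, sex = sex),
            class = "window_counts")
}

# brute-force mappability oracle: canonical k-mer multiplicities
brute_mappability <- function(genome, k) {
  chars <- as.character(plasmacnv::as_genome(genome))
  all_canon <- lapply(chars, function(s) {
    if (nchar(s) < k) return(character(0))
    kmers <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(chartr("N", "A", kmers))))
    hasN <- grepl("N", kmers, fixed = TRUE)
    canon <- pmin(kmers, rc)
    canon[hasN] <- NA
    canon
  })
  counts <- table(unlist(all_canon, use.names = FALSE))
  lapply(all_canon, function(canon) {
    v <- !is.na(canon) & counts[canon] == 1
    v[is.na(v)] <- FALSE
    c(as.vector(v), rep(FALSE, k - 1))
  })
}

# brute-force maximal arc t statistic (O(n^2) scan)
brute_max_stat <- function(x, min_width = 2) {
  n <- length(x)
  best <- list(i = NA, j = NA, stat = -1)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):n) {
      n1 <- j - i; n2 <- n - n1
      if (n2 < min_width) next
      a <- x[(i + 1):j]; b <- x[-((i + 1):j)]
      wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      t <- if (wss <= 1e-12 * (1 + sum(x^2)))
        sign(mean(a) - mean(b)) * 1e6
      else (mean(a) - mean(b)) /
        sqrt(wss / (n - 2) * (1 / n1 + 1 / n2))
      if (abs(t) > abs(best$stat) * (1 + 1e-9) + 1e-12)
        best <- list(i = i, j = j, stat = t)
    }
  }
  best
}

# one shared end-to-end dataset (genome + cohort + case + fusion reads)
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "plasmacnv-shared-fixture")
      cfg <- plasmacnv::fixture_config(
        chrom_lengths = c(chr1 = 70000L, chr8 = 60000L, chr21 = 50000L,
                          chrX = 50000L),
        n_windows = 100L, n_reads = 80000L, n_controls = 6L, lambda = 0.5,
        fusion = list(chrom = "chr21", del_start = 27500L,
                      del_end = 37500L, n_spanning = 9L,
                      n_background = 400L))
      # align the planted focal deletion with the fusion junction
      cfg$cna$start[cfg$cna$chrom == "chr21"] <- 27500L
      cfg$cna$end[cfg$cna$chrom == "chr21"] <- 37500L
      # window apportionment may warn on small multi-chromosome genomes
      cache <<- suppressWarnings(
        plasmacnv::generate_fixture(cfg, out_dir = dir, seed = 101))
    }
    cache
  }
})
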