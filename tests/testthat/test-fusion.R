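# Split-read fusion detection: split geometry, the built-in aligner,
# discordance classification, breakpoint refinement and calling.

test_that("split geometry is first/last 60 bp with a 30 bp gap", {
  read150 <- strrep("A", 150)
  sp <- split_read(read150)
  expect_equal(nchar(sp$head), 60)
  expect_equal(nchar(sp$tail), 60)
  expect_equal(sp$gap, 30)
  r <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
             collapse = "")
  sp2 <- split_read(r)
  expect_equal(sp2$head, substr(r, 1, 60))
  expect_equal(sp2$tail, substr(r, 91, 150))

  sp120 <- split_read(strrep("C", 120))
  expect_equal(sp120$gap, 0)
  expect_null(split_read(strrep("C", 119)))
})

test_that("the seed aligner finds unique loci on both strands", {
  set.seed(40)
  g <- synth_genome(c(c1 = 20000L, c2 = 15000L))
  idx <- seed_index(g)
  chars <- as.character(g)

  frag <- substr(chars[[2]], 5001, 5060)
  hit <- align_fragments(idx, frag)
  expect_equal(hit$chrom, "c2")
  expect_equal(hit$pos, 5000)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mapq, 60)
  expect_true(hit$unique)

  # reverse complement maps to the same locus on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(frag)))
  hit_rc <- align_fragments(idx, rc)
  expect_equal(hit_rc$pos, 5000)
  expect_equal(hit_rc$strand, "-")

  # a fragment from a duplicated block is ambiguous: mapq 0
  dup <- chars
  substr(dup[[1]], 1001, 1100) <- substr(dup[[2]], 2001, 2100)
  idx2 <- seed_index(dup)
  amb <- align_fragments(idx2, substr(dup[[2]], 2011, 2070))
  expect_false(amb$unique)
  expect_equal(amb$mapq, 0)
  expect_gte(amb$n_best, 2)
})

test_that("find_discordant classifies pair geometry and applies filters", {
  base <- data.frame(id = "r", read = strrep("A", 150),
                     head_chrom = "c1", head_pos = 1000L, head_strand = "+",
                     head_mapq = 60L, head_mapped = TRUE, head_unique = TRUE,
                     tail_chrom = "c1", tail_pos = 1090L, tail_strand = "+",
                     tail_mapq = 60L, tail_mapped = TRUE, tail_unique = TRUE,
                     stringsAsFactors = FALSE)
  # contiguous (gap 0): concordant, dropped
  expect_equal(nrow(find_discordant(base)), 0)
  # 30 bp insert-size-like wobble: still concordant
  near <- base; near$tail_pos <- 1120L
  expect_equal(nrow(find_discordant(near)), 0)
  # 3 Mbp apart: deletion candidate with the implied span
  del <- base; del$tail_pos <- base$tail_pos + 3000000L
  d <- find_discordant(del)
  expect_equal(d$class, "deletion")
  expect_equal(d$implied_span, 3e6)
  # strand mismatch: inversion; different chromosome: interchromosomal
  inv <- del; inv$tail_strand <- "-"
  expect_equal(find_discordant(inv)$class, "inversion")
  ich <- del; ich$tail_chrom <- "c2"
  expect_equal(find_discordant(ich)$class, "interchromosomal")
  # low mapping quality on either half is filtered out
  lowq <- del; lowq$tail_mapq <- 0L
  expect_equal(nrow(find_discordant(lowq)), 0)
  # repeat-region filter
  reps <- data.frame(chrom = "c1", start = 900, end = 1100)
  expect_equal(nrow(find_discordant(del, repeats = reps)), 0)
})

test_that("refinement recovers planted junctions to the base pair", {
  set.seed(41)
  g <- synth_genome(c(c1 = 40000L))
  chars <- as.character(g)[[1]]
  # deletion junction: [.., 10000) joined to [25000, ..): posA = 9999,
  # posB = 25000 (0-based)
  del_start <- 10000L; del_end <- 25000L
  idx <- seed_index(g)
  for (off in c(60, 75, 90)) {
    read <- paste0(substr(chars, del_start - off + 1, del_start),
                   substr(chars, del_end + 1, del_end + 150 - off))
    pairs <- align_split_reads(read, idx)
    cand <- find_discordant(pairs)
    expect_equal(cand$class, "deletion")
    bp <- refine_breakpoint(cand[1, ], g)
    expect_true(bp$refined)
    expect_equal(bp$posA, del_start - 1L)
    expect_equal(bp$posB, del_end)
  }

  # microhomology: the 4 bases ending the left flank also end the
  # deleted interval, so the junction is ambiguous over 4 positions;
  # make sure no accidental homology extends the ambiguity either way
  g2chars <- chars
  hom <- substr(g2chars, del_start - 3, del_start)
  substr(g2chars, del_end - 3, del_end) <- hom
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  if (substr(g2chars, del_start + 1, del_start + 1) ==
      substr(g2chars, del_end + 1, del_end + 1))
    substr(g2chars, del_end + 1, del_end + 1) <-
      flip[[substr(g2chars, del_end + 1, del_end + 1)]]
  if (substr(g2chars, del_start - 4, del_start - 4) ==
      substr(g2chars, del_end - 4, del_end - 4))
    substr(g2chars, del_end - 4, del_end - 4) <-
      flip[[substr(g2chars, del_end - 4, del_end - 4)]]
  g2 <- c(c1 = g2chars)
  read2 <- paste0(substr(g2chars, del_start - 75 + 1, del_start),
                  substr(g2chars, del_end + 1, del_end + 75))
  idx2 <- seed_index(g2)
  pairs2 <- align_split_reads(read2, idx2)
  cand2 <- find_discordant(pairs2)
  bp2 <- refine_breakpoint(cand2[1, ], g2)
  expect_equal(bp2$microhomology, 4L)
  expect_equal(bp2$posA, del_start - 1L - 4L)  # leftmost convention

  # a concordant read forced through refinement is not refined
  conc <- substr(chars, 3001, 3150)
  pc <- align_split_reads(conc, idx)
  fake <- pc; fake$class <- "deletion"; fake$implied_span <- 0
  expect_false(refine_breakpoint(fake[1, ], g)$refined)
})

test_that("call_fusions clusters supporting reads deterministically", {
  mk <- function(posA, posB, id) list(chromA = "c1", posA = posA,
                                      chromB = "c1", posB = posB,
                                      orientation = "++",
                                      microhomology = 0L, refined = TRUE,
                                      class = "deletion", id = id)
  five <- lapply(1:5, function(i) mk(1000L + (i %% 3), 5000L, i))
  calls <- call_fusions(five)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$support, 5)

  two <- c(lapply(1:3, function(i) mk(1000L, 5000L, i)),
           lapply(1:2, function(i) mk(20000L, 30000L, i + 3)))
  calls2 <- call_fusions(two)
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$support, c(3, 2))  # sorted by support

  expect_equal(nrow(call_fusions(list())), 0)
})

test_that("end-to-end fusion detection on the fixture is exact and specific", {
  fx <- shared_fixture()
  genome <- fx$genome
  calls <- detect_fusions(fx$fastq, genome, min_support = 3)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chromA, fx$truth$fusion$chrom)
  expect_equal(calls$posA, fx$truth$fusion$posA)
  expect_equal(calls$posB, fx$truth$fusion$posB)
  expect_gte(calls$support, fx$truth$fusion$n_spanning - 1)

  # no calls on rearrangement-free reads
  set.seed(42)
  chars <- as.character(genome)
  lens <- nchar(chars)
  n_conc <- 2000
  ci <- sample.int(length(chars), n_conc, replace = TRUE,
                   prob = lens / sum(lens))
  reads <- vapply(seq_len(n_conc), function(i) {
    p <- sample.int(lens[ci[i]] - 150, 1)
    substr(chars[[ci[i]]], p, p + 149)
  }, character(1))
  expect_equal(nrow(detect_fusions(reads, genome)), 0)

  # VCF/TSV output writers
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_fusion_calls(calls, tsv, vcf_path = vcf, genome = genome)
  expect_true(any(grepl("SVTYPE=BND", readLines(vcf))))
  expect_equal(nrow(read.table(tsv, header = TRUE, sep = "\t")), 1)
})
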