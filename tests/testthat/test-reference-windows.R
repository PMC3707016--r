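# Reference preparation: PAR masking, mappability, window construction.

test_that("mask_par substitutes exactly the requested intervals", {
  set.seed(1)
  g <- synth_genome(c(chrY = 1000L))
  masked <- mask_par(g, data.frame(chrom = "chrY", start = 100, end = 200))
  s <- as.character(masked[[1]])
  expect_equal(nchar(s), 1000)
  expect_true(all(strsplit(substr(s, 101, 200), "")[[1]] == "N"))
  expect_equal(substr(s, 1, 100), substr(as.character(g[[1]]), 1, 100))
  expect_equal(substr(s, 201, 1000), substr(as.character(g[[1]]), 201, 1000))

  # empty interval list: identity
  expect_equal(as.character(mask_par(g, NULL)), as.character(g))
  expect_equal(as.character(mask_par(g, data.frame(chrom = character(0),
                                                   start = numeric(0),
                                                   end = numeric(0)))),
               as.character(g))

  # overlapping intervals mask their union
  m2 <- mask_par(g, data.frame(chrom = "chrY", start = c(100, 150),
                               end = c(200, 250)))
  n_masked <- Biostrings::letterFrequency(m2, "N")[1] -
    Biostrings::letterFrequency(g, "N")[1]
  expect_equal(as.numeric(n_masked), 150)
  # brute-force per-position union check
  pos_is_N <- strsplit(as.character(m2[[1]]), "")[[1]] == "N"
  in_union <- seq_len(1000) %in% c(101:200, 151:250)
  orig_N <- strsplit(as.character(g[[1]]), "")[[1]] == "N"
  expect_equal(pos_is_N, in_union | orig_N)

  expect_error(mask_par(g, data.frame(chrom = "chrY", start = 900,
                                      end = 1100)), "bounds")
  expect_error(mask_par(g, data.frame(chrom = "chrZ", start = 0, end = 10)),
               "unknown")
})

test_that("mappability marks unique, N-free k-mer starts", {
  set.seed(2)
  g <- synth_genome(c(c1 = 10000L))
  tr <- mappability_track(g, 150)
  v <- tr$mappable[[1]]
  # non-repetitive random sequence: everything before the tail is unique
  expect_true(all(v[1:(10000 - 150 + 1)]))
  expect_true(all(!v[(10000 - 150 + 2):10000]))

  # a duplicated 500 bp block kills both copies
  chars <- as.character(g)
  dup <- paste0(chars[[1]], paste(rep("A", 50), collapse = ""),
                substr(chars[[1]], 2001, 2500))
  tr2 <- mappability_track(c(c1 = dup), 150)
  v2 <- tr2$mappable[[1]]
  # any 150-mer fully inside the original copy [2000, 2500) is duplicated
  inside <- 2000:(2500 - 150)  # 0-based starts; R index +1
  expect_true(all(!v2[inside + 1]))
  expect_true(v2[1])

  # N runs make overlapping reads unmappable
  withN <- chars[[1]]
  substr(withN, 3001, 3200) <- strrep("N", 200)
  tr3 <- mappability_track(c(c1 = withN), 150)
  v3 <- tr3$mappable[[1]]
  expect_true(all(!v3[(3001 - 149):3200]))
  expect_true(v3[3000 - 149])

  # read longer than every chromosome: all-false with a warning
  expect_warning(tr4 <- mappability_track(c(c1 = "ACGTACGTAC"), 150),
                 "longest")
  expect_true(all(!tr4$mappable[[1]]))
})

test_that("mappability agrees with the brute-force k-mer oracle", {
  set.seed(3)
  for (k in c(10, 25, 40)) {
    g <- synth_genome(c(a = 4000L, b = 2500L))
    # plant a cross-chromosome duplication and an N run
    chars <- as.character(g)
    substr(chars[[2]], 501, 500 + k + 20) <- substr(chars[[1]], 1001,
                                                    1000 + k + 20)
    substr(chars[[1]], 2001, 2030) <- strrep("N", 30)
    tr <- mappability_track(chars, k)
    oracle <- brute_mappability(chars, k)
    expect_equal(tr$mappable[["a"]], unname(oracle[["a"]]))
    expect_equal(tr$mappable[["b"]], unname(oracle[["b"]]))
  }
})

test_that("build_windows partitions mappable positions evenly", {
  # 1000 mappable positions over one chromosome -> 10 windows of 100
  set.seed(4)
  g <- synth_genome(c(c1 = 1000L + 49L))
  tr <- mappability_track(g, 50)
  stopifnot(sum(tr$mappable[[1]]) == 1000)
  w <- build_windows(tr, 10)
  expect_equal(nrow(w), 10)
  expect_true(all(w$n_mappable == 100))

  # 1001 positions -> nine windows of 100 and one (the last) of 101
  g2 <- synth_genome(c(c1 = 1001L + 49L))
  tr2 <- mappability_track(g2, 50)
  stopifnot(sum(tr2$mappable[[1]]) == 1001)
  w2 <- build_windows(tr2, 10)
  expect_equal(w2$n_mappable, c(rep(100L, 9), 101L))

  # conservation + sorted, non-overlapping half-open spans
  expect_equal(sum(w2$n_mappable), 1001)
  expect_true(all(diff(w2$start) > 0))
  expect_true(all(w2$start < w2$end))
  expect_true(all(utils::head(w2$end, -1) <= utils::tail(w2$start, -1) |
                    utils::head(w2$end, -1) <= w2$start[-1]))

  expect_error(build_windows(tr2, 5000), "exceeds")
})

test_that("windows never cross chromosomes and cover all mappable positions", {
  set.seed(5)
  g <- synth_genome(c(a = 30000L, b = 18000L, c = 12000L))
  tr <- mappability_track(g, 100)
  w <- suppressWarnings(build_windows(tr, 24))
  expect_equal(sum(w$n_mappable), sum(vapply(tr$mappable, sum, 1)))
  # per chromosome: windows tile that chromosome's mappable positions
  for (ch in names(tr$mappable)) {
    rows <- w[w$chrom == ch, ]
    pos <- which(tr$mappable[[ch]]) - 1
    expect_equal(rows$start[1], pos[1])
    expect_equal(rows$end[nrow(rows)], pos[length(pos)] + 1)
    expect_equal(sum(rows$n_mappable), length(pos))
    # within a chromosome the quota varies by at most one
    expect_lte(diff(range(rows$n_mappable)), 1)
  }
  # deterministic
  w2 <- suppressWarnings(build_windows(tr, 24))
  expect_identical(w, w2)
})

test_that("window GC is (G+C)/(A+C+G+T) with N excluded", {
  g <- c(c1 = paste0(strrep("GGCC", 25), strrep("ACGT", 25),
                     "AANNCG", strrep("T", 94)))
  w <- structure(data.frame(chrom = "c1",
                            start = c(0, 100, 200, 206),
                            end = c(100, 200, 206, 300),
                            n_mappable = 1, gc = NA_real_),
                 class = c("window_set", "data.frame"))
  w <- window_gc(g, w)
  expect_equal(w$gc[1], 1.0)
  expect_equal(w$gc[2], 0.5)
  expect_equal(w$gc[3], 0.5)   # AANNCG: 2 GC / 4 non-N
  expect_equal(w$gc[4], 0.0)
  # all-N span is flagged missing
  gN <- c(c1 = strrep("N", 300))
  wN <- window_gc(gN, w[1, ])
  expect_true(is.na(wN$gc[1]))
  expect_error(window_gc(g, toy_windows(4, width = 1e5)), "unknown|bounds")
})

test_that("window TSV round-trips with and without header", {
  set.seed(6)
  g <- synth_genome(c(c1 = 20000L))
  w <- window_gc(g, build_windows(mappability_track(g, 100), 8))
  for (hdr in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".bed")
    write_windows(w, path, header = hdr)
    back <- read_windows(path)
    expect_equal(back$start, w$start)
    expect_equal(back$n_mappable, w$n_mappable)
    expect_equal(back$gc, w$gc, tolerance = 1e-12)
  }
})
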