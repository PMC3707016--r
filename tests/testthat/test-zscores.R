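# z-score battery: per-window, segmental, region, genome-wide,
# significance calling and clustering.

test_that("window_z follows the standardization formula", {
  ctrl <- cbind(rep(0.9, 5), rep(1.0, 5), rep(1.1, 5))
  z <- window_z(rep(1.3, 5), ctrl)
  expect_equal(unname(z), rep(3, 5), tolerance = 1e-9)

  # sample equal to control means
  expect_true(all(window_z(rowMeans(ctrl), ctrl) == 0))

  # zero-SD windows are flagged missing
  ctrl0 <- ctrl; ctrl0[2, ] <- 1
  z0 <- window_z(rep(1.3, 5), ctrl0)
  expect_true(is.na(z0[2]))
  expect_false(anyNA(z0[-2]))

  expect_error(window_z(1:5, ctrl[, 1:2]), "at least 3")
  expect_error(window_z(1:4, ctrl), "different numbers")
})

test_that("leave-one-out excludes the control's own values", {
  set.seed(22)
  ctrl <- matrix(rnorm(50 * 5, 1, 0.1), 50, 5)
  z <- window_z(ctrl[, 2], ctrl, leave_out = 2)
  m <- rowMeans(ctrl[, -2]); s <- apply(ctrl[, -2], 1, sd)
  expect_equal(unname(z), (ctrl[, 2] - m) / s, tolerance = 1e-12)
  zm <- control_z_matrix(ctrl)
  expect_equal(unname(zm[, 2]), unname(z), tolerance = 1e-12)
})

test_that("cross-validated null z follows the scaled t reference", {
  set.seed(23)
  n <- 10
  ctrl <- matrix(rnorm(10000 * n, 1, 0.1), ncol = n)
  z <- control_z_matrix(ctrl)[, 1]
  # z = sqrt(n/(n-1)) * t with n-2 degrees of freedom
  ks <- stats::ks.test(z / sqrt(n / (n - 1)), "pt", df = n - 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("significant_fraction applies the >3 SD rule", {
  expect_equal(significant_fraction(rep(0, 10)),
               list(fraction_normal = 1.0, n_significant = 0L))
  r <- significant_fraction(c(-4, 0, 4, 1))
  expect_equal(r$fraction_normal, 0.5)
  expect_equal(r$n_significant, 2L)
  # boundary: |z| exactly 3 counts as significant (>= threshold)
  expect_equal(significant_fraction(c(3, -3, 0))$n_significant, 2L)

  # null expectation from the scaled-t reference via Monte Carlo
  set.seed(24)
  n <- 10; m <- 2909
  p_tail <- 2 * stats::pt(-3 / sqrt(n / (n - 1)), df = n - 2)
  counts <- replicate(40, {
    ctrl <- matrix(rnorm(m * n, 1, 0.03), ncol = n)
    significant_fraction(control_z_matrix(ctrl)[, 1])$n_significant
  })
  expect_equal(mean(counts), m * p_tail, tolerance = 0.25)
})

test_that("segmental z standardizes segment ratio sums against controls", {
  set.seed(25)
  n <- 60
  w <- toy_windows(n)
  ctrl <- matrix(1, n, 6) + matrix(rnorm(n * 6, 0, 0.02), n, 6)
  prof <- make_profile(w, rep(1, n))
  prof$log2ratio <- rep(0, n)
  res <- list(segments = data.frame(chrom = "c1", start = 0, end = 20000,
                                    first_window = 1L, last_window = 20L,
                                    n_windows = 20L, n_used = 20L,
                                    mean_log2 = 0,
                                    sum_ratio = sum(prof$ratio[1:20])),
              params = cbs_params(), sample_id = "s")
  class(res) <- "cbs_result"

  # flat controls with known per-sum SD; sample elevated by 0.1/window
  prof2 <- prof; prof2$ratio[1:20] <- 1.1
  res2 <- res; res2$segments$sum_ratio <- sum(prof2$ratio[1:20])
  sz <- segmental_z(prof2, res2, ctrl)
  sums <- colSums(ctrl[1:20, ])
  expect_equal(sz$z, (22 - mean(sums)) / sd(sums), tolerance = 1e-12)

  # sample equal to a control scores ~0
  prof3 <- prof; prof3$ratio <- ctrl[, 1]
  res3 <- res; res3$segments$sum_ratio <- sum(ctrl[1:20, 1])
  expect_lt(abs(segmental_z(prof3, res3, ctrl)$z), 2)

  # monotonicity: a constant gain strictly increases z
  zs <- vapply(c(0, 0.05, 0.1, 0.2), function(g) {
    p <- prof; p$ratio[1:20] <- 1 + g
    r <- res; r$segments$sum_ratio <- sum(p$ratio[1:20])
    segmental_z(p, r, ctrl)$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))

  # zero control SD flags the segment
  ctrl0 <- matrix(1, n, 6)
  expect_true(is.na(segmental_z(prof2, res2, ctrl0)$z))
})

test_that("trisomy-like gains give segmental z > 3 only on the gained chromosome", {
  set.seed(26)
  n_chr <- 4; n_win <- 400   # ~20 Mbp chromosomes at 50 kb windows
  w <- do.call(rbind, lapply(sprintf("chr%d", 1:n_chr), function(ch)
    toy_windows(n_win, chrom = ch)))
  w <- structure(w, class = c("window_set", "data.frame"))
  m <- n_chr * n_win
  sd_w <- sqrt(50000 / 3e6)    # per equal-mappability window at 3M reads
  ctrl <- matrix(pmax(rnorm(m * 10, 1, sd_w), 0), m, 10)
  smp <- pmax(rnorm(m, 1, sd_w), 0)
  tri <- w$chrom == "chr3"
  smp[tri] <- smp[tri] + 0.05  # 10% fetal/tumor fraction of a trisomy
  prof <- make_profile(w, smp)
  seg <- data.frame(chrom = sprintf("chr%d", 1:n_chr),
                    start = 0, end = n_win * 1000,
                    first_window = seq(1, m, n_win),
                    last_window = seq(n_win, m, n_win),
                    n_windows = n_win, n_used = n_win, mean_log2 = 0,
                    sum_ratio = NA)
  seg$sum_ratio <- vapply(seq_len(n_chr), function(i)
    sum(smp[seg$first_window[i]:seg$last_window[i]]), numeric(1))
  res <- structure(list(segments = seg, params = cbs_params(),
                        sample_id = "s"), class = "cbs_result")
  sz <- segmental_z(prof, res, ctrl)
  expect_gt(sz$z[sz$chrom == "chr3"], 3)
  expect_true(all(abs(sz$z[sz$chrom != "chr3"]) < 3))
})

test_that("region z implements the expected-reads formula", {
  rr <- region_ratio(13000, 1e6, 1e6, 100e6)
  expect_equal(rr$reads_expected, 10000)
  expect_equal(rr$ratio, 1.3)
  expect_error(region_ratio(10, 1000, 0, 100), "positive")

  regions <- data.frame(chrom = "c1", start = 0, end = 1e6, name = "AR")
  smp <- list(counts = 13000, total = 1e6)
  ctls <- lapply(c(0.9, 1.0, 1.1), function(r)
    list(counts = r * 10000, total = 1e6))
  rz <- region_z(regions, smp, ctls, length_genome = 100e6)
  expect_equal(rz$z, 3, tolerance = 1e-9)
  expect_equal(rz$reads_expected, 10000)

  # null calibration: diploid draws stay within 3 SDs >= 99% of the time
  set.seed(27)
  hits <- 0
  reps <- 1000
  exp_reads <- 1000
  for (r in seq_len(reps)) {
    ctl_counts <- lapply(1:10, function(i)
      list(counts = rbinom(1, 1e5, exp_reads / 1e5), total = 1e5))
    smp_counts <- list(counts = rbinom(1, 1e5, exp_reads / 1e5), total = 1e5)
    z <- region_z(data.frame(chrom = "c1", start = 0, end = 1e6),
                  smp_counts, ctl_counts, length_genome = 100e6)$z
    if (abs(z) < 3) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("segmental and region z agree when region equals segment", {
  set.seed(28)
  n <- 40
  w <- toy_windows(n)
  total <- 40000L
  counts <- lapply(1:5, function(i) as.integer(rmultinom(1, total,
                                                         rep(1, n))))
  # identical totals: per-window ratio = count / mean(count)
  ratios <- lapply(counts, function(cc) cc / mean(cc))
  ctrl <- do.call(cbind, ratios[1:4])
  smp_ratio <- ratios[[5]]
  prof <- make_profile(w, smp_ratio)
  rows <- 11:20
  seg <- data.frame(chrom = "c1", start = w$start[11], end = w$end[20],
                    first_window = 11L, last_window = 20L, n_windows = 10L,
                    n_used = 10L, mean_log2 = 0,
                    sum_ratio = sum(smp_ratio[rows]))
  res <- structure(list(segments = seg, params = cbs_params(),
                        sample_id = "s"), class = "cbs_result")
  z_seg <- segmental_z(prof, res, ctrl)$z

  region <- data.frame(chrom = "c1", start = w$start[11], end = w$end[20])
  smp_rc <- list(counts = sum(counts[[5]][rows]), total = total)
  ctl_rc <- lapply(1:4, function(i)
    list(counts = sum(counts[[i]][rows]), total = total))
  z_reg <- region_z(region, smp_rc, ctl_rc, length_genome = n * 1000)$z
  expect_equal(z_seg, z_reg, tolerance = 1e-9)
})

test_that("S-score and genome-wide z reproduce the hand examples", {
  expect_equal(s_score(rep(0, 10)), 0)
  expect_equal(s_score(c(3, 4)), 25)
  expect_equal(s_score(c(3, NA, 4)), 25)
  expect_equal(genome_wide_z(24, c(10, 12, 14)), 6, tolerance = 1e-9)
  expect_error(genome_wide_z(24, c(10, 10, 10)), "zero SD")
})

test_that("aneuploidy_score detects aneuploid samples against a cohort", {
  set.seed(29)
  m <- 500; n <- 10
  ctrl <- matrix(pmax(rnorm(m * n, 1, 0.03), 0), m, n)
  ref <- control_reference(ctrl)
  null_s <- aneuploidy_score(pmax(rnorm(m, 1, 0.03), 0), ref)
  expect_lt(abs(null_s$genome_wide_z), 4)
  expect_gt(null_s$fraction_normal, 0.95)

  aneu <- pmax(rnorm(m, 1, 0.03), 0)
  aneu[1:100] <- aneu[1:100] + 0.15
  an_s <- aneuploidy_score(aneu, ref)
  expect_gt(an_s$genome_wide_z, 10)
  expect_lt(an_s$fraction_normal, 0.9)

  # scoring a control by index uses leave-one-out
  cs <- aneuploidy_score(3, ref)
  expect_lt(abs(cs$genome_wide_z), 4)
})

test_that("Manhattan clustering separates shared copy-number signatures", {
  # two-window toy distance
  zmat <- rbind(a = c(0, 0), b = c(1, 2))
  expect_equal(as.numeric(dist(zmat, method = "manhattan")), 3)

  # duplicate samples merge first at height 0
  z3 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  hc <- cluster_samples(z3)
  expect_equal(min(hc$height), 0)

  # metric axioms on a small fixture
  set.seed(30)
  zm <- matrix(rnorm(5 * 20), 5, 20)
  d <- as.matrix(dist(zm, method = "manhattan"))
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)

  # flat nulls vs a shared 8q-gain-like signature: disjoint subtrees
  set.seed(31)
  m <- 200
  base <- matrix(rnorm(10 * m, 0, 1), 10, m)
  base[6:10, 150:200] <- base[6:10, 150:200] + 4
  rownames(base) <- c(paste0("null", 1:5), paste0("gain", 1:5))
  hc2 <- cluster_samples(base)
  grp <- stats::cutree(hc2, k = 2)
  expect_equal(length(unique(grp[1:5])), 1)
  expect_equal(length(unique(grp[6:10])), 1)
  expect_false(grp[1] == grp[6])

  # newick export
  nwk <- tempfile(fileext = ".nwk")
  write_newick(hc2, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(base))
})

test_that("1-Mbp binning aggregates windows by midpoint", {
  w <- toy_windows(30, width = 1e5)   # 30 windows of 100 kb -> 3 bins
  r <- c(rep(1, 10), rep(2, 10), rep(4, 10))
  b <- bin_ratios(w, r, bin_size = 1e6)
  expect_equal(nrow(b$bins), 3)
  expect_equal(unname(b$ratio), c(1, 2, 4))
  # NAs are ignored within a bin
  r[1] <- NA
  expect_equal(unname(bin_ratios(w, r, bin_size = 1e6)$ratio[1]), 1)
  # matrix input keeps columns
  bm <- bin_ratios(w, cbind(r, r * 2), bin_size = 1e6)
  expect_equal(dim(bm$ratio), c(3, 2))
})
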