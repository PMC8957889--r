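test_that("minimum-SNP threshold reproduces the published formula arithmetic", {
  # chip-scale inputs: 45,424 SNPs, 2,096 individuals, mean het 0.27 -> 68
  expect_identical(min_snp_count(0.05, 45424, 2096, 0.27), 68L)
  # identity ratio ln(0.5)/ln(0.5)
  expect_identical(min_snp_count(0.5, 1, 1, 0.5), 1L)
  # direct evaluation oracle at other chip-scale inputs
  direct <- ceiling(log(0.05 / (39416 * 3770)) / log(1 - 0.29))
  expect_identical(min_snp_count(0.05, 39416, 3770, 0.29), as.integer(direct))
  expect_error(min_snp_count(0.05, 100, 10, 0), "mean_het")
})

test_that("generation dating inverts the segment-length formula", {
  expect_equal(generations_from_length(10), 5)
  expect_equal(generations_from_length(50), 1)
  expect_equal(generations_from_length(1), 50)
  expect_error(generations_from_length(0), "positive")
})

test_that("a fully heterozygous individual yields zero segments", {
  x <- fix_mat(matrix(1L, nrow = 1, ncol = 120))
  expect_equal(nrow(detect_roh(x, roh_params(min_snp_count = 10))), 0L)
})

test_that("201 homozygous markers at exact 50-kb spacing give one >10 Mb segment", {
  x <- fix_mat(matrix(0L, nrow = 1, ncol = 201), spacing_bp = 5e4)
  segs <- detect_roh(x, roh_params(min_snp_count = 63))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_bp, 5e4)
  expect_equal(segs$end_bp, 201 * 5e4)
  expect_equal(segs$n_snps, 201L)
  expect_equal(segs$length_bp, 1e7 + 1)
  expect_equal(segs$length_class, ">10Mb")
})

test_that("a planted tract with fully heterozygous flanks is recovered with exact bounds", {
  # 5 Mb homozygous tract (markers 51-150) between heterozygous flanks
  g <- c(rep(1L, 50), rep(0L, 100), rep(1L, 50))
  x <- fix_mat(matrix(g, nrow = 1), spacing_bp = 5e4)
  segs <- detect_roh(x, roh_params(min_snp_count = 40))
  expect_equal(nrow(segs), 1L)
  pos <- x$map$pos_bp
  # bounds within one inter-marker interval of the planted tract bounds
  expect_lte(abs(segs$start_bp - pos[51]), 5e4)
  expect_lte(abs(segs$end_bp - pos[150]), 5e4)
  expect_gte(segs$n_snps, 98L)
})

test_that("caller equals the exhaustive brute-force oracle on random fixtures", {
  set.seed(41)
  for (trial in 1:40) {
    m <- sample(60:200, 1)
    p_hom_run <- runif(1, 0.1, 0.6)
    g <- integer(m)
    # alternate homozygous stretches and noisy stretches to exercise runs
    j <- 1L
    while (j <= m) {
      L <- sample(5:60, 1)
      hi <- min(m, j + L - 1L)
      if (runif(1) < p_hom_run) g[j:hi] <- sample(c(0L, 2L), 1)
      else g[j:hi] <- rbinom(hi - j + 1L, 2, runif(1, 0.2, 0.8))
      j <- hi + 1L
    }
    g[runif(m) < 0.03] <- NA
    pos <- fix_positions(m, span_bp = m * 6e4, seed = 41000 + trial)
    params <- roh_params(min_length_bp = sample(c(5e5, 1e6), 1),
                         window_snps = sample(c(20L, 50L), 1),
                         window_max_het = sample(0:2, 1),
                         window_max_missing = sample(c(2L, 5L), 1),
                         min_snp_count = sample(c(5L, 15L, 30L), 1),
                         min_density_bp_per_snp = 1e5)
    x <- fix_mat(matrix(g, nrow = 1), pos = pos)
    mine <- detect_roh(x, params)
    ora <- oracle_roh(g, pos, params)
    expect_equal(nrow(mine), nrow(ora))
    if (nrow(ora)) {
      expect_equal(mine$start_bp, ora$start_bp)
      expect_equal(mine$end_bp, ora$end_bp)
      expect_equal(mine$n_snps, ora$n_snps)
    }
  }
})

test_that("raising thresholds never increases the number of called segments", {
  x <- fix_rand_mat(5, 300, seed = 42, miss = 0.02)
  x$calls[, 40:120] <- 0L              # shared homozygous block
  base <- roh_params(min_snp_count = 10)
  n0 <- nrow(detect_roh(x, base))
  for (par in list(roh_params(min_snp_count = 40),
                   roh_params(min_snp_count = 10, min_length_bp = 3e6))) {
    expect_lte(nrow(detect_roh(x, par)), n0)
  }
})

test_that("segments are invariant to sample order and chromosome relabeling", {
  x <- fix_rand_mat(6, 200, seed = 43)
  x$calls[2, 30:110] <- 0L
  par <- roh_params(min_snp_count = 20)
  a <- detect_roh(x, par)
  perm <- c(4, 2, 6, 1, 3, 5)
  b <- detect_roh(subset_geno(x, samples = perm), par)
  key <- function(d) d[order(d$sample_id, d$start_bp),
                       c("sample_id", "start_bp", "end_bp", "n_snps")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  y <- x
  y$map$chrom <- "9"
  cc <- detect_roh(y, par)
  expect_equal(cc$start_bp, a$start_bp)
  expect_equal(unique(cc$chrom), "9")
})

test_that("short chromosomes are scanned with one truncated window, not skipped", {
  calls <- matrix(0L, nrow = 1, ncol = 70)
  chrom <- c(rep("1", 30), rep("2", 40))   # chrom 1 shorter than the window
  x <- fix_mat(calls, chrom = chrom, spacing_bp = 6e4)
  expect_message(segs <- detect_roh(x, roh_params(window_snps = 50,
                                                  min_snp_count = 10)),
                 "truncated")
  expect_true("1" %in% segs$chrom)
})

test_that("gap splitting severs candidate runs at >1 Mb spacing", {
  pos <- c(seq(5e4, 30 * 5e4, by = 5e4),
           seq(30 * 5e4 + 2e6, 30 * 5e4 + 2e6 + 29 * 5e4, by = 5e4))
  x <- fix_mat(matrix(0L, nrow = 1, ncol = 60), pos = pos)
  segs <- detect_roh(x, roh_params(min_snp_count = 10))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_snps, c(30L, 30L))
})

test_that("length classes are left-closed and summaries add up", {
  expect_equal(roh_length_class(c(5e6, 9999999, 1e7, 1.2e6)),
               c("5-10Mb", "5-10Mb", ">10Mb", "1-5Mb"))
  segs <- data.frame(sample_id = "s1", chrom = "1",
                     start_bp = c(1, 1, 1), end_bp = c(2e6, 7e6, 12e6),
                     n_snps = c(40L, 140L, 240L),
                     length_bp = c(2e6, 7e6, 12e6),
                     length_class = c("1-5Mb", "5-10Mb", ">10Mb"))
  cls <- classify_segments(segs)
  expect_equal(cls$by_class$n, c(1L, 1L, 1L))
  expect_equal(cls$by_class$length_share, c(2, 7, 12) / 21)
  empty <- classify_segments(segs[0, ])
  expect_true(all(empty$by_class$n == 0L))
})
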