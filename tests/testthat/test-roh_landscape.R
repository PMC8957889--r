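test_that("occurrence counts individuals whose segments cover each marker", {
  x <- fix_rand_mat(4, 50, seed = 81)
  segs <- data.frame(sample_id = c("s1", "s2", "s3", "s4"), chrom = "1",
                     start_bp = c(1, 1, 1, 1), end_bp = rep(50 * 5e4, 4),
                     length_bp = NA, length_class = NA)
  tr <- roh_occurrence(segs, x)
  expect_true(all(tr$occurrence == 1))
  empty <- roh_occurrence(segs[0, ], x)
  expect_true(all(empty$occurrence == 0))
})

test_that("occurrence equals an exhaustive membership count on a 10-individual fixture", {
  set.seed(82)
  x <- fix_rand_mat(10, 80, seed = 82, spacing_bp = 1e5)
  segs <- do.call(rbind, lapply(1:10, function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    start <- sort(sample(seq(1e5, 70e5, by = 1e5), k))
    data.frame(sample_id = paste0("s", i), chrom = "1", start_bp = start,
               end_bp = start + sample(5:15, k, TRUE) * 1e5)
  }))
  # segments of one individual must not overlap: space them out
  segs <- segs[order(segs$sample_id, segs$start_bp), ]
  keep <- rep(TRUE, nrow(segs))
  for (r in seq_len(nrow(segs))[-1]) {
    if (segs$sample_id[r] == segs$sample_id[r - 1] && keep[r - 1] &&
        segs$start_bp[r] <= segs$end_bp[r - 1]) keep[r] <- FALSE
  }
  segs <- segs[keep, ]
  tr <- roh_occurrence(segs, x)
  for (j in seq_len(nrow(x$map))) {
    direct <- 0L
    for (i in 1:10) {
      s <- segs[segs$sample_id == paste0("s", i), , drop = FALSE]
      if (any(s$start_bp <= x$map$pos_bp[j] & s$end_bp >= x$map$pos_bp[j]))
        direct <- direct + 1L
    }
    expect_identical(tr$n_in_roh[j], direct)
  }
  # conservation: total marker-hits equal summed per-segment marker counts
  per_seg <- vapply(seq_len(nrow(segs)), function(r)
    sum(x$map$pos_bp >= segs$start_bp[r] & x$map$pos_bp <= segs$end_bp[r]), 0L)
  expect_equal(sum(tr$n_in_roh), sum(per_seg))
})

test_that("hotspot calling finds maximal runs above threshold", {
  tr <- data.frame(marker_id = paste0("m", 1:10), chrom = "1",
                   pos_bp = (1:10) * 1e5,
                   n_in_roh = 0L, occurrence = rep(0.85, 10))
  hs <- call_hotspots(tr, 0.80)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_snps, 10L)
  expect_equal(hs$start_bp, 1e5)
  expect_equal(hs$end_bp, 1e6)
  # alternating high/low: every high marker is its own region
  tr$occurrence <- rep(c(0.85, 0.5), 5)
  hs2 <- call_hotspots(tr, 0.80)
  expect_equal(nrow(hs2), 5L)
  expect_true(all(hs2$n_snps == 1L))
  # inclusive flag controls the boundary
  tr$occurrence <- rep(0.80, 10)
  expect_equal(nrow(call_hotspots(tr, 0.80, inclusive = TRUE)), 1L)
  expect_equal(nrow(call_hotspots(tr, 0.80, inclusive = FALSE)), 0L)
})

test_that("hotspots at a higher threshold are nested within lower-threshold ones", {
  set.seed(83)
  tr <- data.frame(marker_id = paste0("m", 1:200), chrom = "1",
                   pos_bp = (1:200) * 5e4, n_in_roh = 0L,
                   occurrence = pmin(1, pmax(0, runif(200))))
  hi <- call_hotspots(tr, 0.85)
  lo <- call_hotspots(tr, 0.80)
  for (r in seq_len(nrow(hi))) {
    inside <- any(lo$start_bp <= hi$start_bp[r] & lo$end_bp >= hi$end_bp[r])
    expect_true(inside)
  }
})

test_that("coldspots are zero-occurrence runs shared by all populations", {
  pos <- (1:30) * 45000
  mk <- function(occ) data.frame(marker_id = paste0("m", 1:30), chrom = "2",
                                 pos_bp = pos, n_in_roh = 0L, occurrence = occ)
  # both populations zero at markers 1-15, population 2 nonzero at 16
  occ1 <- c(rep(0, 15), rep(0.2, 15))
  occ2 <- c(rep(0, 16), rep(0.3, 14))
  cs <- call_coldspots(list(mk(occ1), mk(occ2)))
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$n_snps, 15L)
  expect_equal(cs$start_bp, pos[1])
  expect_equal(cs$end_bp, pos[15])
  # a population with ROH everywhere kills every coldspot
  expect_equal(nrow(call_coldspots(list(mk(rep(0, 30)), mk(rep(0.1, 30))))), 0L)
  # all-nonzero tracks produce an empty list
  expect_equal(nrow(call_coldspots(mk(rep(0.5, 30)))), 0L)
  expect_error(call_coldspots(list(mk(occ1)[1:10, ], mk(occ2))), "identical")
})

test_that("flanking expands, clips and merges intervals", {
  snp <- data.frame(chrom = "1", pos_bp = 1e5)
  fl <- flank_regions(snp, 5e4)
  expect_equal(fl$start_bp, 5e4)
  expect_equal(fl$end_bp, 15e4)
  # clipped at the chromosome start
  fl2 <- flank_regions(data.frame(chrom = "1", pos_bp = 2e4), 5e4)
  expect_equal(fl2$start_bp, 1)
  expect_equal(fl2$end_bp, 7e4)
  # two SNPs 60 kb apart merge into one 160-kb interval
  fl3 <- flank_regions(data.frame(chrom = "1", pos_bp = c(1e5, 1.6e5)), 5e4)
  expect_equal(nrow(fl3), 1L)
  expect_equal(fl3$end_bp - fl3$start_bp + 1, 160001)
  # zero flank on intervals is the identity (disjoint input)
  iv <- data.frame(chrom = "1", start_bp = c(10, 100), end_bp = c(20, 200))
  fl4 <- flank_regions(iv, 0)
  expect_equal(fl4$start_bp, iv$start_bp)
  expect_equal(fl4$end_bp, iv$end_bp)
  # chromosome-end clipping
  fl5 <- flank_regions(data.frame(chrom = "1", pos_bp = 9.99e6), 5e4,
                       chrom_lengths = c("1" = 1e7))
  expect_equal(fl5$end_bp, 1e7)
})

test_that("interval overlap equals the quadratic all-pairs scan", {
  # identical single intervals overlap fully; disjoint ones not at all
  a <- data.frame(chrom = "1", start_bp = 100, end_bp = 200)
  expect_equal(overlap_intervals(a, a, NULL)$overlap_bp, 101)
  b <- data.frame(chrom = "1", start_bp = 300, end_bp = 400)
  expect_equal(nrow(overlap_intervals(a, b, NULL)), 0L)
  # random 100x100 fixture
  set.seed(84)
  q <- data.frame(chrom = as.character(sample(1:3, 100, TRUE)),
                  start_bp = sample.int(5e5, 100))
  q$end_bp <- q$start_bp + sample.int(5e4, 100)
  s <- data.frame(chrom = as.character(sample(1:3, 100, TRUE)),
                  start_bp = sample.int(5e5, 100))
  s$end_bp <- s$start_bp + sample.int(5e4, 100)
  got <- overlap_intervals(q, s, NULL)
  want <- oracle_overlap(q, s)
  expect_equal(nrow(got), nrow(want))
  expect_equal(sort(got$overlap_bp), sort(want$overlap_bp))
})

test_that("the QTL length pre-filter drops over-long subjects", {
  q <- data.frame(chrom = "1", start_bp = 1, end_bp = 5e6)
  s <- data.frame(chrom = "1", start_bp = c(1, 100), end_bp = c(2e6, 500),
                  name = c("long", "short"))
  got <- overlap_intervals(q, s, max_subject_length_bp = 1e6)
  expect_equal(got$s_name, "short")
})
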