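test_that("per-marker heterozygosity statistics follow their definitions", {
  x <- fix_mat(cbind(rep(1L, 10), rep(0L, 10), c(rep(2L, 5), rep(0L, 5))))
  hs <- het_stats(x)
  expect_equal(hs$per_marker$ho, c(1, 0, 0))
  expect_equal(hs$per_marker$he, c(0.5, 0, 0.5))
  expect_equal(hs$per_marker$maf, c(0.5, 0, 0.5))
})

test_that("mean observed heterozygosity matches 2pq under Hardy-Weinberg", {
  x <- fix_rand_mat(1000, 300, seed = 91, p = rep(0.3, 300))
  hs <- het_stats(x)
  expect_equal(unname(hs$means["ho"]), 0.42, tolerance = 0.025)
  expect_equal(unname(hs$means["he"]), 0.42, tolerance = 0.025)
})

test_that("windowed pi matches the combinatorial definition", {
  # one SNP at p = 0.5 with 4 chromosomes: per-site pi = 2/3
  x <- fix_mat(matrix(c(0L, 2L), ncol = 1), pos = 100)
  w <- windowed_pi(x, 5e5)
  expect_equal(w$pi_sum, 2 / 3)
  expect_equal(w$pi, (2 / 3) / 5e5)
  # monomorphic window
  y <- fix_mat(matrix(0L, nrow = 4, ncol = 5))
  expect_true(all(windowed_pi(y, 5e5)$pi == 0))
})

test_that("windowed pi equals the exhaustive pairwise oracle", {
  x <- fix_rand_mat(8, 20, seed = 92, miss = 0.1, spacing_bp = 2e4)
  w <- windowed_pi(x, 5e5)
  expect_equal(nrow(w), 1L)
  want <- sum(vapply(1:20, function(j) oracle_pi_site(x$calls[, j]), 0))
  expect_equal(w$pi_sum, want, tolerance = 1e-12)
})

test_that("pi conservation: windowed sums add to the chromosome total", {
  x <- fix_rand_mat(10, 120, seed = 93, spacing_bp = 3e4)  # complete data
  w <- windowed_pi(x, 5e5)
  ac_total <- sum(vapply(1:120, function(j) oracle_pi_site(x$calls[, j]), 0))
  expect_equal(sum(w$pi_sum), ac_total, tolerance = 1e-10)
})

test_that("Tajima's D has the expected sign for extreme frequency spectra", {
  # five intermediate-frequency sites among 10 chromosomes -> D > 0
  calls_mid <- matrix(rep(c(0L, 0L, 1L, 2L, 2L), 5), nrow = 5)
  x <- fix_mat(calls_mid)
  d_mid <- windowed_tajima_d(x, 5e5)$tajima_d
  expect_gt(d_mid, 0)
  # all singletons -> D < 0
  calls_sing <- matrix(0L, nrow = 5, ncol = 5)
  for (j in 1:5) calls_sing[j, j] <- 1L
  d_sing <- windowed_tajima_d(fix_mat(calls_sing), 5e5)$tajima_d
  expect_lt(d_sing, 0)
})

test_that("Tajima's D equals its dual implementation on random windows", {
  set.seed(94)
  for (k in 1:60) {
    n <- sample(4:15, 1)
    m <- sample(5:30, 1)
    x <- fix_rand_mat(n, m, seed = 9400 + k, miss = ifelse(k %% 3 == 0, 0.1, 0),
                      spacing_bp = 1e4)
    d <- windowed_tajima_d(x, 5e5)$tajima_d
    want <- oracle_tajima_d(x$calls)
    if (is.na(want)) expect_true(is.na(d))
    else expect_equal(d, want, tolerance = 1e-10)
  }
})

test_that("pi, D and FST are invariant to allele label swaps", {
  x <- fix_rand_mat(10, 40, seed = 95, miss = 0.05, spacing_bp = 1e4)
  y <- x
  flip <- c(3, 7, 21)
  y$calls[, flip] <- 2L - y$calls[, flip]
  expect_equal(windowed_pi(x, 5e5)$pi, windowed_pi(y, 5e5)$pi, tolerance = 1e-12)
  expect_equal(windowed_tajima_d(x, 5e5)$tajima_d,
               windowed_tajima_d(y, 5e5)$tajima_d, tolerance = 1e-12)
  x2 <- fix_rand_mat(10, 40, seed = 96, spacing_bp = 1e4)
  y2 <- x2
  y2$calls[, flip] <- 2L - y2$calls[, flip]
  f1 <- windowed_fst(x, x2, 5e5)
  f2 <- windowed_fst(y, y2, 5e5)
  expect_equal(f1$fst_weighted, f2$fst_weighted, tolerance = 1e-12)
})

test_that("Weir-Cockerham components match the nested-ANOVA oracle per site", {
  set.seed(97)
  for (k in 1:200) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    g2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    mine <- wc_fst_components(
      n = c(n1, n2),
      p = c(mean(g1) / 2, mean(g2) / 2),
      h = c(mean(g1 == 1), mean(g2 == 1)))
    want <- oracle_wc_abc(list(g1, g2))
    expect_equal(unname(mine), unname(want), tolerance = 1e-10)
  }
})

test_that("FST is one at a fixed difference and near zero for split halves", {
  # fixed difference: site FST = 1
  m1 <- fix_mat(matrix(2L, nrow = 50, ncol = 2))
  m2 <- fix_mat(matrix(0L, nrow = 50, ncol = 2))
  m1$calls[, 2] <- rbinom(50, 2, 0.5); m2$calls[, 2] <- rbinom(50, 2, 0.5)
  f <- windowed_fst(m1, m2, 5e5)
  expect_equal(f$per_site$a[1] / (f$per_site$a[1] + f$per_site$b[1] +
                                    f$per_site$c[1]), 1, tolerance = 1e-10)
  # random halves of one population: no differentiation
  x <- fix_rand_mat(200, 2000, seed = 98, spacing_bp = 2e4)
  set.seed(99)
  half <- sample(200, 100)
  f0 <- windowed_fst(subset_geno(x, samples = half),
                     subset_geno(x, samples = setdiff(1:200, half)), 5e5)
  expect_lt(abs(f0$fst_weighted), 0.005)
})

test_that("Ne follows the LD formula on analytic and hand fixtures", {
  # analytic: c = 0.01 Morgan, mean r2_adj = 0.1, alpha = 2.2 -> Ne = 195
  # engineered via a bin whose midpoint is 1 Mb = 0.01 Morgan
  expect_equal((1 / (4 * 0.01)) * (1 / 0.1 - 2.2), 195)
  # hand fixture: 2 markers, 6 samples; r2 is the squared dosage correlation
  g1 <- c(0L, 1L, 2L, 1L, 0L, 2L)
  g2 <- c(1L, 0L, 2L, 2L, 0L, 1L)   # r2 = 0.25 by hand
  x <- fix_mat(cbind(g1, g2), pos = c(1e5, 9e5))
  ne <- ne_ld(x, bins_bp = c(5e5, 11e5), maf_min = 0)
  expect_equal(ne$mean_r2, 0.25, tolerance = 1e-12)
  expect_equal(ne$mean_r2_adj, 0.25 - 1 / 6, tolerance = 1e-12)
  expect_equal(ne$c_morgan, 8e5 * 1e-8)
  expect_equal(ne$t_generations, 1 / (2 * 8e5 * 1e-8))
  expect_equal(ne$ne, (1 / (4 * 0.008)) * (12 - 2.2), tolerance = 1e-9)
  # boundary: 1/r2_adj at or below alpha would give Ne <= 0 -> reported NA
  g3 <- c(0L, 2L, 2L, 1L, 1L, 2L)   # r2 = 0.675 with g1: r2_adj too large
  y <- fix_mat(cbind(g1, g3), pos = c(1e5, 9e5))
  ne2 <- ne_ld(y, bins_bp = c(5e5, 11e5), maf_min = 0)
  expect_true(is.na(ne2$ne))
})
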