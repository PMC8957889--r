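# Windowed and genome-wide diversity/differentiation statistics and the
# LD-based effective population size.
#
# Windows are non-overlapping tiles of `window_bp` starting at bp 1 of each
# chromosome (step = size, the behaviour of the standard windowed VCF tools);
# `step_bp` is exposed for overlapping windows.

# allele2 counts / non-missing chromosome counts per marker (or subset)
.allele_counts <- function(calls) {
  nm <- !is.na(calls)
  n_chr <- 2 * colSums(nm)
  c2 <- colSums(calls, na.rm = TRUE)
  list(n_chr = n_chr, c2 = c2, c1 = n_chr - c2)
}

#' Per-marker and genome-mean heterozygosity
#'
#' `Ho` is the heterozygous fraction among non-missing calls, `He = 2p(1-p)`
#' with `p` the sample allele frequency. Genome means are unweighted averages
#' over markers; all-missing markers are excluded with a message.
#'
#' @param mat a [geno_matrix()].
#' @return list with `per_marker` (data.frame marker_id, chrom, pos_bp, ho,
#'   he, maf, n) and `means` (named vector ho, he, maf).
#' @export
het_stats <- function(mat) {
  calls <- mat$calls
  nm <- !is.na(calls)
  n <- colSums(nm)
  ho <- colSums(calls == 1L, na.rm = TRUE) / n
  p <- colSums(calls, na.rm = TRUE) / (2 * n)
  he <- 2 * p * (1 - p)
  maf <- pmin(p, 1 - p)
  if (any(n == 0)) message("het_stats: ", sum(n == 0),
                           " all-missing marker(s) excluded from means")
  per <- data.frame(marker_id = mat$map$marker_id, chrom = mat$map$chrom,
                    pos_bp = mat$map$pos_bp, ho = ho, he = he, maf = maf,
                    n = n, stringsAsFactors = FALSE)
  ok <- n > 0
  list(per_marker = per,
       means = c(ho = mean(ho[ok]), he = mean(he[ok]), maf = mean(maf[ok])))
}

# window assignment: tile index per marker for one chromosome
.window_index <- function(pos, window_bp) (pos - 1) %/% window_bp

# per-site pairwise diversity: c1*c2 / C(n,2); 0 where n < 2
.site_pi <- function(c1, c2, n_chr) {
  denom <- n_chr * (n_chr - 1) / 2
  ifelse(denom > 0, c1 * c2 / denom, 0)
}

#' Windowed nucleotide diversity
#'
#' Per window, the sum of per-site pairwise diversity over member SNPs divided
#' by the window span in bp. Per-site diversity at allele counts `(c1, c2)`
#' over `n` non-missing chromosomes is `c1 c2 / C(n, 2)`. Windows without
#' SNPs get pi = 0 (monomorphic assumption) and are flagged.
#'
#' @param mat a [geno_matrix()].
#' @param window_bp window size in bp (default 500 kb tiles).
#' @return data.frame `chrom`, `win_start_bp`, `win_end_bp`, `n_snps`,
#'   `pi_sum` (summed per-site diversity) and `pi` (per bp).
#' @export
windowed_pi <- function(mat, window_bp = 5e5) {
  ac <- .allele_counts(mat$calls)
  sp <- .site_pi(ac$c1, ac$c2, ac$n_chr)
  out <- list()
  for (ch in unique(mat$map$chrom)) {
    jj <- which(mat$map$chrom == ch)
    wi <- .window_index(mat$map$pos_bp[jj], window_bp)
    for (w in seq(0, max(wi))) {
      sel <- jj[wi == w]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, win_start_bp = w * window_bp + 1,
        win_end_bp = (w + 1) * window_bp, n_snps = length(sel),
        pi_sum = sum(sp[sel]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$pi <- res$pi_sum / window_bp
  rownames(res) <- NULL
  res
}

# Tajima's D constants for n sampled chromosomes
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))` with the classical
#' constants computed from the window's chromosome count `n`. With missing
#' data, `n` is taken conservatively as the minimum non-missing chromosome
#' count among the window's segregating sites (the constants assume a single
#' `n`); per-site diversity still uses each site's own counts. Windows with no
#' segregating sites or `n < 4` return `NA`.
#'
#' @param mat a [geno_matrix()].
#' @param window_bp window size in bp.
#' @return data.frame `chrom`, `win_start_bp`, `win_end_bp`, `n_snps`, `s`
#'   (segregating sites), `n_chr`, `tajima_d`.
#' @export
windowed_tajima_d <- function(mat, window_bp = 5e5) {
  ac <- .allele_counts(mat$calls)
  sp <- .site_pi(ac$c1, ac$c2, ac$n_chr)
  seg <- ac$c1 > 0 & ac$c2 > 0
  out <- list()
  for (ch in unique(mat$map$chrom)) {
    jj <- which(mat$map$chrom == ch)
    wi <- .window_index(mat$map$pos_bp[jj], window_bp)
    for (w in seq(0, max(wi))) {
      sel <- jj[wi == w]
      ss <- sel[seg[sel]]
      S <- length(ss)
      n_min <- if (S) min(ac$n_chr[ss]) else NA_integer_
      d <- NA_real_
      if (S >= 1 && !is.na(n_min) && n_min >= 4) {
        k <- .tajima_constants(n_min)
        vr <- k$e1 * S + k$e2 * S * (S - 1)
        if (vr > 0) d <- (sum(sp[ss]) - S / k$a1) / sqrt(vr)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, win_start_bp = w * window_bp + 1,
        win_end_bp = (w + 1) * window_bp, n_snps = length(sel), s = S,
        n_chr = if (is.na(n_min)) NA_integer_ else as.integer(n_min),
        tajima_d = d, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weir-Cockerham variance components per site
#'
#' The 1984 diploid estimator's among-population (`a`), among-individual
#' (`b`) and within-individual (`c`) components for a biallelic site, from the
#' per-population sample sizes `n_i`, allele frequencies `p_i` and observed
#' heterozygote proportions `h_i`. `FST = a / (a + b + c)`.
#'
#' @param n vector of per-population diploid sample sizes (length >= 2).
#' @param p vector of per-population allele frequencies.
#' @param h vector of per-population observed heterozygote proportions.
#' @return named numeric vector with components `a`, `b`, `c`.
#' @export
wc_fst_components <- function(n, p, h) {
  r <- length(n)
  stopifnot(r >= 2, length(p) == r, length(h) == r)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Windowed and genome-wide Weir-Cockerham FST
#'
#' Per-site variance components are summed as a ratio of averages:
#' `FST = sum(a) / sum(a + b + c)` over member sites, per window and
#' genome-wide (the weighted estimate). The unweighted mean of window values
#' is reported alongside. Sites where any population has fewer than two
#' non-missing samples, or where `a + b + c = 0`, are excluded.
#'
#' @param mat1,mat2 [geno_matrix()] objects for the two populations on
#'   identical marker maps.
#' @param window_bp window size in bp.
#' @return list with `windows` (data.frame chrom, win_start_bp, win_end_bp,
#'   n_snps, fst), `fst_weighted`, `fst_mean` and `per_site` (a, b, c).
#' @export
windowed_fst <- function(mat1, mat2, window_bp = 5e5) {
  if (!identical(mat1$map$marker_id, mat2$map$marker_id) ||
      !identical(mat1$map$pos_bp, mat2$map$pos_bp))
    stop("the two populations must share an identical marker map")
  comp <- function(calls) {
    nm <- !is.na(calls)
    n <- colSums(nm)
    list(n = n, p = colSums(calls, na.rm = TRUE) / (2 * n),
         h = colSums(calls == 1L, na.rm = TRUE) / n)
  }
  s1 <- comp(mat1$calls); s2 <- comp(mat2$calls)
  m <- ncol(mat1$calls)
  a <- b <- cc <- rep(NA_real_, m)
  usable <- s1$n >= 2 & s2$n >= 2
  for (j in which(usable)) {
    v <- wc_fst_components(c(s1$n[j], s2$n[j]), c(s1$p[j], s2$p[j]),
                           c(s1$h[j], s2$h[j]))
    a[j] <- v["a"]; b[j] <- v["b"]; cc[j] <- v["c"]
  }
  tot <- a + b + cc
  use <- usable & !is.na(tot) & tot != 0
  out <- list()
  for (ch in unique(mat1$map$chrom)) {
    jj <- which(mat1$map$chrom == ch)
    wi <- .window_index(mat1$map$pos_bp[jj], window_bp)
    for (w in seq(0, max(wi))) {
      sel <- jj[wi == w]
      sel <- sel[use[sel]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, win_start_bp = w * window_bp + 1,
        win_end_bp = (w + 1) * window_bp, n_snps = length(sel),
        fst = if (length(sel)) sum(a[sel]) / sum(tot[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  list(windows = windows,
       fst_weighted = sum(a[use]) / sum(tot[use]),
       fst_mean = mean(windows$fst, na.rm = TRUE),
       per_site = data.frame(marker_id = mat1$map$marker_id, a = a, b = b,
                             c = cc, stringsAsFactors = FALSE))
}

#' LD-based effective population size
#'
#' Pairs of markers on the same chromosome are binned by physical distance;
#' for each bin the mean squared genotype (dosage) correlation `r2` is
#' adjusted for sampling (`r2_adj = r2 - 1/n_ind`, the unphased-data
#' correction), the bin midpoint is converted to Morgans at 1 Mb = 1 cM
#' (`c = mid_bp * 1e-8`), and
#' `Ne = (4 f(c))^-1 (1 / r2_adj - alpha)` with `f(c) = c`, dated
#' `t = 1 / (2c)` generations ago. Bins where `r2_adj <= 0` or where
#' `1/r2_adj <= alpha` give no estimate (`NA`).
#'
#' @param mat a [geno_matrix()].
#' @param bins_bp increasing vector of bin edges in bp; pairs beyond the last
#'   edge are ignored. Default edges 50 kb to 4 Mb.
#' @param alpha_const the constant correcting for mutation (2.2 by
#'   convention; 2 ignores mutation, 1 for phased data).
#' @param maf_min minimum MAF for markers entering pairs.
#' @return data.frame per bin: `dist_lo_bp`, `dist_hi_bp`, `mid_bp`,
#'   `c_morgan`, `t_generations`, `n_pairs`, `mean_r2`, `mean_r2_adj`, `ne`.
#' @export
ne_ld <- function(mat, bins_bp = c(5e4, 1e5, 2.5e5, 5e5, 1e6, 2e6, 4e6),
                  alpha_const = 2.2, maf_min = 0.05) {
  stopifnot(length(bins_bp) >= 2, all(diff(bins_bp) > 0))
  n_ind <- nrow(mat$calls)
  p <- colMeans(mat$calls, na.rm = TRUE) / 2
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf_min
  max_d <- bins_bp[length(bins_bp)]
  nb <- length(bins_bp) - 1L
  r2_sum <- numeric(nb); n_pair <- integer(nb)
  for (ch in unique(mat$map$chrom)) {
    jj <- which(mat$map$chrom == ch & keep)
    pos <- mat$map$pos_bp[jj]
    for (ii in seq_along(jj)) {
      kk <- ii + which(pos[seq_along(jj) > ii] - pos[ii] <= max_d)
      if (!length(kk)) next
      d <- pos[kk] - pos[ii]
      bin <- findInterval(d, bins_bp, rightmost.closed = TRUE)
      ok <- bin >= 1 & bin <= nb
      for (q in which(ok)) {
        r <- suppressWarnings(
          stats::cor(mat$calls[, jj[ii]], mat$calls[, jj[kk[q]]],
                     use = "complete.obs"))
        if (is.na(r)) next
        r2_sum[bin[q]] <- r2_sum[bin[q]] + r^2
        n_pair[bin[q]] <- n_pair[bin[q]] + 1L
      }
    }
  }
  mean_r2 <- ifelse(n_pair > 0, r2_sum / n_pair, NA_real_)
  r2_adj <- mean_r2 - 1 / n_ind
  mid <- (bins_bp[-length(bins_bp)] + bins_bp[-1]) / 2
  cm <- mid * 1e-8                       # Morgans at 1 Mb = 1 cM
  ne <- ifelse(!is.na(r2_adj) & r2_adj > 0 & 1 / r2_adj > alpha_const,
               (1 / (4 * cm)) * (1 / r2_adj - alpha_const), NA_real_)
  data.frame(dist_lo_bp = bins_bp[-length(bins_bp)], dist_hi_bp = bins_bp[-1],
             mid_bp = mid, c_morgan = cm, t_generations = 1 / (2 * cm),
             n_pairs = n_pair, mean_r2 = mean_r2, mean_r2_adj = r2_adj,
             ne = ne, stringsAsFactors = FALSE)
}
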