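# Independent brute-force oracles. Each recomputes a statistic from first
# principles by a different route than the package implementation (explicit
# enumeration, raw sums of squares, closed forms), so agreement is evidence,
# not tautology.

# --- exact HWE by direct enumeration with lchoose ---------------------------
# P(het = h | allele counts) = multinomial(n; hom1, h, hom2) * 2^h / C(2n, nA)
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  if (min(nA, nB) == 0) return(1)
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  lp <- vapply(hs, function(h) {
    a <- (nA - h) / 2
    lchoose(n, a) + lchoose(n - a, h) + h * log(2) - lchoose(2 * n, nA)
  }, 0)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[hs == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# --- per-site pi by exhaustive pairwise allele comparison -------------------
oracle_pi_site <- function(g) {
  g <- g[!is.na(g)]
  al <- unlist(lapply(g, function(x) c(as.integer(x >= 1), as.integer(x == 2))))
  n <- length(al)
  if (n < 2) return(0)
  diff_sum <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diff_sum <- diff_sum + as.integer(al[i] != al[j])
  diff_sum / (n * (n - 1) / 2)
}

# --- Tajima's D, dual implementation over a window's genotype columns -------
# pi_sum from the exhaustive pairwise oracle; constants re-derived inline.
oracle_tajima_d <- function(calls) {
  nm_counts <- 2 * colSums(!is.na(calls))
  p2 <- colSums(calls, na.rm = TRUE) / nm_counts
  seg <- !is.na(p2) & p2 > 0 & p2 < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n <- min(nm_counts[seg])
  if (n < 4) return(NA_real_)
  pi_sum <- sum(vapply(which(seg), function(j) oracle_pi_site(calls[, j]), 0))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  (pi_sum - S / a1) / sqrt(v)
}

# --- Weir-Cockerham a, b, c from raw nested-ANOVA sums of squares -----------
# Alleles are 0/1 observations, copies nested in individuals nested in
# populations; a, b, c are the method-of-moments variance components.
oracle_wc_abc <- function(geno_list) {
  r <- length(geno_list)
  geno_list <- lapply(geno_list, function(g) g[!is.na(g)])
  n <- vapply(geno_list, length, 0L)
  p <- vapply(geno_list, function(g) mean(g) / 2, 0)
  N <- 2 * sum(n)
  pbar <- sum(2 * n * p) / N
  ssp <- sum(2 * n * (p - pbar)^2)
  msp <- ssp / (r - 1)
  ssi <- 0; ssg <- 0
  for (k in seq_len(r)) {
    g <- geno_list[[k]]
    ssi <- ssi + sum(2 * (g / 2 - p[k])^2)
    ssg <- ssg + sum(ifelse(g == 1L, 0.5, 0))   # within-individual SS
  }
  msi <- ssi / (sum(n) - r)
  msg <- ssg / sum(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  c(a = (msp - msi) / (2 * nc), b = (msi - msg) / 2, c = msg)
}

# --- OLS beta/se in closed form ---------------------------------------------
oracle_ols <- function(y, X) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - ncol(X))
  list(beta = as.vector(beta), se = sqrt(diag(XtX_inv) * sigma2))
}

# --- ROH caller by plain loops ----------------------------------------------
# Re-derives window verdicts, per-marker eligibility, maximal runs, gap
# splits and filters with explicit loops and no shared code.
oracle_roh <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snps
  is_het <- function(j) !is.na(g[j]) && g[j] == 1L
  is_mis <- function(j) is.na(g[j])
  if (m < w) {
    win_starts <- 1L
    win_ends <- m
  } else {
    win_starts <- 1:(m - w + 1L)
    win_ends <- win_starts + w - 1L
  }
  qual <- logical(length(win_starts))
  for (q in seq_along(win_starts)) {
    nh <- 0L; nmis <- 0L
    for (j in win_starts[q]:win_ends[q]) {
      if (is_het(j)) nh <- nh + 1L
      if (is_mis(j)) nmis <- nmis + 1L
    }
    qual[q] <- nh <= params$window_max_het && nmis <= params$window_max_missing
  }
  elig <- logical(m)
  for (j in 1:m) {
    contain <- which(win_starts <= j & win_ends >= j)
    elig[j] <- sum(qual[contain]) / length(contain) >= params$window_hit_fraction
  }
  segs <- list()
  j <- 1L
  while (j <= m) {
    if (!elig[j]) { j <- j + 1L; next }
    k <- j
    while (k < m && elig[k + 1L]) k <- k + 1L
    # gap-split the run [j, k]
    piece_start <- j
    for (q in j:k) {
      at_gap <- q < k && (pos[q + 1L] - pos[q]) > params$max_gap_bp
      if (at_gap || q == k) {
        piece_end <- q
        len <- pos[piece_end] - pos[piece_start] + 1
        nsnp <- piece_end - piece_start + 1L
        if (len >= params$min_length_bp && nsnp >= params$min_snp_count &&
            len / nsnp <= params$min_density_bp_per_snp) {
          segs[[length(segs) + 1L]] <- data.frame(
            start_bp = pos[piece_start], end_bp = pos[piece_end],
            n_snps = nsnp, length_bp = len)
        }
        piece_start <- q + 1L
      }
    }
    j <- k + 1L
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric()))
  do.call(rbind, segs)
}

# --- interval overlap by quadratic all-pairs scan ---------------------------
oracle_overlap <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] != subject$chrom[j]) next
    lo <- max(query$start_bp[i], subject$start_bp[j])
    hi <- min(query$end_bp[i], subject$end_bp[j])
    if (hi >= lo)
      out[[length(out) + 1L]] <- data.frame(qi = i, sj = j, overlap_bp = hi - lo + 1)
  }
  if (!length(out)) return(data.frame(qi = integer(), sj = integer(),
                                      overlap_bp = numeric()))
  do.call(rbind, out)
}
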