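# Sliding-window ROH detection.
#
# Semantics, per individual and chromosome:
#  (a) a window of `window_snps` consecutive markers slides one marker at a
#      time; it qualifies if it holds <= window_max_het heterozygous and
#      <= window_max_missing missing calls;
#  (b) a marker is ROH-eligible if >= window_hit_fraction of the windows
#      containing it qualify;
#  (c) maximal runs of consecutive eligible markers are candidate segments;
#  (d) a candidate is split wherever adjacent marker spacing exceeds
#      max_gap_bp;
#  (e) candidates failing the minimum length, minimum SNP count or density
#      criteria are discarded. Segment bounds are the first/last member
#      marker positions, length = end - start + 1 bp.

#' ROH caller parameters
#'
#' Defaults are the standard SNP-chip settings: minimum segment length 1 Mb,
#' 50-SNP scanning window tolerating one heterozygous and five missing calls,
#' maximum 1 Mb gap between consecutive segment markers, minimum density of
#' one SNP per 100 kb. `window_hit_fraction` governs how window verdicts
#' become per-marker calls; 0.05 is the scanning-tool convention and is
#' exposed because it is the one semantic the criteria above do not pin down.
#'
#' @param min_length_bp minimum segment length (bp).
#' @param window_snps scanning window size in markers.
#' @param window_max_het maximum heterozygous calls per qualifying window.
#' @param window_max_missing maximum missing calls per qualifying window.
#' @param max_gap_bp maximum gap between adjacent markers inside a segment.
#' @param min_density_bp_per_snp maximum bp per SNP inside a segment.
#' @param min_snp_count minimum markers per segment; compute from
#'   [min_snp_count()] for false-positive control.
#' @param window_hit_fraction minimum fraction of qualifying windows for a
#'   marker to be ROH-eligible.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, window_snps = 50,
                       window_max_het = 1, window_max_missing = 5,
                       max_gap_bp = 1e6, min_density_bp_per_snp = 1e5,
                       min_snp_count = 1, window_hit_fraction = 0.05) {
  stopifnot(min_length_bp > 0, window_snps > 0, window_max_het >= 0,
            window_max_missing >= 0, max_gap_bp > 0,
            min_density_bp_per_snp > 0, min_snp_count >= 1,
            window_hit_fraction > 0, window_hit_fraction <= 1,
            window_max_het < window_snps)
  structure(list(min_length_bp = min_length_bp, window_snps = window_snps,
                 window_max_het = window_max_het,
                 window_max_missing = window_max_missing,
                 max_gap_bp = max_gap_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 min_snp_count = min_snp_count,
                 window_hit_fraction = window_hit_fraction),
            class = "roh_params")
}

#' Minimum consecutive-SNP threshold for false-positive control
#'
#' `l = ln(alpha / (n_snps * n_inds)) / ln(1 - mean_het)`, rounded up. `alpha`
#' is the tolerated number of false-positive ROH genome-wide across all
#' individuals; `mean_het` is the observed proportion of heterozygous calls
#' across all genotypes.
#'
#' @param alpha false-positive rate in (0, 1).
#' @param n_snps markers per individual.
#' @param n_inds number of individuals.
#' @param mean_het mean heterozygosity in (0, 1).
#' @return integer threshold (ceiling of the formula value).
#' @export
min_snp_count <- function(alpha, n_snps, n_inds, mean_het) {
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1, n_inds >= 1)
  if (mean_het <= 0)
    stop("mean_het must be > 0: the threshold formula divides by ln(1 - mean_het)")
  if (mean_het >= 1) stop("mean_het must be < 1")
  as.integer(ceiling(log(alpha / (n_snps * n_inds)) / log(1 - mean_het)))
}

#' Observed mean heterozygosity of a genotype matrix
#'
#' The proportion of heterozygous calls among all non-missing genotypes,
#' the `mean_het` input of [min_snp_count()].
#'
#' @param mat a [geno_matrix()].
#' @return scalar in `[0, 1]`.
#' @export
mean_heterozygosity <- function(mat) {
  mean(mat$calls == 1L, na.rm = TRUE)
}

#' Detect runs of homozygosity
#'
#' Scanning-window ROH detection per individual (see the criteria at the top
#' of this help page's implementation). Chromosomes with fewer markers than
#' the window size are scanned with a single truncated window covering all
#' their markers (reported via a message).
#'
#' @param mat a [geno_matrix()] with sorted markers.
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`, `length_class`.
#' @export
detect_roh <- function(mat, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  chroms <- unique(mat$map$chrom)
  out <- list()
  warned_short <- FALSE
  for (ch in chroms) {
    jj <- which(mat$map$chrom == ch)
    pos <- mat$map$pos_bp[jj]
    m <- length(jj)
    w <- params$window_snps
    if (m < w && !warned_short) {
      message("detect_roh: chromosome ", ch, " has ", m, " < ", w,
              " markers; scanned with a single truncated window")
      warned_short <- TRUE
    }
    for (i in seq_len(nrow(mat$calls))) {
      g <- mat$calls[i, jj]
      elig <- roh_eligible(g, w, params$window_max_het,
                           params$window_max_missing,
                           params$window_hit_fraction)
      segs <- eligible_runs_to_segments(elig, pos, params)
      if (!is.null(segs)) {
        segs$sample_id <- mat$samples$sample_id[i]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      length_class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps",
                 "length_bp", "length_class")]
  rownames(res) <- NULL
  res
}

# Per-marker ROH eligibility from window verdicts, via cumulative sums.
roh_eligible <- function(g, w, max_het, max_miss, hit_fraction) {
  m <- length(g)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  if (m < w) {
    ok <- sum(het) <= max_het && sum(mis) <= max_miss
    return(rep(ok, m))
  }
  nwin <- m - w + 1L
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  win_het <- ch[(w + 1L):(m + 1L)] - ch[1L:nwin]
  win_mis <- cm[(w + 1L):(m + 1L)] - cm[1L:nwin]
  qual <- win_het <= max_het & win_mis <= max_miss
  cq <- c(0L, cumsum(as.integer(qual)))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nwin)
  n_contain <- hi - lo + 1L
  n_qual <- cq[hi + 1L] - cq[lo]
  n_qual / n_contain >= hit_fraction
}

# Maximal eligible runs -> gap split -> length/count/density filters.
eligible_runs_to_segments <- function(elig, pos, params) {
  if (!any(elig)) return(NULL)
  r <- rle(elig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    # split where adjacent spacing exceeds the gap limit
    cut <- if (b > a) which(diff(pos[a:b]) > params$max_gap_bp) else integer()
    piece_start <- c(a, a + cut)
    piece_end <- c(a + cut - 1L, b)
    for (p in seq_along(piece_start)) {
      s <- piece_start[p]; e <- piece_end[p]
      len <- pos[e] - pos[s] + 1
      nsnp <- e - s + 1L
      if (len < params$min_length_bp) next
      if (nsnp < params$min_snp_count) next
      if (len / nsnp > params$min_density_bp_per_snp) next
      segs[[length(segs) + 1L]] <- data.frame(
        start_bp = pos[s], end_bp = pos[e], n_snps = nsnp, length_bp = len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(NULL)
  res <- do.call(rbind, segs)
  res$length_class <- roh_length_class(res$length_bp)
  res
}

#' ROH length class
#'
#' Left-closed classes on length in bp: `[1, 5)` Mb, `[5, 10)` Mb and
#' `[10, Inf)` Mb (1 Mb = 1e6 bp), so a segment of exactly 5,000,000 bp falls
#' in the 5-10 Mb class.
#'
#' @param length_bp numeric vector of segment lengths.
#' @return character vector of class labels.
#' @export
roh_length_class <- function(length_bp) {
  cut(length_bp / 1e6, breaks = c(0, 5, 10, Inf), right = FALSE,
      labels = c("1-5Mb", "5-10Mb", ">10Mb")) |> as.character()
}

#' Summarise ROH segments
#'
#' Counts and length sums per length class, per chromosome and per individual,
#' plus per-chromosome ROH coverage when chromosome spans are supplied.
#'
#' @param segments data.frame from [detect_roh()].
#' @param chrom_lengths optional named vector of chromosome spans in bp.
#' @return list of data.frames `by_class`, `by_chrom`, `by_individual`.
#' @export
classify_segments <- function(segments, chrom_lengths = NULL) {
  classes <- c("1-5Mb", "5-10Mb", ">10Mb")
  if (nrow(segments) == 0) {
    return(list(
      by_class = data.frame(length_class = classes, n = 0L, total_bp = 0,
                            length_share = 0, stringsAsFactors = FALSE),
      by_chrom = data.frame(chrom = character(), n = integer(),
                            total_bp = numeric(), coverage = numeric()),
      by_individual = data.frame(sample_id = character(), n = integer(),
                                 total_bp = numeric())))
  }
  cls <- factor(segments$length_class, levels = classes)
  by_class <- data.frame(
    length_class = classes,
    n = as.integer(table(cls)),
    total_bp = as.numeric(tapply(segments$length_bp, cls, sum, default = 0)),
    stringsAsFactors = FALSE)
  by_class$length_share <- by_class$total_bp / sum(by_class$total_bp)

  by_chrom <- stats::aggregate(list(n = rep(1L, nrow(segments)),
                             total_bp = segments$length_bp),
                        by = list(chrom = segments$chrom), FUN = sum)
  by_chrom$coverage <- if (!is.null(chrom_lengths))
    by_chrom$total_bp / as.numeric(chrom_lengths[by_chrom$chrom])
  else NA_real_

  by_ind <- stats::aggregate(list(n = rep(1L, nrow(segments)),
                           total_bp = segments$length_bp),
                      by = list(sample_id = segments$sample_id), FUN = sum)
  list(by_class = by_class, by_chrom = by_chrom, by_individual = by_ind)
}

#' Date ROH origin in generations
#'
#' The expected length of an autozygous segment reaching back `g` generations
#' is `L = 100 / (2 g)` cM; with 1 cM ~ 1 Mb this inverts to
#' `g = 100 / (2 L_Mb)`, so a 10 Mb segment points to a common ancestor about
#' five generations back.
#'
#' @param length_mb segment length in Mb (> 0).
#' @return generations to the common ancestor.
#' @export
generations_from_length <- function(length_mb) {
  if (any(length_mb <= 0)) stop("segment length must be positive")
  100 / (2 * length_mb)
}
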