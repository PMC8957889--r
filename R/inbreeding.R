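# Genomic inbreeding coefficients: F_ROH (total and by length class) from
# called segments, and the excess-homozygosity F_HOM from genotypes.

#' ROH-based inbreeding coefficient
#'
#' `F_ROH = L_ROH / L_auto`: the summed segment length of an individual
#' divided by the autosomal genome span, computed in total and within each
#' length class (which decompose the total exactly). The default `l_auto_bp`
#' of 2.45 Gb is the SNP-covered span of the 18 pig autosomes.
#'
#' @param segments data.frame from [detect_roh()].
#' @param l_auto_bp autosomal genome span in bp (> 0).
#' @param sample_ids optional character vector of individuals to report
#'   (individuals without segments get zeros); defaults to the individuals
#'   present in `segments`.
#' @return data.frame with columns `sample_id`, `l_roh_bp`, `f_roh_total`,
#'   `f_roh_1_5`, `f_roh_5_10`, `f_roh_gt10`.
#' @export
f_roh <- function(segments, l_auto_bp = 2.45e9, sample_ids = NULL) {
  stopifnot(l_auto_bp > 0)
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  sum_by <- function(seg) {
    v <- tapply(seg$length_bp, factor(seg$sample_id, levels = sample_ids),
                sum, default = 0)
    as.numeric(v)
  }
  tot <- if (nrow(segments)) sum_by(segments) else numeric(length(sample_ids))
  cls <- function(lab) {
    s <- segments[segments$length_class == lab, , drop = FALSE]
    if (nrow(s)) sum_by(s) else numeric(length(sample_ids))
  }
  data.frame(sample_id = sample_ids,
             l_roh_bp = tot,
             f_roh_total = tot / l_auto_bp,
             f_roh_1_5 = cls("1-5Mb") / l_auto_bp,
             f_roh_5_10 = cls("5-10Mb") / l_auto_bp,
             f_roh_gt10 = cls(">10Mb") / l_auto_bp,
             stringsAsFactors = FALSE)
}

#' Excess-homozygosity inbreeding coefficient
#'
#' Method-of-moments estimator `F = (O_hom - E_hom) / (N_nm - E_hom)` per
#' individual, where `N_nm` is the individual's non-missing marker count,
#' `O_hom` its observed homozygous count and `E_hom` the summed expected
#' homozygosity `1 - 2 p (1-p) * 2n/(2n-1)` over those markers, with `p` the
#' sample allele frequency (focal individual included) and `n` the number of
#' non-missing samples at the marker. The `2n/(2n-1)` factor is the standard
#' small-sample correction. Monomorphic markers contribute 1 to `E_hom`.
#'
#' @param mat a [geno_matrix()] with at least 2 samples.
#' @return data.frame `sample_id`, `o_hom`, `e_hom`, `n_nm`, `f_hom`
#'   (`NA` where `N_nm = E_hom`).
#' @export
f_hom <- function(mat) {
  calls <- mat$calls
  if (nrow(calls) < 2) stop("f_hom needs >= 2 samples to estimate frequencies")
  nm <- !is.na(calls)
  n_site <- colSums(nm)
  p <- colSums(calls, na.rm = TRUE) / (2 * n_site)       # allele2 frequency
  e_site <- 1 - 2 * p * (1 - p) * (2 * n_site / (2 * n_site - 1))
  e_site[n_site == 0] <- 0
  o_hom <- rowSums(calls != 1L, na.rm = TRUE)
  e_hom <- as.numeric(nm %*% e_site)
  n_nm <- rowSums(nm)
  f <- ifelse(abs(n_nm - e_hom) < .Machine$double.eps * n_nm * 4,
              NA_real_, (o_hom - e_hom) / (n_nm - e_hom))
  data.frame(sample_id = mat$samples$sample_id, o_hom = o_hom, e_hom = e_hom,
             n_nm = n_nm, f_hom = f, stringsAsFactors = FALSE)
}

#' Combined per-individual inbreeding table
#'
#' @param mat a [geno_matrix()].
#' @param segments ROH segments from [detect_roh()].
#' @param l_auto_bp autosomal span in bp.
#' @return data.frame joining [f_roh()] and [f_hom()] plus sample metadata.
#' @export
inbreeding_coefficients <- function(mat, segments, l_auto_bp = 2.45e9) {
  fr <- f_roh(segments, l_auto_bp, sample_ids = mat$samples$sample_id)
  fh <- f_hom(mat)
  out <- merge(mat$samples, merge(fr, fh[, c("sample_id", "f_hom")],
                                  by = "sample_id"), by = "sample_id", sort = FALSE)
  out[match(mat$samples$sample_id, out$sample_id), , drop = FALSE]
}

#' Pearson correlations among inbreeding measures
#'
#' Pairwise-complete Pearson correlations, with two-sided p-values from the
#' t transform, among `f_hom`, `f_roh_total` and the per-class F_ROH columns.
#' Zero-variance columns yield `NA` for their pairs.
#'
#' @param records data.frame from [inbreeding_coefficients()] (or any frame
#'   holding the columns to correlate).
#' @param columns columns to correlate.
#' @return list with matrices `r` and `p`.
#' @export
correlate_inbreeding <- function(records,
                                 columns = c("f_hom", "f_roh_total",
                                             "f_roh_1_5", "f_roh_5_10",
                                             "f_roh_gt10")) {
  columns <- intersect(columns, names(records))
  x <- as.matrix(records[, columns, drop = FALSE])
  if (nrow(x) < 3) stop("need >= 3 records to correlate")
  k <- length(columns)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(x[, c(i, j)])
    xi <- x[ok, i]; xj <- x[ok, j]
    if (sum(ok) < 3 || stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(xi, xj, method = "pearson")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Compare an inbreeding measure between groups
#'
#' Group means plus a two-sided Wilcoxon rank-sum test (distribution-free;
#' the test used is named in the output). With more than two groups, all
#' pairwise contrasts are reported.
#'
#' @param records data.frame holding the value and grouping columns.
#' @param group_col name of the grouping column (e.g. `"sex"`,
#'   `"population"`).
#' @param value_col name of the value column (e.g. `"f_roh_total"`).
#' @return list with `means` (data.frame group, n, mean) and `tests`
#'   (data.frame group1, group2, mean_diff, p, test).
#' @export
group_compare <- function(records, group_col, value_col = "f_roh_total") {
  g <- records[[group_col]]
  v <- records[[value_col]]
  ok <- !is.na(g) & !is.na(v)
  g <- g[ok]; v <- v[ok]
  groups <- sort(unique(g))
  if (length(groups) < 2) stop("need >= 2 groups in ", group_col)
  if (any(table(g) < 2)) stop("each group needs >= 2 members")
  means <- data.frame(group = groups,
                      n = as.integer(table(factor(g, levels = groups))),
                      mean = as.numeric(tapply(v, factor(g, levels = groups), mean)),
                      stringsAsFactors = FALSE)
  pairs <- utils::combn(groups, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    wt <- suppressWarnings(stats::wilcox.test(v[g == a], v[g == b]))
    data.frame(group1 = a, group2 = b,
               mean_diff = mean(v[g == a]) - mean(v[g == b]),
               p = wt$p.value, test = "wilcoxon_rank_sum",
               stringsAsFactors = FALSE)
  }))
  list(means = means, tests = tests)
}
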