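# Quality control: call-rate filters, exact Hardy-Weinberg test, optional MAF
# filter. Filter order is fixed and reported so removal counts are
# reproducible: autosomes -> SNP call rate -> individual call rate -> HWE ->
# MAF. Individual call rates are recomputed on the markers that survive the
# SNP call-rate step.

#' QC parameter set
#'
#' @param min_call_rate_snp minimum per-marker call rate (default 0.90).
#' @param min_call_rate_ind minimum per-individual call rate (default 0.90).
#' @param hwe_min_p markers with exact HWE p below this are removed
#'   (default 1e-6).
#' @param maf_min minimum minor allele frequency, or `NULL` to skip the MAF
#'   filter (the default: low-MAF pruning discards homozygous regions that the
#'   ROH caller needs; diversity analyses typically use 0.01).
#' @param autosomes_only drop unmapped markers and sex/mito chromosomes.
#' @param autosome_labels explicit whitelist of autosome labels, or `NULL` to
#'   drop the conventional non-autosomal labels (0, X, Y, XY, MT, M).
#' @param hwe_per_population if `TRUE` (default) and more than one population
#'   label is present, the HWE test runs within each population and a marker is
#'   removed if it fails in any of them; otherwise samples are pooled.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate_snp = 0.90, min_call_rate_ind = 0.90,
                      hwe_min_p = 1e-6, maf_min = NULL, autosomes_only = TRUE,
                      autosome_labels = NULL, hwe_per_population = TRUE) {
  stopifnot(min_call_rate_snp >= 0, min_call_rate_snp <= 1,
            min_call_rate_ind >= 0, min_call_rate_ind <= 1,
            hwe_min_p > 0, hwe_min_p < 1)
  structure(list(min_call_rate_snp = min_call_rate_snp,
                 min_call_rate_ind = min_call_rate_ind,
                 hwe_min_p = hwe_min_p, maf_min = maf_min,
                 autosomes_only = autosomes_only,
                 autosome_labels = autosome_labels,
                 hwe_per_population = hwe_per_population),
            class = "qc_params")
}

#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test conditional on the observed allele counts: the p-value
#' is the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (no mid-p
#' adjustment). Monomorphic markers return 1.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (non-negative, not all zero).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("all genotype counts are zero")
  n1 <- 2 * n_hom1 + n_het          # copies of allele 1
  n2 <- 2 * n_hom2 + n_het
  rare <- min(n1, n2)
  if (rare == 0) return(1)
  # heterozygote count shares parity with the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each het count given allele counts
  logp <- vapply(hets, function(h) {
    h1 <- (n1 - h) / 2; h2 <- (n2 - h) / 2
    lgamma(n + 1) - lgamma(h1 + 1) - lgamma(h + 1) - lgamma(h2 + 1) +
      h * log(2) + lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Apply quality-control filters
#'
#' Filters are applied in a fixed, reported order: (1) non-autosomal/unmapped
#' markers, (2) marker call rate, (3) individual call rate (recomputed on the
#' surviving markers), (4) exact HWE, (5) optional MAF (computed on surviving
#' samples). Re-application is idempotent.
#'
#' @param mat a [geno_matrix()].
#' @param params a [qc_params()].
#' @return list with `matrix` (filtered) and `report` (data.frame of removal
#'   counts per step, plus attributes recording the parameters and HWE mode).
#' @export
apply_qc <- function(mat, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  steps <- character(); removed <- integer(); kind <- character()
  drop_markers <- function(keep, label) {
    steps <<- c(steps, label); removed <<- c(removed, sum(!keep))
    kind <<- c(kind, "markers")
    if (any(!keep)) mat <<- subset_geno(mat, markers = which(keep))
  }

  if (params$autosomes_only) {
    if (!is.null(params$autosome_labels)) {
      keep <- mat$map$chrom %in% as.character(params$autosome_labels)
    } else {
      keep <- !(toupper(mat$map$chrom) %in% c("0", "X", "Y", "XY", "MT", "M")) &
        mat$map$pos_bp >= 1
    }
    drop_markers(keep, "non_autosomal")
  } else {
    steps <- c(steps, "non_autosomal"); removed <- c(removed, 0L)
    kind <- c(kind, "markers")
  }

  cr_snp <- colMeans(!is.na(mat$calls))
  drop_markers(cr_snp >= params$min_call_rate_snp, "snp_call_rate")

  cr_ind <- rowMeans(!is.na(mat$calls))
  keep_ind <- cr_ind >= params$min_call_rate_ind
  steps <- c(steps, "ind_call_rate"); removed <- c(removed, sum(!keep_ind))
  kind <- c(kind, "individuals")
  if (any(!keep_ind)) mat <- subset_geno(mat, samples = which(keep_ind))
  if (nrow(mat$calls) == 0) stop("QC removed every individual")

  pops <- unique(mat$samples$population)
  use_pops <- params$hwe_per_population && length(pops) > 1
  hwe_one <- function(calls) {
    apply(calls, 2, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(1)
      hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    })
  }
  if (use_pops) {
    pmin_over_pops <- rep(1, ncol(mat$calls))
    for (pp in pops) {
      rows <- mat$samples$population == pp
      pmin_over_pops <- pmin(pmin_over_pops, hwe_one(mat$calls[rows, , drop = FALSE]))
    }
    hwe_p <- pmin_over_pops
  } else {
    hwe_p <- hwe_one(mat$calls)
  }
  drop_markers(hwe_p >= params$hwe_min_p, "hwe")

  if (!is.null(params$maf_min)) {
    p2 <- colMeans(mat$calls, na.rm = TRUE) / 2
    maf <- pmin(p2, 1 - p2)
    maf[is.nan(maf)] <- 0
    drop_markers(maf >= params$maf_min, "maf")
  } else {
    steps <- c(steps, "maf"); removed <- c(removed, 0L); kind <- c(kind, "markers")
  }
  if (ncol(mat$calls) == 0) stop("QC removed every marker")

  report <- data.frame(step = steps, removed = removed, unit = kind,
                       stringsAsFactors = FALSE)
  attr(report, "params") <- unclass(params)
  attr(report, "hwe_mode") <- if (use_pops) "per_population" else "pooled"
  attr(report, "n_samples") <- nrow(mat$calls)
  attr(report, "n_markers") <- ncol(mat$calls)
  list(matrix = mat, report = report)
}
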