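# Allele/derived-allele frequencies and the single-SNP additive linear model
# with covariates.

#' Allele and derived-allele frequencies
#'
#' Per marker (optionally per population), the frequency of allele2 is the
#' allele2 dosage sum over twice the non-missing sample count. When an
#' ancestral-allele designation is supplied, the derived-allele frequency
#' (DAF) is reported for the non-ancestral allele.
#'
#' @param mat a [geno_matrix()].
#' @param by_population stratify by the `population` sample column.
#' @param ancestral optional named character vector mapping `marker_id` to
#'   `"allele1"` or `"allele2"` (the ancestral allele); markers without a
#'   designation get `NA` DAF.
#' @return data.frame `marker_id`, `population`, `n`, `freq_allele2`,
#'   `derived_allele`, `daf`.
#' @export
allele_freq <- function(mat, by_population = TRUE, ancestral = NULL) {
  groups <- if (by_population) split(seq_len(nrow(mat$calls)), mat$samples$population)
            else list(all = seq_len(nrow(mat$calls)))
  out <- lapply(names(groups), function(gname) {
    calls <- mat$calls[groups[[gname]], , drop = FALSE]
    n <- colSums(!is.na(calls))
    freq <- colSums(calls, na.rm = TRUE) / (2 * n)
    data.frame(marker_id = mat$map$marker_id, population = gname, n = n,
               freq_allele2 = freq, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  anc <- if (is.null(ancestral)) rep(NA_character_, nrow(res))
         else unname(ancestral[res$marker_id])
  res$derived_allele <- ifelse(is.na(anc), NA_character_,
                               ifelse(anc == "allele1", "allele2", "allele1"))
  res$daf <- ifelse(is.na(anc), NA_real_,
                    ifelse(anc == "allele1", res$freq_allele2, 1 - res$freq_allele2))
  res
}

#' Single-SNP additive linear association
#'
#' Ordinary least squares of the trait on an additive genotype code (0/1/2
#' copies of the counted allele) plus covariates:
#' `y = mu + beta * code + covariates + e`. Batch is dummy-encoded by default;
#' `numeric_covariates = TRUE` treats every covariate as a numeric column (the
#' behaviour of the common association tool, for reproducing its output).
#' Samples missing the genotype, trait or any covariate are dropped.
#'
#' @param mat a [geno_matrix()].
#' @param phenotypes data.frame with `sample_id`, `trait` and covariate
#'   columns.
#' @param marker_id the tested marker.
#' @param covariates covariate column names (default `age`, `batch`).
#' @param numeric_covariates treat all covariates as numeric instead of
#'   dummy-encoding character/factor ones.
#' @param count_allele `"allele2"` (default) or `"allele1"`: the allele whose
#'   copies the genotype code counts.
#' @return list of class `assoc_result`: `marker_id`, `n_used`, `beta`, `se`,
#'   `t_stat`, `p_two_sided`, `genotype_means` (named trait means for codes
#'   0/1/2) and the fitted `model`.
#' @export
linear_assoc <- function(mat, phenotypes, marker_id,
                         covariates = c("age", "batch"),
                         numeric_covariates = FALSE,
                         count_allele = c("allele2", "allele1")) {
  count_allele <- match.arg(count_allele)
  j <- match(marker_id, mat$map$marker_id)
  if (is.na(j)) stop("marker ", marker_id, " not in map")
  covariates <- covariates[covariates %in% names(phenotypes)]
  idx <- match(phenotypes$sample_id, mat$samples$sample_id)
  if (all(is.na(idx))) stop("no phenotype sample_id matches the genotypes")
  code <- mat$calls[idx, j]
  if (count_allele == "allele1") code <- 2L - code

  df <- data.frame(trait = phenotypes$trait, geno = as.numeric(code))
  for (cv in covariates) {
    v <- phenotypes[[cv]]
    if (!numeric_covariates && (is.character(v) || is.factor(v)))
      v <- factor(v)
    else v <- as.numeric(v)
    df[[cv]] <- v
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p_cols <- 2L + length(covariates)
  if (nrow(df) < p_cols + 2) stop("too few complete cases (", nrow(df), ")")
  if (stats::var(df$geno) == 0)
    stop("design is rank-deficient: genotype at ", marker_id, " is constant")

  fml <- stats::reformulate(c("geno", covariates), response = "trait")
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank-deficient: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients["geno", ]
  gm <- tapply(df$trait, factor(df$geno, levels = 0:2), mean)
  structure(list(marker_id = marker_id, n_used = nrow(df),
                 beta = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
                 t_stat = unname(sm["t value"]),
                 p_two_sided = unname(sm["Pr(>|t|)"]),
                 genotype_means = gm, model = fit),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("additive association at ", x$marker_id, " (n = ", x$n_used, ")\n",
      sprintf("beta = %.6g  se = %.6g  t = %.4g  p = %.4g\n",
              x$beta, x$se, x$t_stat, x$p_two_sided), sep = "")
  invisible(x)
}
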