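# In-code fixtures: small genotype matrices with controlled layouts.

# Build a geno_matrix from a calls matrix with evenly spaced markers.
fix_mat <- function(calls, spacing_bp = 5e4, chrom = NULL, pos = NULL,
                    pops = NULL, sex = NULL, alleles = c("A", "C")) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) {
    pos <- unlist(lapply(split(seq_len(m), factor(chrom, levels = unique(chrom))),
                         function(jj) seq_along(jj) * spacing_bp))
  }
  map <- data.frame(marker_id = paste0("m", seq_len(m)), chrom = chrom,
                    pos_bp = pos, allele1 = alleles[1], allele2 = alleles[2],
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(nrow(calls))),
                        population = if (is.null(pops)) "pop1" else pops,
                        sex = if (is.null(sex)) NA_character_ else sex,
                        stringsAsFactors = FALSE)
  geno_matrix(calls, map, samples)
}

# Random HWE genotypes at given allele frequencies, optional missingness.
fix_rand_mat <- function(n, m, seed, miss = 0, p = NULL, spacing_bp = 5e4) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.05, 0.95)
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
  if (miss > 0) calls[runif(n * m) < miss] <- NA_integer_
  fix_mat(calls, spacing_bp = spacing_bp)
}

# Irregular marker positions (sorted unique uniform draws) on one chromosome.
fix_positions <- function(m, span_bp, seed) {
  set.seed(seed)
  sort(sample.int(span_bp, m))
}
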