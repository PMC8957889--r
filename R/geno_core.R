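# Core genotype container and text-format readers/writers.
#
# Internal conventions used throughout the package:
#   * genotype codes count copies of allele2: 0 = hom allele1, 1 = het,
#     2 = hom allele2, NA = missing. Orientation to minor/derived alleles is
#     resolved downstream (popgen / assoc), never in storage.
#   * all coordinates are 1-based inclusive base pairs; the BED half-open
#     0-based convention is converted only at the file boundary.
#   * markers are globally sorted by (chrom, pos_bp); every read enforces this
#     and downstream code may assume it.

#' Construct a genotype matrix
#'
#' Bundles diploid genotype calls with their marker map and sample metadata.
#' Markers are sorted by (chromosome, position) and calls are permuted
#' consistently; all downstream functions assume this order.
#'
#' @param calls integer matrix, samples in rows, markers in columns; entries
#'   0 (hom allele1), 1 (het), 2 (hom allele2) or `NA` (missing).
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_bp` and
#'   optionally `allele1`, `allele2`. Positions are 1-based bp and must be
#'   strictly increasing within a chromosome after sorting.
#' @param samples data.frame with column `sample_id` (unique) and optionally
#'   `population` and `sex` (`"male"`, `"female"` or `NA`).
#' @return an object of class `geno_matrix`: a list with elements `calls`,
#'   `map`, `samples`.
#' @export
geno_matrix <- function(calls, map, samples = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos_bp") %in% names(map)))
  if (is.null(map$allele1)) map$allele1 <- "A"
  if (is.null(map$allele2)) map$allele2 <- "B"
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = paste0("ind", seq_len(nrow(calls))),
                          population = "pop1", sex = NA_character_,
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(samples))
  samples$sample_id <- as.character(samples$sample_id)
  if (is.null(samples$population)) samples$population <- "pop1"
  if (is.null(samples$sex)) samples$sex <- NA_character_

  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " markers")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker_id in map")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(map$pos_bp < 1))
    stop("marker positions must be >= 1")

  ord <- order_chrom(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  rownames(map) <- NULL
  dimnames(calls) <- list(samples$sample_id, map$marker_id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "geno_matrix")
}

# Order chromosome labels numerically when possible (1..18), mixed labels
# after numeric ones, then by position.
order_chrom <- function(chrom, pos_bp) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom, pos_bp)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  pops <- table(x$samples$population)
  cat("populations:", paste(names(pops), pops, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / markers
#' @param x a `geno_matrix`
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname n_samples
#' @export
n_markers <- function(x) ncol(x$calls)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`
#' @param samples logical/integer/character index into samples (optional).
#' @param markers logical/integer/character index into markers (optional).
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(x, samples = NULL, markers = NULL) {
  calls <- x$calls; map <- x$map; smp <- x$samples
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, smp$sample_id)
    calls <- calls[samples, , drop = FALSE]
    smp <- smp[samples, , drop = FALSE]
    rownames(smp) <- NULL
  }
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker_id)
    calls <- calls[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    rownames(map) <- NULL
  }
  geno_matrix(calls, map, smp)
}

# ---------------------------------------------------------------------------
# PED/MAP

#' Read PLINK text PED/MAP files
#'
#' The PED file carries six leading columns (FID, IID, father, mother, sex,
#' phenotype) followed by two allele columns per marker; `"0"` denotes a
#' missing allele and half-missing genotypes are treated as missing. Because
#' PED does not record allele orientation, `allele1`/`allele2` are assigned
#' alphabetically per marker; genotype codes count copies of `allele2`.
#'
#' @param ped_file path to the PED file.
#' @param map_file path to the MAP file (3 or 4 columns: chrom, marker_id,
#'   [cM,] pos_bp).
#' @return a [geno_matrix()]; `population` is taken from the family ID column
#'   and `sex` from PED column 5 (1 = male, 2 = female).
#' @export
read_ped_map <- function(ped_file, map_file) {
  map_raw <- utils::read.table(map_file, header = FALSE,
                               colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(map_raw) == 3) {
    map <- data.frame(chrom = map_raw[[1]], marker_id = map_raw[[2]],
                      pos_bp = as.numeric(map_raw[[3]]), stringsAsFactors = FALSE)
  } else if (ncol(map_raw) >= 4) {
    map <- data.frame(chrom = map_raw[[1]], marker_id = map_raw[[2]],
                      pos_bp = as.numeric(map_raw[[4]]), stringsAsFactors = FALSE)
  } else stop("MAP file must have 3 or 4 columns")
  m <- nrow(map)

  lines <- readLines(ped_file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nf <- lengths(fields)
  if (any(nf != want)) {
    i <- which(nf != want)[1]
    stop("PED format error at line ", i, ": expected ", want,
         " fields (6 + 2 x ", m, " markers), found ", nf[i])
  }
  ped <- do.call(rbind, fields)
  samples <- data.frame(
    sample_id = ped[, 2],
    population = ped[, 1],
    sex = c("male", "female")[match(ped[, 5], c("1", "2"))],
    stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in PED: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = m)
  alle1 <- alle2 <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(obs) > 2)
      stop("marker ", map$marker_id[j], " has >2 alleles in PED: ",
           paste(obs, collapse = ","))
    alle1[j] <- if (length(obs) >= 1) obs[1] else "A"
    alle2[j] <- if (length(obs) == 2) obs[2] else NA_character_
    miss <- a1[, j] == "0" | a2[, j] == "0"
    code <- (a1[, j] == alle2[j]) + (a2[, j] == alle2[j])
    code[is.na(code)] <- 0L   # monomorphic marker: all calls are hom allele1
    code[miss] <- NA_integer_
    calls[, j] <- as.integer(code)
  }
  map$allele1 <- alle1
  map$allele2 <- alle2
  geno_matrix(calls, map, samples)
}

#' Write PLINK text PED/MAP files
#'
#' @param x a `geno_matrix`.
#' @param ped_file,map_file output paths.
#' @return invisibly, `x`.
#' @export
write_ped_map <- function(x, ped_file, map_file) {
  map <- x$map
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0, format(map$pos_bp, scientific = FALSE, trim = TRUE)),
    map_file, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  a1 <- map$allele1
  a2 <- ifelse(is.na(map$allele2), map$allele1, map$allele2)
  sex_code <- match(x$samples$sex, c("male", "female"))
  sex_code[is.na(sex_code)] <- 0L
  con <- file(ped_file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$calls))) {
    g <- x$calls[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2, a1))
    second <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
    writeLines(paste(c(x$samples$population[i], x$samples$sample_id[i],
                       "0", "0", sex_code[i], "-9",
                       as.vector(rbind(first, second))), collapse = " "), con)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# VCF

#' Read a VCF into a genotype matrix
#'
#' Only biallelic SNP records are kept; REF maps to `allele1` and ALT to
#' `allele2`. GT values `0/0`, `0/1` (or `1/0`), `1/1`, `./.` (phased
#' equivalents included) map to codes 0, 1, 2, `NA`.
#'
#' @param vcf_file path to a VCF 4.x file.
#' @param strict if `TRUE`, error on multiallelic/non-SNP records instead of
#'   skipping them with a message.
#' @return a [geno_matrix()] (population and sex metadata unset).
#' @export
read_vcf <- function(vcf_file, strict = FALSE) {
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!is_snp)) {
    if (strict) stop(sum(!is_snp), " non-SNP or multiallelic record(s) in ", vcf_file)
    message("read_vcf: skipped ", sum(!is_snp), " non-SNP/multiallelic record(s)")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", vcf_file)
  if (!"GT" %in% rownames(v@gt) && !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF has no GT format field")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  code <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  for (j in seq_len(nrow(gt))) code[, j] <- lut[gt[j, ]]
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos_bp = as.numeric(fix[, "POS"]),
                    allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), population = "pop1",
                        sex = NA_character_, stringsAsFactors = FALSE)
  geno_matrix(code, map, samples)
}

#' Write a genotype matrix as VCF 4.2 text
#'
#' @param x a `geno_matrix`.
#' @param vcf_file output path.
#' @return invisibly, `x`.
#' @export
write_vcf <- function(x, vcf_file) {
  map <- x$map
  con <- file(vcf_file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rohscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples$sample_id), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(x$calls))) {
    g <- x$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    writeLines(paste(c(map$chrom[j],
                       format(map$pos_bp[j], scientific = FALSE, trim = TRUE),
                       map$marker_id[j], map$allele1[j],
                       ifelse(is.na(map$allele2[j]), ".", map$allele2[j]),
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Intervals (BED at the file boundary, 1-based inclusive internally)

#' Read a BED-like interval file
#'
#' BED is 0-based half-open on disk; the returned data.frame uses the
#' package's 1-based inclusive convention (`start_bp = BED start + 1`).
#' Unsorted input is sorted with a message.
#'
#' @param bed_file path to a 3+-column BED file (chrom, start, end[, name]).
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
read_intervals <- function(bed_file) {
  if (file.size(bed_file) == 0)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  raw <- utils::read.table(bed_file, header = FALSE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  out <- data.frame(chrom = raw[[1]],
                    start_bp = as.numeric(raw[[2]]) + 1,
                    end_bp = as.numeric(raw[[3]]),
                    name = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start_bp > out$end_bp)) stop("interval with start > end in ", bed_file)
  ord <- order_chrom(out$chrom, out$start_bp)
  if (is.unsorted(ord)) {
    message("read_intervals: input not sorted; sorting by (chrom, start)")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write intervals to a BED file
#'
#' Converts from the internal 1-based inclusive convention to BED's 0-based
#' half-open convention. An empty interval list produces an empty file.
#'
#' @param x data.frame with columns `chrom`, `start_bp`, `end_bp` and
#'   optionally `name`.
#' @param bed_file output path.
#' @return invisibly, `x`.
#' @export
write_intervals <- function(x, bed_file) {
  if (nrow(x) == 0) {
    file.create(bed_file)
    return(invisible(x))
  }
  cols <- data.frame(x$chrom,
                     format(x$start_bp - 1, scientific = FALSE, trim = TRUE),
                     format(x$end_bp, scientific = FALSE, trim = TRUE))
  if (!is.null(x$name) && any(!is.na(x$name))) cols$name <- x$name
  utils::write.table(cols, bed_file, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read a phenotype table
#'
#' Tab-separated with header `sample_id trait age batch` (age/batch optional).
#'
#' @param file path.
#' @return data.frame with one row per sample.
#' @export
read_phenotypes <- function(file) {
  ph <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "trait") %in% names(ph)))
    stop("phenotype table must have columns 'sample_id' and 'trait'")
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample_id in phenotype table")
  ph
}
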