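# Seeded synthetic genotype/phenotype generator with known ground truth:
# Balding-Nichols population divergence, planted autozygous tracts, and an
# additive single-SNP phenotype model with age/batch covariates.

#' Simulation configuration
#'
#' Defaults emulate the study design this package was built around: two
#' diverged commercial pig lines genotyped on a ~50K SNP chip. 18 autosomes of
#' 136 Mb (2.45 Gb total) with 2,500 markers each give a mean inter-marker
#' spacing of ~54 kb; between-population divergence follows the
#' Balding-Nichols model at F = 0.093; the planted-tract plan places one
#' autozygous tract per length class (plus one short sub-threshold tract) in
#' every individual; no-call and genotyping-error rates are typical
#' SNP-array values.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population.
#' @param n_chrom number of autosomes.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param n_snps_per_chrom markers per chromosome.
#' @param fst_target Balding-Nichols F in `[0, 1)`; 0 means panmixia.
#' @param roh_plan data.frame describing tracts to plant; see
#'   [plant_autozygosity()]. `NULL` for none.
#' @param miss_rate per-call missingness probability.
#' @param err_rate per-call hom-to-het genotyping error probability.
#' @param seed mandatory integer seed (Mersenne-Twister).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, n_per_pop = 100, n_chrom = 18,
                       chrom_length_bp = 136e6, n_snps_per_chrom = 2500,
                       fst_target = 0.093, roh_plan = default_roh_plan(),
                       miss_rate = 0.01, err_rate = 0.002, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_chrom >= 1,
            n_snps_per_chrom >= 2, chrom_length_bp > n_snps_per_chrom)
  if (fst_target < 0 || fst_target >= 1) stop("fst_target must be in [0, 1)")
  if (miss_rate < 0 || miss_rate >= 1 || err_rate < 0 || err_rate >= 1)
    stop("miss_rate and err_rate must be in [0, 1)")
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_chrom = n_chrom,
                 chrom_length_bp = chrom_length_bp,
                 n_snps_per_chrom = n_snps_per_chrom, fst_target = fst_target,
                 roh_plan = roh_plan, miss_rate = miss_rate,
                 err_rate = err_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted-tract plan
#'
#' One tract per individual in each ROH length class (3, 7.5 and 15 Mb for
#' the 1-5, 5-10 and >10 Mb classes) plus one short 1.5 Mb tract near the
#' caller's resolution limit.
#'
#' @return data.frame with columns `length_bp`, `count`, `freq`, `chrom`,
#'   `start_bp` (the last three `NA` = random placement per individual).
#' @export
default_roh_plan <- function() {
  data.frame(length_bp = c(1.5e6, 3e6, 7.5e6, 15e6), count = 1L,
             freq = NA_real_, chrom = NA_character_, start_bp = NA_real_,
             stringsAsFactors = FALSE)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniform on `[0.05, 0.95]` per
#' marker; population frequencies follow
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` when `F > 0` (equal to ancestral when
#' `F = 0`); genotypes are Hardy-Weinberg draws within population. Marker
#' positions are uniform without replacement, sorted. Output is deterministic
#' given `config$seed`. Missingness/error are not applied here; they are part
#' of [plant_autozygosity()], so genotypes from this function are clean.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (a [geno_matrix()]) and `truth` (a list
#'   with `ancestral_freqs`, `pop_allele_freqs` (markers x pops, frequency of
#'   allele2), `rng` and the resolved config).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  m_total <- config$n_chrom * config$n_snps_per_chrom
  n_total <- config$n_pops * config$n_per_pop

  chrom <- rep(as.character(seq_len(config$n_chrom)), each = config$n_snps_per_chrom)
  pos <- unlist(lapply(seq_len(config$n_chrom), function(ch)
    sort(sample.int(config$chrom_length_bp, config$n_snps_per_chrom))))
  map <- data.frame(marker_id = sprintf("snp_%s_%05d", chrom,
                                        rep(seq_len(config$n_snps_per_chrom), config$n_chrom)),
                    chrom = chrom, pos_bp = pos,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)

  p_anc <- stats::runif(m_total, 0.05, 0.95)
  f <- config$fst_target
  pop_freq <- matrix(NA_real_, nrow = m_total, ncol = config$n_pops)
  for (k in seq_len(config$n_pops)) {
    if (f > 0) {
      pk <- stats::rbeta(m_total, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      pop_freq[, k] <- pmin(pmax(pk, 1e-6), 1 - 1e-6)
    } else {
      pop_freq[, k] <- p_anc
    }
  }

  calls <- matrix(NA_integer_, nrow = n_total, ncol = m_total)
  for (k in seq_len(config$n_pops)) {
    rows <- (k - 1L) * config$n_per_pop + seq_len(config$n_per_pop)
    calls[rows, ] <- matrix(
      stats::rbinom(config$n_per_pop * m_total, 2L,
                    rep(pop_freq[, k], each = config$n_per_pop)),
      nrow = config$n_per_pop)
  }
  samples <- data.frame(
    sample_id = sprintf("pop%d_%04d", rep(seq_len(config$n_pops), each = config$n_per_pop),
                        rep(seq_len(config$n_per_pop), config$n_pops)),
    population = sprintf("pop%d", rep(seq_len(config$n_pops), each = config$n_per_pop)),
    sex = rep_len(c("male", "female"), n_total),
    stringsAsFactors = FALSE)

  mat <- geno_matrix(calls, map, samples)
  truth <- list(ancestral_freqs = p_anc,
                pop_allele_freqs = pop_freq,
                config = config,
                rng = "Mersenne-Twister")
  list(matrix = mat, truth = truth)
}

#' Plant autozygous tracts and apply genotyping noise
#'
#' Each planted tract overwrites the individual's genotypes inside
#' `[start_bp, end_bp]` with homozygous calls consistent with a single
#' sampled haplotype (allele2 with the marker's population frequency), so the
#' tract carries zero heterozygous calls before noise. Genotyping error
#' (hom flipped to het with probability `err_rate`) and missingness
#' (`miss_rate`) are then applied genome-wide, inside and outside tracts.
#' Overlapping tracts planted in one individual are merged in the truth.
#'
#' @param mat a [geno_matrix()].
#' @param roh_plan data.frame with columns `length_bp`, `count`, `freq`,
#'   `chrom`, `start_bp`. Rows with a finite `freq` plant a tract at the fixed
#'   locus (`chrom`, `start_bp`) in each individual independently with that
#'   probability (a shared hotspot); otherwise `count` tracts of `length_bp`
#'   are placed uniformly at random per individual.
#' @param err_rate,miss_rate per-call probabilities; error flips a homozygous
#'   call to heterozygous.
#' @param seed integer seed.
#' @param pop_freqs optional markers x pops matrix of allele2 frequencies
#'   (from [simulate_genotypes()] truth) used to sample tract haplotypes;
#'   defaults to observed sample frequencies.
#' @return list with `matrix` (modified) and `truth` (data.frame
#'   `planted_segments` with sample_id, chrom, start_bp, end_bp).
#' @export
plant_autozygosity <- function(mat, roh_plan, err_rate = 0, miss_rate = 0,
                               seed, pop_freqs = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  calls <- mat$calls
  map <- mat$map
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(ch) max(map$pos_bp[map$chrom == ch]), 0)
  pop_idx <- match(mat$samples$population, unique(mat$samples$population))
  if (is.null(pop_freqs)) {
    pop_freqs <- matrix(colMeans(calls == 2L, na.rm = TRUE) +
                          colMeans(calls == 1L, na.rm = TRUE) / 2,
                        nrow = ncol(calls),
                        ncol = max(pop_idx))
  }

  segs <- list()
  if (!is.null(roh_plan) && nrow(roh_plan) > 0) {
    for (r in seq_len(nrow(roh_plan))) {
      len <- roh_plan$length_bp[r]
      if (any(len > chrom_len))
        stop("planned tract length ", len, " exceeds a chromosome span")
      fixed <- !is.na(roh_plan$freq[r])
      for (i in seq_len(nrow(calls))) {
        n_tracts <- if (fixed) stats::rbinom(1, 1, roh_plan$freq[r]) else roh_plan$count[r]
        if (n_tracts == 0) next
        for (t in seq_len(n_tracts)) {
          if (fixed) {
            ch <- as.character(roh_plan$chrom[r]); s0 <- roh_plan$start_bp[r]
          } else {
            ch <- sample(chroms, 1)
            s0 <- sample.int(max(1, floor(chrom_len[ch] - len + 1)), 1)
          }
          e0 <- s0 + len - 1
          jj <- which(map$chrom == ch & map$pos_bp >= s0 & map$pos_bp <= e0)
          if (length(jj)) {
            hap <- stats::rbinom(length(jj), 1L, pop_freqs[jj, pop_idx[i]])
            calls[i, jj] <- 2L * hap
          }
          segs[[length(segs) + 1L]] <- data.frame(
            sample_id = mat$samples$sample_id[i], chrom = ch,
            start_bp = s0, end_bp = e0, stringsAsFactors = FALSE)
        }
      }
    }
  }
  planted <- if (length(segs)) merge_planted(do.call(rbind, segs))
             else data.frame(sample_id = character(), chrom = character(),
                             start_bp = numeric(), end_bp = numeric())

  if (err_rate > 0) {
    hom <- which(!is.na(calls) & calls != 1L)
    flip <- hom[stats::runif(length(hom)) < err_rate]
    calls[flip] <- 1L
  }
  if (miss_rate > 0) {
    drop <- which(stats::runif(length(calls)) < miss_rate)
    calls[drop] <- NA_integer_
  }
  out <- mat
  out$calls <- calls
  dimnames(out$calls) <- dimnames(mat$calls)
  list(matrix = out, truth = list(planted_segments = planted,
                                  err_rate = err_rate, miss_rate = miss_rate,
                                  rng = "Mersenne-Twister"))
}

# Merge overlapping planted tracts within (sample, chrom).
merge_planted <- function(segs) {
  out <- list()
  for (key in unique(paste(segs$sample_id, segs$chrom, sep = "\r"))) {
    s <- segs[paste(segs$sample_id, segs$chrom, sep = "\r") == key, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    cur <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start_bp[i] <= cur$end_bp + 1) {
        cur$end_bp <- max(cur$end_bp, s$end_bp[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- s[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order_chrom(res$chrom, res$start_bp), , drop = FALSE]
  res <- res[order(res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate an additive phenotype at a focal marker
#'
#' `y = mu + beta * code + gamma_age * age + batch offset + N(0, noise_sd^2)`,
#' where `code` counts copies of the effect allele (allele2) at the focal
#' marker. Ages are uniform integers in `age_range`; batches are assigned
#' round-robin. A missing genotype at the focal marker is replaced by the
#' population mean dosage for phenotype generation (and flagged in the truth).
#'
#' @param mat a [geno_matrix()].
#' @param focal_marker marker_id of the causal SNP.
#' @param beta additive effect per allele copy.
#' @param cov_effects list with `age` (slope per unit age) and `batch`
#'   (numeric vector of per-batch offsets; its length sets the batch count).
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @param mu intercept.
#' @param age_range integer range ages are drawn from.
#' @return list with `phenotypes` (data.frame sample_id, trait, age, batch)
#'   and `truth` (beta, covariate effects, noise_sd, imputed sample ids).
#' @export
simulate_phenotypes <- function(mat, focal_marker, beta,
                                cov_effects = list(age = 0.05, batch = c(0, 1, -1, 0.5)),
                                noise_sd = 1, seed, mu = 50,
                                age_range = c(140L, 200L)) {
  if (missing(seed)) stop("seed is mandatory")
  j <- match(focal_marker, mat$map$marker_id)
  if (is.na(j)) stop("focal marker ", focal_marker, " not in map")
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  n <- nrow(mat$calls)
  code <- mat$calls[, j]
  imputed <- mat$samples$sample_id[is.na(code)]
  code_num <- as.numeric(code)
  code_num[is.na(code_num)] <- mean(code_num, na.rm = TRUE)
  age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
  batch_off <- cov_effects$batch
  batch <- rep_len(seq_along(batch_off), n)
  y <- mu + beta * code_num + cov_effects$age * age + batch_off[batch] +
    stats::rnorm(n, 0, noise_sd)
  list(phenotypes = data.frame(sample_id = mat$samples$sample_id, trait = y,
                               age = age, batch = paste0("b", batch),
                               stringsAsFactors = FALSE),
       truth = list(beta = beta, mu = mu, covariate_effects = cov_effects,
                    noise_sd = noise_sd, focal_marker = focal_marker,
                    imputed = imputed, rng = "Mersenne-Twister"))
}
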