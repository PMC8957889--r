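# Pipeline orchestration: qc -> roh -> inbreeding -> landscape -> sweep -> ne
# -> assoc from a single configuration, with a manifest of every resolved
# parameter so a run can be reproduced exactly.

#' Pipeline configuration
#'
#' @param input one of: a [geno_matrix()], a list `list(ped=, map=)` or
#'   `list(vcf=)` of file paths.
#' @param phenotypes optional phenotype data.frame or TSV path (enables the
#'   association stage together with `assoc_marker`).
#' @param assoc_marker marker_id for the association stage.
#' @param qc a [qc_params()] or `NULL` to skip QC.
#' @param roh a [roh_params()]; `roh_alpha` (false-positive rate) resolves
#'   `min_snp_count` from the data when `roh$min_snp_count` is 1.
#' @param roh_alpha false-positive rate for the minimum-SNP threshold.
#' @param l_auto_bp autosomal span for F_ROH.
#' @param hotspot_threshold occurrence threshold for hotspots.
#' @param flank_bp flank size around hotspot SNPs for the candidate intervals.
#' @param window_bp window size for the diversity/differentiation scan.
#' @param ne_bins_bp distance-bin edges for the Ne stage, `NULL` to skip.
#' @param qtl optional interval data.frame or BED path for overlap reporting.
#' @param qtl_max_bp subject length pre-filter for QTL overlaps.
#' @param stages character vector of stages to run.
#' @param seed integer seed recorded in the manifest (stages themselves are
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, phenotypes = NULL, assoc_marker = NULL,
                            qc = qc_params(), roh = roh_params(),
                            roh_alpha = 0.05, l_auto_bp = 2.45e9,
                            hotspot_threshold = 0.80, flank_bp = 5e4,
                            window_bp = 5e5, ne_bins_bp = NULL, qtl = NULL,
                            qtl_max_bp = 1e6,
                            stages = c("qc", "roh", "inbreeding", "landscape",
                                       "sweep", "ne", "assoc"),
                            seed = 1L) {
  known <- c("qc", "roh", "inbreeding", "landscape", "sweep", "ne", "assoc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(input = input, phenotypes = phenotypes,
                 assoc_marker = assoc_marker, qc = qc, roh = roh,
                 roh_alpha = roh_alpha, l_auto_bp = l_auto_bp,
                 hotspot_threshold = hotspot_threshold, flank_bp = flank_bp,
                 window_bp = window_bp, ne_bins_bp = ne_bins_bp, qtl = qtl,
                 qtl_max_bp = qtl_max_bp, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full ROH analysis pipeline
#'
#' Executes the configured stages in fixed order (qc, roh, inbreeding,
#' landscape, sweep, ne, assoc), writes one TSV/BED per stage under `out_dir`,
#' logs stage/row-count progress to standard error, and writes a
#' `manifest.json` recording the package version, seed, every resolved
#' parameter, input checksums and per-stage row counts. Stage outputs are
#' deterministic: re-running a config gives byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, note) {
    message(sprintf("[%7.2fs] %-10s %s", proc.time()[["elapsed"]] - t0, stage, note))
  }
  checksums <- list()
  if (inherits(config$input, "geno_matrix")) {
    mat <- config$input
  } else if (!is.null(config$input$ped)) {
    mat <- read_ped_map(config$input$ped, config$input$map)
    checksums <- as.list(tools::md5sum(c(config$input$ped, config$input$map)))
  } else if (!is.null(config$input$vcf)) {
    mat <- read_vcf(config$input$vcf)
    checksums <- as.list(tools::md5sum(config$input$vcf))
  } else stop("config$input must be a geno_matrix or list(ped=,map=)/list(vcf=)")
  log_stage("input", sprintf("%d samples x %d markers", n_samples(mat), n_markers(mat)))

  manifest <- list(tool = "rohscape",
                   version = as.character(utils::packageVersion("rohscape")),
                   seed = config$seed, input_checksums = checksums,
                   parameters = list(), counts = list())
  results <- list()
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("qc", function() {
    qr <- apply_qc(mat, config$qc)
    mat <<- qr$matrix
    results$qc_report <<- qr$report
    manifest$parameters$qc <<- unclass(config$qc)
    manifest$counts$post_qc <<- c(samples = n_samples(mat), markers = n_markers(mat))
    write_tsv(qr$report, "qc_report.tsv")
    log_stage("qc", sprintf("%d samples x %d markers retained",
                            n_samples(mat), n_markers(mat)))
  })

  roh_par <- config$roh
  segments <- NULL
  run_stage("roh", function() {
    if (roh_par$min_snp_count <= 1) {
      roh_par$min_snp_count <<- min_snp_count(config$roh_alpha, n_markers(mat),
                                              n_samples(mat),
                                              mean_heterozygosity(mat))
    }
    segments <<- detect_roh(mat, roh_par)
    results$segments <<- segments
    manifest$parameters$roh <<- unclass(roh_par)
    manifest$counts$roh_segments <<- nrow(segments)
    write_tsv(segments, "roh.tsv")
    log_stage("roh", sprintf("%d segments (min_snp_count = %d)",
                             nrow(segments), roh_par$min_snp_count))
  })

  run_stage("inbreeding", function() {
    if (is.null(segments)) stop("requires the roh stage")
    inb <- inbreeding_coefficients(mat, segments, config$l_auto_bp)
    results$inbreeding <<- inb
    manifest$parameters$l_auto_bp <<- config$l_auto_bp
    manifest$counts$inbreeding_rows <<- nrow(inb)
    write_tsv(inb, "inbreeding.tsv")
    log_stage("inbreeding", sprintf("mean F_ROH = %.4f", mean(inb$f_roh_total)))
  })

  run_stage("landscape", function() {
    if (is.null(segments)) stop("requires the roh stage")
    pops <- split(mat$samples$sample_id, mat$samples$population)
    tracks <- lapply(pops, function(ids) roh_occurrence(segments, mat$map, ids))
    track_all <- roh_occurrence(segments, mat)
    hot <- call_hotspots(track_all, config$hotspot_threshold)
    cold <- call_coldspots(tracks)
    results$occurrence <<- track_all
    results$hotspots <<- hot
    results$coldspots <<- cold
    manifest$parameters$hotspot_threshold <<- config$hotspot_threshold
    manifest$parameters$flank_bp <<- config$flank_bp
    manifest$counts$hotspots <<- nrow(hot)
    manifest$counts$coldspots <<- nrow(cold)
    write_tsv(track_all, "occurrence.tsv")
    write_intervals(hot, file.path(out_dir, "hotspots.bed"))
    write_intervals(cold, file.path(out_dir, "coldspots.bed"))
    if (nrow(hot)) {
      flanked <- flank_regions(hot, config$flank_bp)
      write_intervals(flanked, file.path(out_dir, "hotspots_flanked.bed"))
      if (!is.null(config$qtl)) {
        qtl <- if (is.character(config$qtl)) read_intervals(config$qtl) else config$qtl
        ov <- overlap_intervals(flanked, qtl, config$qtl_max_bp)
        results$qtl_overlaps <<- ov
        write_tsv(ov, "qtl_overlaps.tsv")
      }
    }
    log_stage("landscape", sprintf("%d hotspot(s), %d coldspot(s)",
                                   nrow(hot), nrow(cold)))
  })

  run_stage("sweep", function() {
    pops <- unique(mat$samples$population)
    win_pi <- windowed_pi(mat, config$window_bp)
    win_d <- windowed_tajima_d(mat, config$window_bp)
    sweep_tbl <- merge(win_pi[, c("chrom", "win_start_bp", "win_end_bp", "n_snps", "pi")],
                       win_d[, c("chrom", "win_start_bp", "tajima_d")],
                       by = c("chrom", "win_start_bp"))
    if (length(pops) >= 2) {
      m1 <- subset_geno(mat, samples = which(mat$samples$population == pops[1]))
      m2 <- subset_geno(mat, samples = which(mat$samples$population == pops[2]))
      fst <- windowed_fst(m1, m2, config$window_bp)
      sweep_tbl <- merge(sweep_tbl,
                         fst$windows[, c("chrom", "win_start_bp", "fst")],
                         by = c("chrom", "win_start_bp"), all.x = TRUE)
      manifest$counts$fst_weighted <<- fst$fst_weighted
    }
    sweep_tbl <- sweep_tbl[order_chrom(sweep_tbl$chrom, sweep_tbl$win_start_bp), ]
    results$sweep <<- sweep_tbl
    manifest$parameters$window_bp <<- config$window_bp
    write_tsv(sweep_tbl, "sweep.tsv")
    log_stage("sweep", sprintf("%d windows", nrow(sweep_tbl)))
  })

  run_stage("ne", function() {
    if (is.null(config$ne_bins_bp)) return(invisible(NULL))
    ne <- ne_ld(mat, config$ne_bins_bp)
    results$ne <<- ne
    manifest$parameters$ne <<- list(bins_bp = config$ne_bins_bp,
                                    alpha_const = 2.2, f_c = "c",
                                    t = "1/(2c)", r2_adj = "r2 - 1/n")
    write_tsv(ne, "ne.tsv")
    log_stage("ne", sprintf("%d distance bins", nrow(ne)))
  })

  run_stage("assoc", function() {
    if (is.null(config$phenotypes) || is.null(config$assoc_marker))
      return(invisible(NULL))
    ph <- if (is.character(config$phenotypes)) read_phenotypes(config$phenotypes)
          else config$phenotypes
    ar <- linear_assoc(mat, ph, config$assoc_marker)
    results$assoc <<- ar
    manifest$parameters$assoc_marker <<- config$assoc_marker
    write_tsv(data.frame(marker_id = ar$marker_id, n_used = ar$n_used,
                         beta = ar$beta, se = ar$se, t_stat = ar$t_stat,
                         p = ar$p_two_sided), "assoc.tsv")
    log_stage("assoc", sprintf("beta = %.4g, p = %.4g", ar$beta, ar$p_two_sided))
  })

  manifest$counts$final <- c(samples = n_samples(mat), markers = n_markers(mat))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}
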