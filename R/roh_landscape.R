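# ROH landscape: per-SNP occurrence, hotspot/coldspot calling, interval
# flanking and overlap. Interval set operations go through IRanges.

#' Per-SNP ROH occurrence track
#'
#' For each marker, the number and fraction of individuals whose ROH cover it.
#' A marker counts for an individual when its position lies within
#' `[start_bp, end_bp]` of any of that individual's segments; the denominator
#' is all individuals supplied (not only those with segments).
#'
#' @param segments data.frame from [detect_roh()].
#' @param map marker map (data.frame with `marker_id`, `chrom`, `pos_bp`) or a
#'   [geno_matrix()] whose map is used.
#' @param sample_ids all individuals in the population; defaults to the
#'   samples of `map` when it is a `geno_matrix`.
#' @return data.frame `marker_id`, `chrom`, `pos_bp`, `n_in_roh`, `occurrence`.
#' @export
roh_occurrence <- function(segments, map, sample_ids = NULL) {
  if (inherits(map, "geno_matrix")) {
    if (is.null(sample_ids)) sample_ids <- map$samples$sample_id
    map <- map$map
  }
  if (is.null(sample_ids)) stop("sample_ids required when map is a data.frame")
  n_ind <- length(sample_ids)
  n_in <- integer(nrow(map))
  segments <- segments[segments$sample_id %in% sample_ids, , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    jj <- which(map$chrom == ch)
    if (!length(jj)) next
    pos <- map$pos_bp[jj]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    # segments of one individual never overlap, so summing per segment counts
    # each (individual, marker) pair at most once
    for (s in seq_len(nrow(seg))) {
      lo <- findInterval(seg$start_bp[s] - 0.5, pos) + 1L
      hi <- findInterval(seg$end_bp[s] + 0.5, pos)
      if (hi >= lo) n_in[jj[lo:hi]] <- n_in[jj[lo:hi]] + 1L
    }
  }
  data.frame(marker_id = map$marker_id, chrom = map$chrom, pos_bp = map$pos_bp,
             n_in_roh = n_in, occurrence = n_in / n_ind,
             stringsAsFactors = FALSE)
}

#' Call ROH hotspots
#'
#' Maximal runs of consecutive markers whose occurrence reaches the threshold
#' (>= by default); a single sub-threshold marker breaks a run. Region bounds
#' are the first/last member marker positions; single-marker regions are
#' reported.
#'
#' @param track occurrence track from [roh_occurrence()].
#' @param threshold occurrence threshold in (0, 1], default 0.80.
#' @param inclusive if `TRUE` (default) markers at exactly the threshold are
#'   included; if `FALSE` the rule is strictly greater.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `mean_occurrence`, `max_occurrence`.
#' @export
call_hotspots <- function(track, threshold = 0.80, inclusive = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  hot <- if (inclusive) track$occurrence >= threshold else track$occurrence > threshold
  runs_to_regions(track, hot, function(idx) {
    data.frame(n_snps = length(idx),
               mean_occurrence = mean(track$occurrence[idx]),
               max_occurrence = max(track$occurrence[idx]))
  })
}

#' Call ROH coldspots
#'
#' Maximal runs of consecutive markers with occurrence exactly zero in every
#' supplied population track (markers never covered by any individual's ROH).
#'
#' @param tracks a single track or a list of occurrence tracks on identical
#'   marker maps (one per population).
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`.
#' @export
call_coldspots <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!identical(t$marker_id, ref$marker_id) ||
        !identical(t$pos_bp, ref$pos_bp))
      stop("coldspot tracks must share an identical marker map")
  }
  cold <- Reduce(`&`, lapply(tracks, function(t) t$occurrence == 0))
  runs_to_regions(ref, cold, function(idx) data.frame(n_snps = length(idx)))
}

# Shared run-to-region logic: maximal runs of `flag` within chromosomes.
runs_to_regions <- function(track, flag, summarise) {
  out <- list()
  for (ch in unique(track$chrom)) {
    jj <- which(track$chrom == ch)
    r <- rle(flag[jj])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- jj[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- cbind(
        data.frame(chrom = ch, start_bp = track$pos_bp[idx[1]],
                   end_bp = track$pos_bp[idx[length(idx)]],
                   stringsAsFactors = FALSE),
        summarise(idx))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flank and merge genomic positions or regions
#'
#' Expands each input point/region by `flank_bp` on both sides (the 100 kb
#' candidate-gene windows use 50 kb on each side), clips at 1 bp and at the
#' chromosome end when known, and merges overlapping or bookended expansions.
#'
#' @param x data.frame of positions (`chrom`, `pos_bp`) or regions
#'   (`chrom`, `start_bp`, `end_bp`).
#' @param flank_bp flank size in bp (>= 0), default 50,000.
#' @param chrom_lengths optional named vector of chromosome ends for clipping.
#' @return data.frame of merged intervals `chrom`, `start_bp`, `end_bp`.
#' @export
flank_regions <- function(x, flank_bp = 5e4, chrom_lengths = NULL) {
  stopifnot(flank_bp >= 0)
  if (!is.null(x$pos_bp) && is.null(x$start_bp)) {
    start <- x$pos_bp; end <- x$pos_bp
  } else {
    start <- x$start_bp; end <- x$end_bp
  }
  start <- pmax(1, start - flank_bp)
  end <- end + flank_bp
  if (!is.null(chrom_lengths))
    end <- pmin(end, as.numeric(chrom_lengths[as.character(x$chrom)]))
  out <- list()
  for (ch in unique(as.character(x$chrom))) {
    sel <- as.character(x$chrom) == ch
    ir <- IRanges::reduce(IRanges::IRanges(start = start[sel], end = end[sel]))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start_bp = as.numeric(IRanges::start(ir)),
      end_bp = as.numeric(IRanges::end(ir)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order_chrom(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Overlap two interval sets
#'
#' Reports every (query, subject) pair sharing at least one bp, with the
#' overlap length. Subjects longer than `max_subject_length_bp` are dropped
#' first (the convention for uncertain, over-long QTL annotations).
#'
#' @param query,subject interval data.frames (`chrom`, `start_bp`, `end_bp`,
#'   optional `name`).
#' @param max_subject_length_bp pre-filter on subject length in bp, or `NULL`
#'   to keep all subjects; default 1,000,000.
#' @return data.frame with query/subject coordinates, names and `overlap_bp`.
#' @export
overlap_intervals <- function(query, subject, max_subject_length_bp = 1e6) {
  if (!is.null(max_subject_length_bp)) {
    keep <- (subject$end_bp - subject$start_bp + 1) <= max_subject_length_bp
    subject <- subject[keep, , drop = FALSE]
  }
  empty <- data.frame(q_chrom = character(), q_start_bp = numeric(),
                      q_end_bp = numeric(), q_name = character(),
                      s_start_bp = numeric(), s_end_bp = numeric(),
                      s_name = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(query) == 0 || nrow(subject) == 0) return(empty)
  qname <- if (is.null(query$name)) rep(NA_character_, nrow(query)) else query$name
  sname <- if (is.null(subject$name)) rep(NA_character_, nrow(subject)) else subject$name
  out <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch); si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(start = query$start_bp[qi], end = query$end_bp[qi])
    sr <- IRanges::IRanges(start = subject$start_bp[si], end = subject$end_bp[si])
    hits <- IRanges::findOverlaps(qr, sr)
    if (!length(hits)) next
    qh <- qi[S4Vectors::queryHits(hits)]; sh <- si[S4Vectors::subjectHits(hits)]
    ov <- pmin(query$end_bp[qh], subject$end_bp[sh]) -
      pmax(query$start_bp[qh], subject$start_bp[sh]) + 1
    out[[length(out) + 1L]] <- data.frame(
      q_chrom = ch, q_start_bp = query$start_bp[qh], q_end_bp = query$end_bp[qh],
      q_name = qname[qh], s_start_bp = subject$start_bp[sh],
      s_end_bp = subject$end_bp[sh], s_name = sname[sh], overlap_bp = ov,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
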