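#' Per-base median coverage across IP samples
#'
#' @param tracks List of `coverage_track` objects (typically all IP
#'   libraries).
#' @return An `RleList` with one integer/numeric Rle of per-base medians
#'   per chromosome (chromosomes padded to the longest track).
#' @export
median_ip_coverage <- function(tracks) {
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$depth))))
  res <- lapply(chroms, function(chr) {
    lens <- vapply(tracks, function(t)
      if (chr %in% names(t$depth)) length(t$depth[[chr]]) else 0L, 0L)
    n <- max(lens)
    if (n == 0L) return(S4Vectors::Rle(0L, 0L))
    mat <- vapply(tracks, function(t) {
      v <- rep.int(0L, n)
      if (chr %in% names(t$depth)) {
        d <- as.integer(t$depth[[chr]])
        v[seq_along(d)] <- d
      }
      v
    }, integer(n))
    S4Vectors::Rle(row_median(mat))
  })
  names(res) <- chroms
  methods::as(res, "SimpleRleList")
}

# row-wise median via a column-sorting network of pmin/pmax (fast for the
# small sample counts used here)
row_median <- function(mat) {
  k <- ncol(mat)
  if (k == 1L) return(as.numeric(mat[, 1L]))
  cols <- lapply(seq_len(k), function(j) mat[, j])
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo; cols[[j + 1L]] <- hi
    }
  }
  if (k %% 2L == 1L) as.numeric(cols[[(k + 1L) %/% 2L]])
  else (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
}

#' Occurrence filter across IP samples
#'
#' A window is retained for a technique when it was detected (passed) in at
#' least `min_samples` IP samples.
#'
#' @param results Detection-result data.frame for one technique across IP
#'   samples (rows = window x sample, columns `window_id`, `ip_sample_id`,
#'   `pass`), e.g. `rbind` of per-pair [fisher_detect()] outputs.
#' @param min_samples Minimum supporting IP samples (default 3).
#' @return data.frame with `window_id` and `occurrence` for the retained
#'   windows.
#' @export
occurrence_filter <- function(results, min_samples = 3L) {
  n_ip <- length(unique(results$ip_sample_id))
  if (n_ip < min_samples)
    stop("only ", n_ip, " IP samples present but min_samples = ",
         min_samples, "; lower min_samples to proceed")
  occ <- tapply(results$pass, results$window_id, sum)
  keep <- occ >= min_samples
  data.frame(window_id = names(occ)[keep],
             occurrence = as.integer(occ[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# leftmost position (0-based) of the maximum of med_cov within
# [start, end); falls back to the region centre when coverage is all zero
max_coverage_position <- function(med_cov, chrom, start, end,
                                  warn_zero = TRUE) {
  v <- NULL
  if (chrom %in% names(med_cov)) {
    d <- med_cov[[chrom]]
    s <- start + 1L; e <- min(end, length(d))
    if (s <= e) v <- as.numeric(S4Vectors::window(d, s, e))
  }
  if (is.null(v) || length(v) == 0L || max(v) == 0) {
    if (warn_zero)
      warning("region ", chrom, ":", start, "-", end,
              " has zero median coverage; using region centre")
    return(start + (end - start) %/% 2L)
  }
  start + which.max(v) - 1L
}

#' Merge passing windows and recenter on maximum median coverage
#'
#' Overlapping (by at least 1 bp; not merely adjacent) windows retained for
#' one technique are merged into candidate regions. Each region is replaced
#' by the `width`-bp interval centered at the position of maximum median IP
#' coverage within it (leftmost maximum on ties).
#'
#' @param kept data.frame from [occurrence_filter()] (`window_id`,
#'   `occurrence`).
#' @param windows The window grid the ids refer to.
#' @param med_cov Median IP coverage from [median_ip_coverage()].
#' @param width Final site width in bp (default 150).
#' @return data.frame of candidate sites: `chrom`, `start`, `end` (the
#'   recentered interval), `region_start`, `region_end` (the merged
#'   window union), `max_cov_pos`, `occurrence` (max over merged windows).
#' @export
merge_and_recenter <- function(kept, windows, med_cov, width = 150L) {
  w <- windows[match(kept$window_id, windows$window_id), ]
  merged <- merge_intervals(w$chrom, w$start, w$end)
  if (nrow(merged) == 0L) return(empty_sites())
  gr <- GenomicRanges::GRanges(merged$chrom,
          IRanges::IRanges(merged$start + 1L, merged$end))
  wgr <- windows_to_granges(w)
  hit <- GenomicRanges::findOverlaps(wgr, gr)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  occ <- vapply(seq_len(nrow(merged)), function(i)
    max(kept$occurrence[qh[sh == i]]), 0L)
  pos <- vapply(seq_len(nrow(merged)), function(i)
    max_coverage_position(med_cov, merged$chrom[i], merged$start[i],
                          merged$end[i]), 0L)
  half <- width %/% 2L
  data.frame(chrom = merged$chrom,
             start = pos - half, end = pos - half + width,
             region_start = merged$start, region_end = merged$end,
             max_cov_pos = pos, occurrence = occ,
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             region_start = integer(), region_end = integer(),
             max_cov_pos = integer(), occurrence = integer(),
             stringsAsFactors = FALSE)
}

# union of strictly overlapping intervals (adjacent intervals stay apart)
merge_intervals <- function(chrom, start, end) {
  if (length(chrom) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end)), min.gapwidth = 0L)
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Combine technique-level sites into consensus peaks
#'
#' Genomic positions covered by candidate sites from at least
#' `min_techniques` distinct techniques are merged; each merged region is
#' recentered to a `width`-bp peak at its maximum-median-coverage position
#' (recomputed on the combined region) and clipped at chromosome bounds.
#' Peaks are assigned to the gene they overlap most.
#'
#' @param sites Named list (by technique) of site data.frames from
#'   [merge_and_recenter()].
#' @param med_cov Median IP coverage.
#' @param genes List of [gene_model] objects (for gene assignment).
#' @param min_techniques Minimum distinct supporting techniques (default 3).
#' @param width Peak width (default 150).
#' @param chrom_sizes Optional named chromosome lengths for clipping.
#' @return An object of class `merip_peaks`: data.frame with `peak_id`,
#'   `chrom`, `start`, `end`, `strand`, `gene_id`, `max_cov_pos`,
#'   `n_techniques`, `clipped`.
#' @export
combine_techniques <- function(sites, med_cov, genes, min_techniques = 3L,
                               width = 150L, chrom_sizes = NULL) {
  nonempty <- Filter(function(s) nrow(s) > 0L, sites)
  mk_peaks <- function(d) structure(d, class = c("merip_peaks", "data.frame"))
  empty <- mk_peaks(data.frame(
    peak_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), gene_id = character(),
    max_cov_pos = integer(), n_techniques = integer(), clipped = logical(),
    stringsAsFactors = FALSE))
  if (length(nonempty) < min_techniques) return(empty)
  grl <- lapply(nonempty, function(s) GenomicRanges::reduce(
    GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1L, s$end)),
    min.gapwidth = 0L))
  allgr <- do.call(c, unname(grl))  # each technique reduced: per-base
  support <- GenomicRanges::coverage(allgr)  # count = distinct techniques
  rl <- IRanges::slice(support, lower = min_techniques, rangesOnly = TRUE)
  regions <- GenomicRanges::GRanges(
    rep(names(rl), lengths(rl)), unlist(rl, use.names = FALSE))
  regions <- GenomicRanges::reduce(regions, min.gapwidth = 0L)
  regions <- GenomicRanges::sort(regions)
  if (length(regions) == 0L) return(empty)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  rs <- GenomicRanges::start(regions) - 1L
  re <- GenomicRanges::end(regions)
  pos <- vapply(seq_along(regions), function(i)
    max_coverage_position(med_cov, chrom[i], rs[i], re[i]), 0L)
  half <- width %/% 2L
  start <- pos - half; end <- pos - half + width
  clipped <- rep(FALSE, length(start))
  low <- start < 0L
  start[low] <- 0L; clipped[low] <- TRUE
  if (!is.null(chrom_sizes)) {
    cs <- chrom_sizes[chrom]
    over <- !is.na(cs) & end > cs
    end[over] <- as.integer(cs[over]); clipped[over] <- TRUE
  }
  # distinct techniques actually supporting each final region
  ntech <- rowSums(matrix(vapply(grl, function(g) {
    GenomicRanges::countOverlaps(regions, g) > 0L
  }, logical(length(regions))), nrow = length(regions)))
  peaks <- data.frame(
    peak_id = sprintf("peak_%05d", seq_along(start)),
    chrom = chrom, start = start, end = end, strand = "*",
    gene_id = NA_character_, max_cov_pos = pos,
    n_techniques = as.integer(ntech), clipped = clipped,
    stringsAsFactors = FALSE)
  if (!is.null(genes) && length(genes)) {
    ggr <- genes_to_granges(genes)
    pgr <- GenomicRanges::GRanges(peaks$chrom,
             IRanges::IRanges(peaks$start + 1L, peaks$end))
    hit <- GenomicRanges::findOverlaps(pgr, ggr, ignore.strand = TRUE)
    if (length(hit)) {
      ov <- GenomicRanges::width(IRanges::pintersect(
        pgr[S4Vectors::queryHits(hit)], ggr[S4Vectors::subjectHits(hit)],
        ignore.strand = TRUE))
      best <- tapply(seq_along(ov), S4Vectors::queryHits(hit),
                     function(ii) ii[which.max(ov[ii])])
      qh <- S4Vectors::queryHits(hit)[unlist(best)]
      sh <- S4Vectors::subjectHits(hit)[unlist(best)]
      peaks$gene_id[qh] <- ggr$gene_id[sh]
      peaks$strand[qh] <- as.character(GenomicRanges::strand(ggr))[sh]
    }
  }
  mk_peaks(peaks)
}

#' @export
print.merip_peaks <- function(x, ...) {
  cat("merip_peaks:", nrow(x), "consensus peaks\n")
  if (nrow(x)) {
    if ("region" %in% names(x))
      print(table(region = x$region))
    NextMethod()
  }
  invisible(x)
}

#' Annotate peaks with the gene region they fall in
#'
#' Assigns each peak the label of the gene region it overlaps, with
#' precedence 5UTR > 3UTR > CDS > intron when a peak straddles a junction.
#' Peaks overlapping no annotated gene are labelled `intergenic` with a
#' warning.
#'
#' @param peaks Peaks data.frame (needs `chrom`, `start`, `end`,
#'   `gene_id`).
#' @param genes List of [gene_model] objects named by gene id.
#' @param precedence Character vector ordering the labels (default
#'   `c("5UTR","3UTR","CDS","intron")`).
#' @return `peaks` with a `region` column added.
#' @export
annotate_region <- function(peaks, genes,
                            precedence = c("5UTR", "3UTR", "CDS", "intron")) {
  lab <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- if (!is.na(peaks$gene_id[i])) genes[[peaks$gene_id[i]]] else NULL
    if (is.null(g) || peaks$end[i] <= g$span[["start"]] ||
        peaks$start[i] >= g$span[["end"]]) {
      lab[i] <- "intergenic"
      next
    }
    s <- peaks$start[i]; e <- peaks$end[i]
    hits <- c(`5UTR` = overlaps_any(s, e, g$utr5),
              `3UTR` = overlaps_any(s, e, g$utr3),
              CDS = overlaps_any(s, e, g$cds),
              intron = TRUE)  # inside the span but outside all features
    lab[i] <- precedence[which(hits[precedence])[1L]]
  }
  if (any(lab == "intergenic"))
    warning(sum(lab == "intergenic"), " peak(s) overlap no gene; ",
            "labelled intergenic")
  peaks$region <- lab
  peaks
}

overlaps_any <- function(s, e, iv) {
  nrow(iv) > 0L && any(iv[, "start"] < e & iv[, "end"] > s)
}

#' RGACW motif score of peak sequences
#'
#' Counts occurrences (overlaps allowed) of the four RGACW m6A consensus
#' pentamers on the sense strand of each peak and sums their weights:
#' GAACA = 2, GGACA = 3, GAACT = 5, GGACT = 8.
#'
#' @param peaks Peaks data.frame with `chrom`, `start`, `end`, `strand`.
#' @param genome A named `DNAStringSet` (one sequence per chromosome).
#' @return `peaks` with integer `motif_score` and logical `rgacw_present`
#'   columns added.
#' @export
motif_score <- function(peaks, genome) {
  weights <- c(GAACA = 2L, GGACA = 3L, GAACT = 5L, GGACT = 8L)
  score <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(genome)) next
    s <- max(0L, peaks$start[i]); e <- min(length(genome[[chr]]), peaks$end[i])
    if (e - s < 5L) next
    seq <- Biostrings::subseq(genome[[chr]], s + 1L, e)
    if (identical(peaks$strand[i], "-"))
      seq <- Biostrings::reverseComplement(seq)
    score[i] <- sum(vapply(names(weights), function(mot)
      Biostrings::countPattern(mot, seq) * weights[[mot]], 0L))
  }
  peaks$motif_score <- score
  peaks$rgacw_present <- score > 0L
  peaks
}

#' Overlap of peaks with a reference peak set
#'
#' @param peaks Peaks data.frame.
#' @param reference data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. a published m6A peak database exported as BED.
#' @return list with `overlap` (per-peak logical, >= 1 bp overlap) and
#'   `fraction` (share of peaks overlapping the reference).
#' @export
reference_overlap <- function(peaks, reference) {
  if (nrow(peaks) == 0L) return(list(overlap = logical(), fraction = NA_real_))
  if (nrow(reference) == 0L)
    return(list(overlap = rep(FALSE, nrow(peaks)), fraction = 0))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
           IRanges::IRanges(peaks$start + 1L, peaks$end))
  rgr <- GenomicRanges::GRanges(reference$chrom,
           IRanges::IRanges(reference$start + 1L, reference$end))
  ov <- GenomicRanges::countOverlaps(pgr, rgr) > 0L
  list(overlap = ov, fraction = mean(ov))
}

#' Metagene position of each peak on its transcript
#'
#' Maps each peak's midpoint onto the spliced transcript of its host gene
#' and rescales piecewise so that the 5'UTR spans [0,1), the CDS [1,2) and
#' the 3'UTR [2,3). Strand-aware: transcript coordinates run 5' to 3'.
#' Peaks on genes without CDS annotation, or whose midpoint is intronic,
#' get `NA` and are excluded from metagene summaries.
#'
#' @param peaks Peaks data.frame (needs `chrom`, `start`, `end`,
#'   `gene_id`).
#' @param genes List of [gene_model] objects named by gene id.
#' @return Numeric vector of scaled positions in [0,3), `NA` where
#'   undefined.
#' @export
metagene_positions <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    gid <- peaks$gene_id[i]
    if (is.na(gid) || is.null(genes[[gid]])) return(NA_real_)
    g <- genes[[gid]]
    if (nrow(g$cds) == 0L) return(NA_real_)
    mid <- peaks$start[i] + (peaks$end[i] - peaks$start[i]) %/% 2L
    pos <- exonic_positions(g)
    if (g$strand == "-") pos <- rev(pos)
    ti <- match(mid, pos)
    if (is.na(ti)) return(NA_real_)
    L5 <- sum(g$utr5[, "end"] - g$utr5[, "start"])
    Lc <- sum(g$cds[, "end"] - g$cds[, "start"])
    L3 <- sum(g$utr3[, "end"] - g$utr3[, "start"])
    if (ti <= L5) return((ti - 1) / L5)
    if (ti <= L5 + Lc) return(1 + (ti - L5 - 1) / Lc)
    if (L3 > 0 && ti <= L5 + Lc + L3) return(2 + (ti - L5 - Lc - 1) / L3)
    NA_real_
  }, 0)
}
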