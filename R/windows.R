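#' Generate the 100-bp half-overlapping window grid
#'
#' Each gene's genomic extent (introns included) is tiled with windows of
#' `size` bp starting every `step` bp from the gene's leftmost coordinate,
#' so consecutive windows overlap in their middle. Windows are emitted
#' while they fit entirely inside the gene span; a gene shorter than `size`
#' yields a single window covering the whole gene. For a span of L >= size
#' bp the window count is `floor((L - size)/step) + 1`.
#'
#' @param genes List of [gene_model] objects.
#' @param size Window width in bp (default 100).
#' @param step Offset between consecutive window starts (default 50, half
#'   the width).
#' @return data.frame with `window_id` (`gene_id:index`), `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open genomic).
#' @export
generate_windows <- function(genes, size = 100L, step = 50L) {
  out <- lapply(genes, function(g) {
    s0 <- g$span[["start"]]; L <- g$span[["end"]] - s0
    starts <- if (L < size) 0L else seq.int(0L, L - size, by = step)
    ends <- if (L < size) L else starts + size
    data.frame(
      window_id = paste0(g$gene_id, ":", seq_along(starts)),
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      start = s0 + starts, end = s0 + ends,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
    IRanges::IRanges(windows$start + 1L, windows$end))
}

#' Count reads in windows or features
#'
#' Builds the window-by-sample count matrix. For tracks carrying read
#' intervals, a read contributes to every window it overlaps (the
#' union/nonunique-all convention, so overlapping windows each count it).
#' For depth-only tracks the count is the summed per-base depth over the
#' window divided by the read length, rounded.
#'
#' @param tracks List of `coverage_track` objects.
#' @param windows Window (or feature) data.frame with `chrom`, `start`,
#'   `end` and an id in the first column.
#' @param samples Optional sample metadata data.frame aligned with
#'   `tracks`; defaults to ids/roles taken from the tracks.
#' @param read_length Read length used to convert depth sums to read
#'   counts in coverage mode (default 65).
#' @return An object of class `window_counts`: list with `windows`,
#'   `samples`, integer matrix `counts` (windows x samples) and
#'   `library_sizes`.
#' @export
count_reads_in_windows <- function(tracks, windows, samples = NULL,
                                   read_length = 65L) {
  gr <- windows_to_granges(windows)
  counts <- vapply(tracks, function(tr) {
    if (!is.null(tr$reads)) {
      n <- rep.int(0L, length(gr))
      shared <- as.character(GenomicRanges::seqnames(gr)) %in%
        GenomeInfoDb::seqlevels(tr$reads)
      if (!all(shared))
        warning("track ", tr$sample_id, ": windows on chromosomes ",
                "absent from the track count 0")
      if (any(shared))
        n[shared] <- suppressWarnings(
          GenomicRanges::countOverlaps(gr[shared], tr$reads))
      n
    } else {
      count_from_depth(tr, windows, read_length)
    }
  }, integer(nrow(windows)))
  rownames(counts) <- windows[[1L]]
  if (is.null(samples))
    samples <- data.frame(
      sample_id = vapply(tracks, `[[`, "", "sample_id"),
      role = vapply(tracks, `[[`, "", "role"),
      stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample_id
  structure(list(windows = windows, samples = samples, counts = counts,
                 library_sizes = stats::setNames(
                   vapply(tracks, `[[`, 0, "library_size"),
                   samples$sample_id)),
            class = "window_counts")
}

count_from_depth <- function(tr, windows, read_length) {
  n <- rep.int(0L, nrow(windows))
  for (chr in unique(windows$chrom)) {
    idx <- which(windows$chrom == chr)
    if (!chr %in% names(tr$depth)) {
      warning("track ", tr$sample_id, ": chromosome ", chr,
              " absent, windows count 0")
      next
    }
    d <- tr$depth[[chr]]
    clen <- length(d)
    s <- pmin(windows$start[idx] + 1L, clen + 1L)
    e <- pmin(windows$end[idx], clen)
    ok <- s <= e
    if (any(ok)) {
      v <- IRanges::Views(d, start = s[ok], end = e[ok])
      n[idx[ok]] <- as.integer(round(IRanges::viewSums(v) / read_length))
    }
  }
  n
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Subset a window_counts object by window
#' @param m A `window_counts` object.
#' @param keep Logical or index vector over windows.
#' @return The subset `window_counts`.
#' @export
subset_windows <- function(m, keep) {
  m$windows <- m$windows[keep, , drop = FALSE]
  m$counts <- m$counts[keep, , drop = FALSE]
  m
}

#' Minimum-IP-coverage window filter
#'
#' Keeps the windows whose read count in the IP library under consideration
#' is strictly greater than `min_reads` (default 10). With
#' `mode = "per-sample"` the filter uses the single named IP sample (the
#' per-pair detection convention); with `mode = "any"` a window is kept if
#' any IP sample exceeds the threshold.
#'
#' @param m A `window_counts` object.
#' @param ip_sample IP sample id (required for `mode = "per-sample"`).
#' @param min_reads Threshold; strict inequality (default 10).
#' @param mode `"per-sample"` or `"any"`.
#' @return The filtered `window_counts`.
#' @export
filter_min_ip_coverage <- function(m, ip_sample = NULL, min_reads = 10L,
                                   mode = c("per-sample", "any")) {
  mode <- match.arg(mode)
  if (mode == "per-sample") {
    if (is.null(ip_sample)) stop("ip_sample required for per-sample mode")
    keep <- m$counts[, ip_sample] > min_reads
  } else {
    ip_cols <- m$samples$sample_id[m$samples$role == "IP"]
    keep <- apply(m$counts[, ip_cols, drop = FALSE] > min_reads, 1L, any)
  }
  subset_windows(m, keep)
}

#' @rdname count_reads_in_windows
#' @param features Feature data.frame (genes or peaks) with an id column
#'   first plus `chrom`, `start`, `end`.
#' @export
count_reads_in_features <- function(tracks, features, samples = NULL,
                                    read_length = 65L) {
  count_reads_in_windows(tracks, features, samples = samples,
                         read_length = read_length)
}

#' Feature table for gene-level counting
#' @param genes List of [gene_model] objects.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` spanning each
#'   gene's genomic extent.
#' @export
genes_to_features <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, function(g) g$span[["start"]], 0),
    end = vapply(genes, function(g) g$span[["end"]], 0),
    stringsAsFactors = FALSE, row.names = NULL)
}
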