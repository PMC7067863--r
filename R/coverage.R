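#' Coverage track objects
#'
#' A `coverage_track` holds per-base read depth for one sequencing library
#' (an IP or an Input dataset) as a run-length encoded vector per
#' chromosome, plus the library size used for per-million scaling. Tracks
#' built from alignments additionally carry the read intervals, so that
#' window counting can use exact read-overlap semantics instead of
#' depth-sum approximation.
#'
#' @param sample_id Sample identifier.
#' @param role `"IP"` or `"Input"`.
#' @param depth An `RleList` of integer depths, one element per chromosome.
#' @param library_size Total mapped read count (positive unless the track
#'   is empty).
#' @param reads Optional `GRanges` of the individual reads.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, role, depth, library_size,
                           reads = NULL) {
  role <- match.arg(role, c("IP", "Input"))
  if (library_size < 0) stop("library_size must be >= 0")
  if (any(vapply(depth, function(d) any(S4Vectors::runValue(d) < 0), TRUE)))
    stop("depth values must be >= 0")
  structure(list(sample_id = as.character(sample_id), role = role,
                 depth = depth, library_size = library_size, reads = reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", x$sample_id, sprintf("[%s]", x$role),
      "library_size =", x$library_size,
      "chroms =", paste(names(x$depth), collapse = ","), "\n")
  invisible(x)
}

#' Build a coverage track from aligned reads
#'
#' @param reads `GRanges` of read alignments.
#' @param sample_id,role Passed to [coverage_track()].
#' @param seqlengths Optional named chromosome lengths; defaults to those of
#'   `reads`.
#' @return A `coverage_track`; `library_size` is the number of reads.
#' @export
track_from_reads <- function(reads, sample_id, role, seqlengths = NULL) {
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(reads) <- names(seqlengths)
    GenomeInfoDb::seqlengths(reads) <- seqlengths
  }
  coverage_track(sample_id, role, GenomicRanges::coverage(reads),
                 length(reads), reads = reads)
}

#' Read a coverage track from a bedGraph or BAM file
#'
#' bedGraph intervals are interpreted as 0-based half-open with constant
#' depth; overlapping intervals are rejected. Because a bedGraph does not
#' retain read identity, `library_size` must then be supplied through the
#' sample metadata. For BAM input the reads are loaded (the index is
#' required), depth is computed from the alignments and `library_size` is
#' the alignment count.
#'
#' @param path Path to a `.bedgraph`/`.bdg`/`.bg` or `.bam` file.
#' @param sample One row of a sample metadata table (see
#'   [read_sample_metadata()]) with at least `sample_id` and `role`;
#'   `library_size` is required for bedGraph input.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(path, sample) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      stop("BAM file '", path, "' has no index (.bai)")
    aln <- GenomicAlignments::readGAlignments(path)
    return(track_from_reads(GenomicRanges::granges(aln),
                            sample$sample_id, sample$role))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    by_chr <- GenomicRanges::split(gr, GenomicRanges::seqnames(gr))
    if (any(vapply(by_chr, function(x)
          !IRanges::isDisjoint(IRanges::ranges(x)), TRUE)))
      stop("bedGraph '", path, "' has overlapping intervals")
  }
  depth <- if (length(gr)) GenomicRanges::coverage(gr, weight = "score")
           else GenomicRanges::coverage(gr)
  depth <- methods::as(lapply(depth, function(d) {
    S4Vectors::runValue(d) <- as.integer(round(S4Vectors::runValue(d)))
    d
  }), "SimpleRleList")
  lib <- sample$library_size
  if (is.null(lib) || is.na(lib)) {
    if (length(gr) == 0L) lib <- 0
    else stop("library_size must be supplied in metadata for bedGraph input")
  }
  coverage_track(sample$sample_id, sample$role, depth, lib)
}

#' Write a depth track to bedGraph
#' @param depth `RleList` of per-base depth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path) {
  gr <- methods::as(depth, "GRanges")
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read sample metadata
#'
#' Reads the tab-separated sample table. Required columns: `sample_id`,
#' `role` (IP/Input), `pair_id` (links each IP library to its Input),
#' `condition`, `sequencing_batch`, `library_batch`, `ip_procedure`,
#' `library_size`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "role", "pair_id", "condition", "sequencing_batch",
           "library_batch", "ip_procedure", "library_size")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
  if (!all(md$role %in% c("IP", "Input")))
    stop("role must be 'IP' or 'Input'")
  md
}

#' Write / read consensus peaks as BED6+4
#'
#' Peaks are written sorted by (chrom, start) as BED6 plus four extra
#' columns: `gene_id`, `region`, `motif_score`, `n_techniques`. Coordinates
#' are 0-based half-open in both the file and the data.frame, so the
#' round-trip is the identity.
#'
#' @param peaks A peaks data.frame as produced by [combine_techniques()].
#' @param path Output path.
#' @return `write_peaks_bed`: `path` invisibly; `read_peaks_bed`: the peaks
#'   data.frame.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  o <- order(peaks$chrom, peaks$start)
  p <- peaks[o, ]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%d\t%d",
                   p$chrom, p$start, p$end, p$peak_id, p$motif_score,
                   p$strand, p$gene_id, p$region, p$motif_score,
                   p$n_techniques)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  cols <- c("chrom", "start", "end", "peak_id", "score", "strand",
            "gene_id", "region", "motif_score", "n_techniques")
  empty <- as.data.frame(stats::setNames(
    list(character(), integer(), integer(), character(), integer(),
         character(), character(), character(), integer(), integer()), cols))
  txt <- readLines(path)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (length(txt) == 0L) return(empty[, setdiff(cols, "score")])
  d <- utils::read.delim(text = txt, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  d$score <- NULL
  d
}

#' Read an ENCODE narrowPeak file
#'
#' @param path Path to a 10-column narrowPeak file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`, `signal`, `pvalue`, `qvalue`, `summit`
#'   (absolute genomic position of the summit; `NA` when the file stores
#'   -1).
#' @export
read_narrowpeak <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit")
  if (length(txt) == 0L)
    return(as.data.frame(stats::setNames(
      list(character(), integer(), integer(), character(), numeric(),
           character(), numeric(), numeric(), numeric(), numeric()), cols)))
  nf <- lengths(strsplit(txt, "\t", fixed = TRUE))
  if (any(nf != 10L))
    stop("narrowPeak requires 10 columns; line ", which(nf != 10L)[1L],
         " has ", nf[nf != 10L][1L])
  d <- utils::read.delim(text = txt, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  d$summit <- ifelse(d$summit < 0, NA_real_, d$start + d$summit)
  d
}
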