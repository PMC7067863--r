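#' Gene model objects
#'
#' A `gene_model` describes one protein-coding gene in genomic coordinates:
#' its exons, CDS and UTR intervals. All intervals are 0-based half-open
#' (`[start, end)`), the convention used throughout the package; GTF input
#' and output are converted at the file boundary.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon `start`/`end`
#'   (0-based half-open). Must be sorted and pairwise non-overlapping.
#' @param cds,utr5,utr3 Interval sets in the same format (possibly empty);
#'   must be contained in the exon union.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       cds = NULL, utr5 = NULL, utr3 = NULL) {
  exons <- as_intervals(exons)
  if (nrow(exons) == 0L)
    stop("gene '", gene_id, "' has zero exons")
  if (any(exons[, "start"] >= exons[, "end"]))
    stop("gene '", gene_id, "': interval start must be < end")
  o <- order(exons[, "start"])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("gene '", gene_id, "': exons overlap")
  cds  <- as_intervals(cds)
  utr5 <- as_intervals(utr5)
  utr3 <- as_intervals(utr3)
  for (nm in c("cds", "utr5", "utr3")) {
    iv <- get(nm)
    if (nrow(iv) && !intervals_within(iv, exons))
      stop("gene '", gene_id, "': ", nm, " intervals not contained in exons")
  }
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  structure(list(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
    span = c(start = min(exons[, "start"]), end = max(exons[, "end"]))
  ), class = "gene_model")
}

as_intervals <- function(x) {
  if (is.null(x))
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  x <- as.matrix(x)
  if (nrow(x) > 0 && ncol(x) < 2L) stop("intervals need start and end columns")
  x <- matrix(as.integer(x[, 1:2]), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  x[order(x[, 1L]), , drop = FALSE]
}

# TRUE iff every interval of x lies within the union of intervals of set
intervals_within <- function(x, set) {
  if (nrow(x) == 0L) return(TRUE)
  qr <- IRanges::IRanges(x[, "start"] + 1L, x[, "end"])
  sr <- IRanges::IRanges(set[, "start"] + 1L, set[, "end"])
  all(IRanges::countOverlaps(qr, IRanges::reduce(sr), type = "within") > 0L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, sprintf("(%s:%d-%d:%s)", x$chrom,
      x$span["start"], x$span["end"], x$strand), "\n")
  cat("  exons:", nrow(x$exons),
      " cds:", nrow(x$cds),
      " utr5:", nrow(x$utr5),
      " utr3:", nrow(x$utr3), "\n")
  invisible(x)
}

# total exonic length in bp
exonic_length <- function(gene) sum(gene$exons[, "end"] - gene$exons[, "start"])

# all exonic genomic positions (0-based), ascending
exonic_positions <- function(gene) {
  unlist(lapply(seq_len(nrow(gene$exons)), function(i)
    seq.int(gene$exons[i, "start"], gene$exons[i, "end"] - 1L)),
    use.names = FALSE)
}

intervals_to_granges <- function(chrom, iv, strand = "*") {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(iv[, "start"] + 1L, iv[, "end"]), strand = strand)
}

#' Convert gene models to a GRanges of gene spans
#' @param genes List of [gene_model] objects.
#' @return `GRanges` with one range per gene (genomic extent), `gene_id`
#'   metadata column.
#' @export
genes_to_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges::IRanges(
      vapply(genes, function(g) g$span[["start"]], 0) + 1L,
      vapply(genes, function(g) g$span[["end"]], 0)),
    strand = vapply(genes, `[[`, "", "strand"))
  gr$gene_id <- vapply(genes, `[[`, "", "gene_id")
  gr
}

#' Read protein-coding gene models from a GTF file
#'
#' Parses a Gencode-style GTF, keeps genes with `gene_type` (or
#' `gene_biotype`) equal to `"protein_coding"`, and collapses each gene's
#' transcripts into a single model: the union of its exons, CDS and UTR
#' intervals. GTF 1-based closed coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return List of [gene_model] objects, named by `gene_id`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  gtype <- if ("gene_type" %in% names(meta)) meta$gene_type
           else if ("gene_biotype" %in% names(meta)) meta$gene_biotype
           else stop("GTF lacks gene_type/gene_biotype attribute")
  gr <- gr[!is.na(gtype) & gtype == "protein_coding"]
  if (length(gr) == 0L) return(list())
  ids <- unique(S4Vectors::mcols(gr)$gene_id)
  genes <- lapply(ids, function(id) {
    g <- gr[S4Vectors::mcols(gr)$gene_id == id]
    typ <- as.character(S4Vectors::mcols(g)$type)
    take <- function(what) {
      sub <- IRanges::reduce(g[typ %in% what])
      cbind(start = GenomicRanges::start(sub) - 1L,
            end = GenomicRanges::end(sub))
    }
    ex <- take("exon")
    if (nrow(ex) == 0L) stop("gene '", id, "' has zero exons")
    utr <- take("UTR")
    u5 <- take(c("five_prime_utr", "5UTR"))
    u3 <- take(c("three_prime_utr", "3UTR"))
    cds <- take("CDS")
    strand <- as.character(GenomicRanges::strand(g))[1L]
    if (nrow(utr) && !nrow(u5) && !nrow(u3) && nrow(cds)) {
      # plain "UTR" features: split by position relative to the CDS
      cs <- min(cds[, "start"]); ce <- max(cds[, "end"])
      left <- utr[utr[, "end"] <= cs, , drop = FALSE]
      right <- utr[utr[, "start"] >= ce, , drop = FALSE]
      if (strand == "+") { u5 <- left; u3 <- right }
      else { u5 <- right; u3 <- left }
    }
    gene_model(id, as.character(GenomicRanges::seqnames(g))[1L], strand,
               ex, cds = cds, utr5 = u5, utr3 = u3)
  })
  names(genes) <- ids
  genes
}

#' Write gene models to a GTF file
#'
#' Emits gene, exon, CDS and UTR features in 1-based closed GTF coordinates.
#' Reading the file back with [read_gene_models()] reproduces the input.
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  fmt <- function(g, feat, iv) {
    if (nrow(iv) == 0L) return(character())
    sprintf("%s\tmeripeaks\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_type \"protein_coding\";",
            g$chrom, feat, iv[, "start"] + 1L, iv[, "end"], g$strand, g$gene_id)
  }
  out <- unlist(lapply(genes, function(g) c(
    fmt(g, "gene", matrix(g$span, 1L, dimnames = list(NULL, c("start", "end")))),
    fmt(g, "exon", g$exons),
    fmt(g, "CDS", g$cds),
    fmt(g, "five_prime_utr", g$utr5),
    fmt(g, "three_prime_utr", g$utr3))))
  writeLines(out, path)
  invisible(path)
}
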