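#' Simulation configuration
#'
#' Defaults describe the desk-scale study the package validates itself on:
#' 100 protein-coding genes on one synthetic chromosome, 50 spiked 150-bp
#' m6A sites on exons with 8-fold IP enrichment, two biological conditions
#' with 3 IP/Input pairs each (6 pairs), ~30x Input depth of 65-bp
#' single-end reads, two sequencing/IP-procedure batches with multiplicative
#' (log-additive) per-gene batch effects, 10 sites differentially
#' methylated between the conditions (true log2 enrichment difference 2)
#' and 10 genes differentially expressed.
#'
#' @param seed Integer seed; every output is reproducible from it.
#' @param n_genes Number of genes.
#' @param exon_count_range,exon_length_range,intron_length_range Gene
#'   geometry (bp).
#' @param n_conditions,samples_per_condition Experimental design; condition
#'   labels are `C1`, `C2`, ...
#' @param n_sites Number of spiked m6A sites.
#' @param site_width Site width in bp (default 150).
#' @param gamma IP enrichment fold inside a site (default 8).
#' @param n_diff_sites Sites whose enrichment differs between condition C1
#'   and the others.
#' @param gamma_low Enrichment of differential sites in condition C1
#'   (default 2, i.e. log2 difference 2 against `gamma` = 8).
#' @param n_diff_expr_genes,expr_fold Genes over-expressed (by
#'   `expr_fold`) in condition C2.
#' @param depth Mean Input exonic coverage (default 30).
#' @param read_length Single-end read length (default 65).
#' @param expr_sigma sdlog of the log-normal relative gene expression.
#' @param dispersion Negative-binomial dispersion of per-gene read totals.
#' @param batch_sd SD of per-gene log2 batch effects.
#' @param motifs_per_site RGACW pentamers implanted inside each site.
#' @param ip_input_ratio Background IP:Input rate proportionality.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 100L,
                       exon_count_range = c(1L, 3L),
                       exon_length_range = c(500L, 1200L),
                       intron_length_range = c(200L, 600L),
                       n_conditions = 2L, samples_per_condition = 3L,
                       n_sites = 50L, site_width = 150L,
                       gamma = 8, n_diff_sites = 10L, gamma_low = 2,
                       n_diff_expr_genes = 10L, expr_fold = 4,
                       depth = 30, read_length = 65L,
                       expr_sigma = 0.5, dispersion = 0.05,
                       batch_sd = 0.25, motifs_per_site = 3L,
                       ip_input_ratio = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$gamma > 1, cfg$n_sites >= cfg$n_diff_sites,
            cfg$depth > 0, cfg$seed == as.integer(cfg$seed))
  structure(cfg, class = "sim_config")
}

#' Simulate a transcriptome with spiked m6A sites
#'
#' Generates random gene models (exons, 5'UTR/CDS/3'UTR, both strands) laid
#' out on one synthetic chromosome, a random genome sequence with RGACW
#' motifs implanted inside the spiked sites, and the ground-truth site
#' table. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `genes` (named list of
#'   [gene_model]), `truth` (data.frame: `site_id`, `chrom`, `start`,
#'   `end`, `gene_id`, `is_differential`, one `gamma_<condition>` column
#'   per condition, `true_lfc`), and `chrom_sizes`.
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  chrom <- "chrS"
  gap <- 500L
  pos <- gap
  genes <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ne <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1L)
    elen <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]), ne,
                   replace = TRUE)
    ilen <- if (ne > 1L)
      sample(seq(cfg$intron_length_range[1], cfg$intron_length_range[2]),
             ne - 1L, replace = TRUE) else integer()
    starts <- pos + cumsum(c(0L, elen[-ne] + ilen))
    exons <- cbind(start = starts, end = starts + elen)
    strand <- sample(c("+", "-"), 1L)
    Tlen <- sum(elen)
    L5 <- max(50L, round(0.15 * Tlen))
    L3 <- max(100L, round(0.25 * Tlen))
    if (Tlen - L5 - L3 < 60L) stop("gene too short for UTR/CDS structure")
    gid <- sprintf("gene%03d", i)
    genes[[i]] <- gene_model(gid, chrom, strand, exons,
      cds = transcript_to_genomic(exons, strand, L5, Tlen - L3),
      utr5 = transcript_to_genomic(exons, strand, 0L, L5),
      utr3 = transcript_to_genomic(exons, strand, Tlen - L3, Tlen))
    pos <- max(exons[, "end"]) + gap
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  chrom_size <- pos + gap
  seq <- sample(c("A", "C", "G", "T"), chrom_size, replace = TRUE)

  # spike sites into distinct genes with a long-enough exon
  ok <- vapply(genes, function(g)
    any(g$exons[, "end"] - g$exons[, "start"] >= cfg$site_width + 10L), TRUE)
  host <- sample(names(genes)[ok], min(cfg$n_sites, sum(ok)))
  sites <- lapply(host, function(gid) {
    g <- genes[[gid]]
    wide <- which(g$exons[, "end"] - g$exons[, "start"] >= cfg$site_width + 10L)
    e <- if (length(wide) == 1L) wide else sample(wide, 1L)
    s <- unname(g$exons[e, "start"]) +
      sample.int(g$exons[e, "end"] - g$exons[e, "start"] - cfg$site_width + 1L,
                 1L) - 1L
    c(start = s, end = s + cfg$site_width)
  })
  truth <- data.frame(
    site_id = sprintf("site%03d", seq_along(host)),
    chrom = chrom,
    start = vapply(sites, `[[`, 0L, "start"),
    end = vapply(sites, `[[`, 0L, "end"),
    gene_id = host, stringsAsFactors = FALSE)
  truth$is_differential <- seq_len(nrow(truth)) <= cfg$n_diff_sites
  conds <- paste0("C", seq_len(cfg$n_conditions))
  for (cn in conds)
    truth[[paste0("gamma_", cn)]] <-
      ifelse(truth$is_differential & cn == "C1", cfg$gamma_low, cfg$gamma)
  truth$true_lfc <- log2(truth[[paste0("gamma_", conds[min(2, length(conds))])]] /
                         truth$gamma_C1)

  # implant sense-strand RGACW motifs inside each site
  if (cfg$motifs_per_site > 0L) for (i in seq_len(nrow(truth))) {
    g <- genes[[truth$gene_id[i]]]
    offs <- sample.int(cfg$site_width - 5L, cfg$motifs_per_site)
    for (o in offs) {
      p <- truth$start[i] + o  # 0-based start of the pentamer
      mot <- strsplit("GGACT", "")[[1]]
      if (g$strand == "-") mot <- rev(c(A = "T", C = "G", G = "C", T = "A")[mot])
      seq[(p + 1):(p + 5)] <- mot
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- chrom
  list(genome = genome, genes = genes, truth = truth,
       chrom_sizes = stats::setNames(chrom_size, chrom))
}

# map transcript-coordinate interval [t_start, t_end) (5'->3') to genomic
# interval set, given the gene's exons and strand
transcript_to_genomic <- function(exons, strand, t_start, t_end) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, "start"], exons[i, "end"] - 1L)), use.names = FALSE)
  if (strand == "-") pos <- rev(pos)
  sel <- sort(pos[(t_start + 1L):t_end])
  runs <- cumsum(c(1L, diff(sel) != 1L))
  t(vapply(split(sel, runs), function(v) c(start = v[1L], end = v[length(v)] + 1L),
           c(start = 0L, end = 0L)))
}

#' Simulate a MeRIP-seq experiment
#'
#' Places single-end reads on the simulated transcriptome. Input reads fall
#' uniformly over each gene's exons at a rate proportional to the gene's
#' expression; IP reads follow the same background multiplied by the site
#' enrichment fold inside spiked sites (a step function). Per-gene read
#' totals are negative-binomial; per-gene multiplicative batch effects are
#' applied according to each sample's sequencing batch, library batch and
#' IP procedure. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param tx Output of [simulate_transcriptome()].
#' @return list with `tracks` (list of `coverage_track`, reads attached),
#'   `metadata` (sample table) and `truth` (from `tx`).
#' @export
simulate_experiment <- function(cfg, tx) {
  set.seed(cfg$seed + 1L)
  conds <- paste0("C", seq_len(cfg$n_conditions))
  md <- do.call(rbind, lapply(conds, function(cn) {
    do.call(rbind, lapply(seq_len(cfg$samples_per_condition), function(r) {
      data.frame(
        pair_id = sprintf("%s_r%d", cn, r),
        condition = cn,
        sequencing_batch = if (r <= ceiling(cfg$samples_per_condition / 2))
          "S1" else "S2",
        library_batch = if ((r + match(cn, conds)) %% 2L == 0L) "L1" else "L2",
        ip_procedure = if (r %% 2L == 1L) "P1" else "P2",
        stringsAsFactors = FALSE)
    }))
  }))
  md <- md[rep(seq_len(nrow(md)), each = 2L), ]
  md$role <- rep(c("IP", "Input"), nrow(md) / 2L)
  md$sample_id <- paste0(md$pair_id, "_", md$role)
  rownames(md) <- NULL

  genes <- tx$genes
  exlen <- vapply(genes, exonic_length, 0L)
  rel <- stats::rlnorm(length(genes), meanlog = 0, sdlog = cfg$expr_sigma)
  names(rel) <- names(genes)
  de_genes <- names(genes)[seq_len(min(cfg$n_diff_expr_genes, length(genes)))]
  # per-gene log2 batch effects for the non-reference level of each factor
  beff <- list(
    sequencing_batch = stats::rnorm(length(genes), 0, cfg$batch_sd),
    library_batch = stats::rnorm(length(genes), 0, cfg$batch_sd),
    ip_procedure = stats::rnorm(length(genes), 0, cfg$batch_sd))
  expos <- lapply(genes, exonic_positions)
  in_site <- lapply(names(genes), function(gid) {
    p <- expos[[gid]]
    hit <- tx$truth[tx$truth$gene_id == gid, , drop = FALSE]
    f <- rep(FALSE, length(p))
    for (j in seq_len(nrow(hit)))
      f <- f | (p >= hit$start[j] & p < hit$end[j])
    f
  })
  names(in_site) <- names(genes)
  gamma_of <- function(gid, cn) {
    hit <- tx$truth[tx$truth$gene_id == gid, , drop = FALSE]
    if (nrow(hit) == 0L) return(1)
    hit[[paste0("gamma_", cn)]][1L]
  }
  chrom <- names(tx$chrom_sizes)[1L]
  clen <- tx$chrom_sizes[[1L]]

  tracks <- lapply(seq_len(nrow(md)), function(si) {
    s <- md[si, ]
    starts <- integer(0)
    for (gid in names(genes)) {
      bmult <- 2^((s$sequencing_batch == "S2") * beff$sequencing_batch[[match(gid, names(genes))]] +
                  (s$library_batch == "L2") * beff$library_batch[[match(gid, names(genes))]] +
                  (s$role == "IP") * (s$ip_procedure == "P2") *
                    beff$ip_procedure[[match(gid, names(genes))]])
      emult <- if (gid %in% de_genes && s$condition != "C1") cfg$expr_fold else 1
      base <- cfg$depth * exlen[[gid]] / cfg$read_length * rel[[gid]] *
        emult * bmult
      p <- expos[[gid]]
      if (s$role == "Input") {
        n <- stats::rnbinom(1L, mu = base, size = 1 / cfg$dispersion)
        if (n > 0L) starts <- c(starts, sample(p, n, replace = TRUE))
      } else {
        gam <- gamma_of(gid, s$condition)
        w <- 1 + (gam - 1) * in_site[[gid]]
        n <- stats::rnbinom(1L, mu = base * mean(w) * cfg$ip_input_ratio,
                            size = 1 / cfg$dispersion)
        if (n > 0L)
          starts <- c(starts, sample(p, n, replace = TRUE, prob = w))
      }
    }
    reads <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(starts + 1L,
                       width = pmin(cfg$read_length, clen - starts)))
    track_from_reads(reads, s$sample_id, s$role,
                     seqlengths = tx$chrom_sizes)
  })
  names(tracks) <- md$sample_id
  md$library_size <- vapply(tracks, `[[`, 0, "library_size")
  list(tracks = tracks, metadata = md, truth = tx$truth)
}

#' Write / read a ground-truth site table
#' @param truth Truth data.frame from [simulate_transcriptome()].
#' @param path TSV path.
#' @return `path` invisibly; `read_truth` returns the data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Score peak calls against the simulated truth
#'
#' Overlap-based (>= 1 bp): sensitivity is the fraction of true sites
#' overlapped by at least one call, precision the fraction of calls
#' overlapping at least one true site.
#'
#' @param peaks Peaks data.frame (`chrom`, `start`, `end`).
#' @param truth Truth data.frame.
#' @return list with `sensitivity`, `precision`, `fdr`, `n_calls`,
#'   `n_sites`.
#' @export
score_against_truth <- function(peaks, truth) {
  if (nrow(peaks) == 0L)
    return(list(sensitivity = 0, precision = NA_real_, fdr = NA_real_,
                n_calls = 0L, n_sites = nrow(truth)))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
           IRanges::IRanges(peaks$start + 1L, peaks$end))
  tgr <- GenomicRanges::GRanges(truth$chrom,
           IRanges::IRanges(truth$start + 1L, truth$end))
  sens <- mean(GenomicRanges::countOverlaps(tgr, pgr) > 0L)
  prec <- mean(GenomicRanges::countOverlaps(pgr, tgr) > 0L)
  list(sensitivity = sens, precision = prec, fdr = 1 - prec,
       n_calls = nrow(peaks), n_sites = nrow(truth))
}

#' Score differential calls against known true features
#'
#' Id-based: power is the fraction of truly differential features called
#' significant; the empirical FDR is the fraction of significant calls
#' that are not truly differential.
#'
#' @param results Table from [call_significant()].
#' @param true_ids Character vector of truly differential feature ids.
#' @return list with `power`, `fdr`, `n_significant`.
#' @export
score_differential_calls <- function(results, true_ids) {
  sig <- results$feature_id[results$significant]
  power <- if (length(true_ids)) mean(true_ids %in% sig) else NA_real_
  fdr <- if (length(sig)) mean(!sig %in% true_ids) else 0
  list(power = power, fdr = fdr, n_significant = length(sig))
}

#' Simulate a peak-count matrix for the differential stage
#'
#' Negative-binomial counts for `n_features` peaks over a two-condition
#' design with `n_per_group` samples each, balanced sequencing/library/IP
#' batches carrying per-feature multiplicative effects, and `n_true`
#' features with a real log2 fold change of `lfc` in condition B.
#'
#' @param n_features,n_true,lfc,n_per_group Design of the simulation.
#' @param dispersion NB dispersion (default 0.1).
#' @param batch_sd SD of per-feature log2 batch effects (default 0.25).
#' @param base_meanlog,base_sdlog Log-normal distribution of baseline
#'   means.
#' @param seed Integer seed.
#' @return list with `counts`, `metadata`, `true_ids`.
#' @export
simulate_peak_counts <- function(n_features = 2000L, n_true = 20L, lfc = 2,
                                 n_per_group = 6L, dispersion = 0.1,
                                 batch_sd = 0.25, base_meanlog = log(100),
                                 base_sdlog = 1, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  i <- seq_len(n)
  md <- data.frame(
    sample_id = sprintf("s%02d", i),
    condition = rep(c("A", "B"), each = n_per_group),
    sequencing_batch = c("S1", "S2")[i %% 2L + 1L],
    library_batch = c("L1", "L2")[(ceiling(i / 2) %% 2L) + 1L],
    ip_procedure = rep(rep(c("P1", "P2"),
      each = ceiling(n_per_group / 2)), 2L)[i],
    stringsAsFactors = FALSE)
  base <- stats::rlnorm(n_features, base_meanlog, base_sdlog)
  true_ids <- sprintf("peak%04d", seq_len(n_true))
  ids <- sprintf("peak%04d", seq_len(n_features))
  b_seq <- stats::rnorm(n_features, 0, batch_sd)
  b_lib <- stats::rnorm(n_features, 0, batch_sd)
  b_ip <- stats::rnorm(n_features, 0, batch_sd)
  counts <- vapply(seq_len(n), function(j) {
    lmu <- log2(base) +
      (md$condition[j] == "B") * c(rep(lfc, n_true),
                                   rep(0, n_features - n_true)) +
      (md$sequencing_batch[j] == "S2") * b_seq +
      (md$library_batch[j] == "L2") * b_lib +
      (md$ip_procedure[j] == "P2") * b_ip
    stats::rnbinom(n_features, mu = 2^lmu, size = 1 / dispersion)
  }, numeric(n_features))
  dimnames(counts) <- list(ids, md$sample_id)
  list(counts = counts, metadata = md, true_ids = true_ids)
}

#' Null window counts at realistic sequencing depth
#'
#' Draws IP and Input window counts for one library pair from the same
#' multinomial: window probabilities are log-normal, scaled so the mean
#' window count is `mean_count`, with the remainder of the `lib_size`
#' reads falling outside the window set (windows cover a small fraction of
#' a real transcriptome-scale library). Used to check detector calibration
#' under no enrichment.
#'
#' @param n_windows Number of windows.
#' @param mean_count Mean read count per window.
#' @param lib_size Total mapped reads per library (default 3e7, a typical
#'   MeRIP-seq depth).
#' @param n_genes Windows are grouped into this many pseudo-genes.
#' @param seed Integer seed.
#' @return A `window_counts` object with one IP and one Input column.
#' @export
simulate_null_window_counts <- function(n_windows = 3000L, mean_count = 60,
                                        lib_size = 3e7, n_genes = 100L,
                                        seed = 1L) {
  set.seed(seed)
  rel <- stats::rlnorm(n_windows, 0, 0.5)
  p <- rel / sum(rel) * (n_windows * mean_count / lib_size)
  probs <- c(p, 1 - sum(p))
  cnt <- vapply(1:2, function(i)
    stats::rmultinom(1L, lib_size, probs)[seq_len(n_windows), 1L],
    integer(n_windows))
  gene <- sprintf("g%03d", rep(seq_len(n_genes), length.out = n_windows))
  windows <- data.frame(
    window_id = sprintf("w%05d", seq_len(n_windows)),
    gene_id = gene, chrom = "chrN", strand = "+",
    start = seq_len(n_windows) * 50L,
    end = seq_len(n_windows) * 50L + 100L, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("null_IP", "null_Input"),
                        role = c("IP", "Input"), stringsAsFactors = FALSE)
  dimnames(cnt) <- list(windows$window_id, samples$sample_id)
  structure(list(windows = windows, samples = samples, counts = cnt,
                 library_sizes = stats::setNames(rep(lib_size, 2L),
                                                 samples$sample_id)),
            class = "window_counts")
}
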