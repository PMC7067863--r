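#' Pipeline configuration
#'
#' All tunable thresholds of the peak-calling and differential stages, with
#' defaults equal to the published values: 100-bp windows stepping 50 bp,
#' IP coverage > 10 reads, Fisher adjusted p < 0.001, RPMF > 10, POM >= 4,
#' POI > 2, local-Poisson q < 0.05, detection in >= 3 IP samples, >= 3 of 4
#' techniques, 150-bp peaks, 65-bp reads, CPM >= 5 in >= 3 samples,
#' |log2FC| > 1 at adjusted p < 0.05, motif weights GAACA/GGACA/GAACT/GGACT
#' = 2/3/5/8.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `merip_config`.
#' @export
merip_config <- function(...) {
  cfg <- list(
    window_size = 100L,
    step = 50L,
    min_ip_reads = 10L,
    min_ip_cov_mode = "per-sample",
    fisher_alpha = 0.001,
    rpmf_threshold = 10,
    rpmf_mode = "difference",
    pom_min = 4,
    poi_min = 2,
    poisson_qmax = 0.05,
    min_samples = 3L,
    min_techniques = 3L,
    peak_width = 150L,
    read_length = 65L,
    min_cpm = 5,
    min_cpm_samples = 3L,
    lfc = 1,
    alpha = 0.05,
    motif_weights = c(GAACA = 2L, GGACA = 3L, GAACT = 5L, GGACT = 8L))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "merip_config")
}

validate_config <- function(cfg) {
  pos <- c("window_size", "step", "min_samples", "min_techniques",
           "peak_width", "read_length")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  nonneg <- c("min_ip_reads", "rpmf_threshold", "pom_min", "poi_min",
              "min_cpm", "min_cpm_samples", "lfc")
  for (f in nonneg) if (cfg[[f]] < 0) stop(f, " must be non-negative")
  for (f in c("fisher_alpha", "poisson_qmax", "alpha"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stop(f, " must be in (0, 1]")
  invisible(cfg)
}

#' Run all four detectors over every IP/Input pair
#'
#' For each pair the window grid is coverage-filtered for that IP sample
#' (windows with more than `min_ip_reads` IP reads are kept) and the
#' Fisher, RPMF, POI and local-Poisson techniques are applied.
#'
#' @param tracks Named list of `coverage_track` objects.
#' @param genes Named list of [gene_model] objects.
#' @param windows Window grid from [generate_windows()].
#' @param metadata Sample metadata with `sample_id`, `role`, `pair_id`.
#' @param config A [merip_config()].
#' @param narrowpeaks Optional named list (by IP sample id) of narrowPeak
#'   tables used in place of the local-Poisson test.
#' @return Named list (fisher, rpmf, poi, macs2like) of detection-result
#'   data.frames stacked over IP samples.
#' @export
detect_all <- function(tracks, genes, windows, metadata,
                       config = merip_config(), narrowpeaks = NULL) {
  m <- count_reads_in_windows(tracks, windows, samples = metadata,
                              read_length = config$read_length)
  m$library_sizes <- stats::setNames(metadata$library_size,
                                     metadata$sample_id)
  ips <- metadata[metadata$role == "IP", ]
  res <- list(fisher = list(), rpmf = list(), poi = list(),
              macs2like = list())
  for (i in seq_len(nrow(ips))) {
    ip <- ips$sample_id[i]
    input <- metadata$sample_id[metadata$role == "Input" &
                                metadata$pair_id == ips$pair_id[i]]
    if (length(input) != 1L)
      stop("IP sample ", ip, " has no unique paired Input")
    mf <- filter_min_ip_coverage(m, ip, config$min_ip_reads,
                                 mode = config$min_ip_cov_mode)
    if (nrow(mf$windows) == 0L) next
    res$fisher[[ip]] <- fisher_detect(mf, ip, input, config$fisher_alpha)
    res$rpmf[[ip]] <- rpmf_detect(mf, ip, input, config$rpmf_threshold,
                                  mode = config$rpmf_mode)
    res$poi[[ip]] <- poi_detect(tracks, genes, mf$windows, ip, input,
                                config$pom_min, config$poi_min)
    res$macs2like[[ip]] <- if (!is.null(narrowpeaks) && ip %in% names(narrowpeaks))
      narrowpeak_to_results(narrowpeaks[[ip]], mf$windows, ip)
    else
      poisson_enrich_detect(mf, ip, input, config$poisson_qmax)
  }
  lapply(res, function(r) do.call(rbind, c(unname(r),
                                           list(make.row.names = FALSE))))
}

#' Consensus m6A peak calling
#'
#' The full peak-calling chain: window grid, per-pair detection with the
#' four techniques, occurrence filtering across IP samples, per-technique
#' merging and recentering on maximum median IP coverage, technique
#' consensus, 150-bp recentering, region annotation and (when a genome is
#' given) motif scoring.
#'
#' @inheritParams detect_all
#' @param genome Optional named `DNAStringSet` for motif scoring.
#' @param chrom_sizes Optional named chromosome lengths for peak clipping.
#' @return A `merip_peaks` data.frame with a `funnel` attribute recording
#'   row counts after each stage.
#' @export
call_peaks <- function(tracks, genes, metadata, config = merip_config(),
                       genome = NULL, chrom_sizes = NULL,
                       narrowpeaks = NULL) {
  windows <- generate_windows(genes, config$window_size, config$step)
  det <- detect_all(tracks, genes, windows, metadata, config, narrowpeaks)
  ip_tracks <- tracks[vapply(tracks, `[[`, "", "role") == "IP"]
  med_cov <- median_ip_coverage(ip_tracks)
  funnel <- list(windows = nrow(windows))
  sites <- list()
  for (tech in names(det)) {
    r <- det[[tech]]
    if (is.null(r) || nrow(r) == 0L) {
      sites[[tech]] <- empty_sites()
      funnel[[paste0(tech, "_sites")]] <- 0L
      next
    }
    kept <- occurrence_filter(r, config$min_samples)
    sites[[tech]] <- merge_and_recenter(kept, windows, med_cov,
                                        config$peak_width)
    funnel[[paste0(tech, "_sites")]] <- nrow(sites[[tech]])
  }
  peaks <- combine_techniques(sites, med_cov, genes,
                              config$min_techniques, config$peak_width,
                              chrom_sizes)
  funnel$consensus_peaks <- nrow(peaks)
  if (nrow(peaks)) {
    peaks <- annotate_region(peaks, genes)
    if (!is.null(genome)) peaks <- motif_score(peaks, genome)
    else { peaks$motif_score <- 0L; peaks$rgacw_present <- NA }
  } else {
    peaks$region <- character()
    peaks$motif_score <- integer()
    peaks$rgacw_present <- logical()
  }
  attr(peaks, "funnel") <- funnel
  attr(peaks, "sites") <- sites
  peaks
}

#' End-to-end analysis: peaks plus differential statistics
#'
#' Runs [call_peaks()], counts IP reads over the consensus peaks and Input
#' reads over the genes, applies the CPM filters, TMM normalization, the
#' precision-weighted transform and the moderated linear model
#' `~ condition + sequencing_batch + library_batch + ip_procedure` for the
#' requested condition contrast, and classifies differentially methylated
#' peaks against differential expression.
#'
#' @inheritParams call_peaks
#' @param contrast Character vector `c(test, reference)` of condition
#'   levels (default the two conditions present, second vs first).
#' @return An object of class `merip_result`: list with `peaks`,
#'   `diff_meth`, `diff_expr`, `classification`, `config`, `contrast`.
#' @export
run_pipeline <- function(tracks, genes, metadata, config = merip_config(),
                         genome = NULL, chrom_sizes = NULL,
                         contrast = NULL) {
  peaks <- call_peaks(tracks, genes, metadata, config, genome, chrom_sizes)
  conds <- unique(metadata$condition)
  if (is.null(contrast)) contrast <- c(conds[2L], conds[1L])
  ip_md <- metadata[metadata$role == "IP", ]
  in_md <- metadata[metadata$role == "Input", ]
  ip_tracks <- tracks[ip_md$sample_id]
  in_tracks <- tracks[in_md$sample_id]

  diff_meth <- NULL
  if (nrow(peaks) > 0L) {
    pk_feat <- data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
                          start = peaks$start, end = peaks$end,
                          stringsAsFactors = FALSE)
    pk_counts <- count_reads_in_features(ip_tracks, pk_feat, samples = ip_md,
                                         read_length = config$read_length)
    diff_meth <- differential_analysis(
      pk_counts$counts, ip_md, contrast, config,
      ip_procedure_rule = TRUE)
  }
  gene_counts <- count_reads_in_features(in_tracks, genes_to_features(genes),
                                         samples = in_md,
                                         read_length = config$read_length)
  diff_expr <- differential_analysis(gene_counts$counts, in_md, contrast,
                                     config, ip_procedure_rule = FALSE)
  classification <- NULL
  if (!is.null(diff_meth) && nrow(diff_meth)) {
    map <- stats::setNames(peaks$gene_id, peaks$peak_id)
    classification <- classify_peaks_vs_expression(diff_meth, diff_expr, map)
  }
  structure(list(peaks = peaks, diff_meth = diff_meth,
                 diff_expr = diff_expr, classification = classification,
                 config = config, contrast = contrast),
            class = "merip_result")
}

#' Differential analysis of one count matrix
#'
#' CPM filtering, TMM, precision-weighted transform, moderated fit for the
#' condition contrast with batch covariates, BH adjustment and the
#' published significance cut-offs.
#'
#' @param counts Feature x sample count matrix.
#' @param metadata Sample metadata aligned with the columns (`condition`,
#'   `sequencing_batch`, `library_batch`, `ip_procedure`, `library_size`,
#'   `role`).
#' @param contrast `c(test, reference)` condition levels.
#' @param config A [merip_config()].
#' @param ip_procedure_rule Apply the peak-matrix CPM rule (see
#'   [filter_by_cpm()]).
#' @return Result table from [call_significant()] (or an empty table when
#'   nothing survives filtering).
#' @export
differential_analysis <- function(counts, metadata, contrast,
                                  config = merip_config(),
                                  ip_procedure_rule = FALSE) {
  sel <- metadata$condition %in% contrast
  md <- metadata[sel, ]
  counts <- counts[, md$sample_id, drop = FALSE]
  lib <- md$library_size
  counts <- filter_by_cpm(counts, lib, config$min_cpm,
                          config$min_cpm_samples, metadata = md,
                          ip_procedure_rule = ip_procedure_rule)
  if (nrow(counts) == 0L)
    return(data.frame(feature_id = character(), logFC = numeric(),
                      t = numeric(), p = numeric(), df_total = numeric(),
                      p_adj = numeric(), significant = logical()))
  cond <- factor(md$condition, levels = c(contrast[2L], contrast[1L]))
  terms <- list(condition = cond)
  for (f in c("sequencing_batch", "library_batch", "ip_procedure"))
    if (length(unique(md[[f]])) > 1L) terms[[f]] <- factor(md[[f]])
  design <- stats::model.matrix(~ ., data = as.data.frame(terms))
  factors <- tmm_factors(counts, lib)
  v <- voomlike_transform(counts, design, lib, factors)
  fit <- fit_moderated_lm(v$y, design, weights = v$weights, coef = 2L)
  call_significant(fit, config$lfc, config$alpha)
}

#' @export
print.merip_result <- function(x, ...) {
  cat("merip_result (contrast", x$contrast[1L], "vs", x$contrast[2L], ")\n")
  cat("  consensus peaks:", nrow(x$peaks), "\n")
  if (!is.null(x$diff_meth))
    cat("  peaks tested / significant:", nrow(x$diff_meth), "/",
        sum(x$diff_meth$significant), "\n")
  cat("  genes tested / significant:", nrow(x$diff_expr), "/",
      sum(x$diff_expr$significant), "\n")
  if (!is.null(x$classification)) {
    s <- attr(x$classification, "summary")
    cat("  peak classes (%):",
        paste(sprintf("%s %.1f", names(s), as.numeric(s)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.merip_result <- function(object, ...) {
  f <- attr(object$peaks, "funnel")
  cat("Stage funnel:\n")
  for (nm in names(f)) cat(sprintf("  %-18s %d\n", nm, f[[nm]]))
  print(object)
  invisible(object)
}
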