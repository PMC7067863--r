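#' Window-level m6A detection techniques
#'
#' Four per-sample techniques assess 100-bp windows of one IP/Input library
#' pair for methylation enrichment. Each returns a data.frame (one row per
#' tested window) with the technique's statistic and a `pass` flag applying
#' the published threshold with strict inequalities.
#'
#' @name detectors
NULL

detection_result <- function(window_id, technique, ip_sample_id, statistic,
                             pass, extra = NULL) {
  d <- data.frame(window_id = window_id, technique = technique,
                  ip_sample_id = ip_sample_id, statistic = statistic,
                  pass = pass, stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

#' Fisher exact enrichment test per window
#'
#' For each window the 2x2 table contrasts the window's reads against the
#' rest of the library, IP versus Input: `[[ip_win, ip_lib - ip_win],
#' [in_win, in_lib - in_win]]`, where `lib` is the sample's total library
#' size. The one-sided (enrichment) hypergeometric
#' p-value is computed per window, BH-adjusted across all tested windows of
#' the sample, and a window passes when the adjusted p-value is below
#' `alpha`.
#'
#' @param m A `window_counts` object, already coverage-filtered for the IP
#'   sample.
#' @param ip,input Sample ids of the IP and Input library.
#' @param alpha Adjusted-p threshold (default 0.001).
#' @param alternative `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"`.
#' @return data.frame of detection results; `statistic` is the BH-adjusted
#'   p-value, `p` the raw p-value.
#' @export
fisher_detect <- function(m, ip, input, alpha = 0.001,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- m$counts[, ip]; b <- m$counts[, input]
  ip_lib <- m$library_sizes[[ip]]; in_lib <- m$library_sizes[[input]]
  if (ip_lib <= 0 || in_lib <= 0) stop("zero library size")
  p <- fisher_p(a, ip_lib, b, in_lib, alternative)
  padj <- stats::p.adjust(p, method = "BH")
  detection_result(m$windows$window_id, "fisher", ip, padj, padj < alpha,
                   extra = data.frame(p = p))
}

# vectorized hypergeometric p for 2x2 tables [[a, A-a], [b, B-b]]
fisher_p <- function(a, A, b, B, alternative = "greater") {
  k <- a + b
  if (alternative == "greater")
    return(stats::phyper(a - 1, A, B, k, lower.tail = FALSE))
  # two-sided: sum of table probabilities <= observed (fisher.test rule)
  vapply(seq_along(a), function(i) {
    xs <- max(0, k[i] - B):min(A, k[i])
    d <- stats::dhyper(xs, A, B, k[i])
    sum(d[d <= stats::dhyper(a[i], A, B, k[i]) * (1 + 1e-7)])
  }, 0)
}

#' Reads-per-million fold (RPMF) detection
#'
#' RPM is `count / library_size * 1e6` per window and dataset; the RPMF
#' statistic is `RPM_IP - RPM_Input` (a difference, despite the name). A
#' window passes when RPMF exceeds `threshold`. `mode = "ratio"` offers the
#' alternative reading RPM_IP / RPM_Input.
#'
#' @inheritParams fisher_detect
#' @param threshold Pass threshold, strict (default 10).
#' @param mode `"difference"` (default) or `"ratio"`.
#' @return data.frame of detection results; `statistic` is the RPMF.
#' @export
rpmf_detect <- function(m, ip, input, threshold = 10,
                        mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (any(m$library_sizes[c(ip, input)] <= 0))
    stop("library sizes must be > 0")
  rpm_ip <- m$counts[, ip] / m$library_sizes[[ip]] * 1e6
  rpm_in <- m$counts[, input] / m$library_sizes[[input]] * 1e6
  stat <- if (mode == "difference") rpm_ip - rpm_in else rpm_ip / rpm_in
  detection_result(m$windows$window_id, "rpmf", ip, stat, stat > threshold)
}

#' Peak-over-median / peak-over-input (POM/POI) detection
#'
#' Works on per-base coverage with zero-depth positions removed. POM is the
#' median depth over the window's non-zero positions divided by the median
#' depth over the gene's non-zero exonic positions. Windows with IP POM
#' below `pom_min` are removed; POI = POM_IP / POM_Input, and a window
#' passes when POI exceeds `poi_min`. An undefined or zero Input POM gives
#' POI = Inf (pass, flagged `input_empty`). Windows whose gene has no
#' non-zero exonic IP coverage are skipped with a warning.
#'
#' @param tracks Named list of `coverage_track` objects (must include `ip`
#'   and `input`).
#' @param genes List of [gene_model] objects named by gene id.
#' @param windows Window data.frame (usually the coverage-filtered set).
#' @param ip,input Sample ids.
#' @param pom_min Minimum IP POM; windows below are removed (default 4).
#' @param poi_min POI pass threshold, strict (default 2).
#' @return data.frame of detection results with `statistic` = POI and
#'   extra columns `pom_ip`, `pom_input`, `input_empty`.
#' @export
poi_detect <- function(tracks, genes, windows, ip, input,
                       pom_min = 4, poi_min = 2) {
  names(tracks) <- vapply(tracks, `[[`, "", "sample_id")
  tr_ip <- tracks[[ip]]; tr_in <- tracks[[input]]
  out <- vector("list", length(unique(windows$gene_id)))
  i <- 0L
  skipped <- 0L
  for (gid in unique(windows$gene_id)) {
    g <- genes[[gid]]
    wdx <- which(windows$gene_id == gid)
    gmed_ip <- nonzero_median_depth(tr_ip, g$chrom, exonic_positions(g))
    if (is.na(gmed_ip)) { skipped <- skipped + length(wdx); next }
    gmed_in <- nonzero_median_depth(tr_in, g$chrom, exonic_positions(g))
    wmed_ip <- window_nonzero_medians(tr_ip, windows[wdx, , drop = FALSE])
    wmed_in <- window_nonzero_medians(tr_in, windows[wdx, , drop = FALSE])
    pom_ip <- wmed_ip / gmed_ip
    pom_in <- if (is.na(gmed_in)) rep(NA_real_, length(wdx))
              else wmed_in / gmed_in
    keep <- !is.na(pom_ip) & pom_ip >= pom_min
    input_empty <- is.na(pom_in) | pom_in == 0
    poi <- ifelse(input_empty, Inf, pom_ip / pom_in)
    pass <- keep & poi > poi_min
    i <- i + 1L
    out[[i]] <- detection_result(
      windows$window_id[wdx], "poi", ip,
      ifelse(keep, poi, NA_real_), pass,
      extra = data.frame(pom_ip = pom_ip, pom_input = pom_in,
                         input_empty = input_empty))
  }
  if (skipped > 0L)
    warning(skipped, " windows skipped: gene has no non-zero exonic IP coverage")
  if (i == 0L) return(NULL)
  do.call(rbind, c(out[seq_len(i)], list(make.row.names = FALSE)))
}

# median of the non-zero depth values at the given 0-based positions
nonzero_median_depth <- function(track, chrom, pos0) {
  if (!chrom %in% names(track$depth)) return(NA_real_)
  d <- track$depth[[chrom]]
  pos <- pos0[pos0 < length(d)] + 1L
  if (length(pos) == 0L) return(NA_real_)
  v <- as.integer(d[pos])
  v <- v[v > 0]
  if (length(v) == 0L) return(NA_real_)
  stats::median(v)
}

window_nonzero_medians <- function(track, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    nonzero_median_depth(track, windows$chrom[i],
                         seq.int(windows$start[i], windows$end[i] - 1L))
  }, 0)
}

#' Local-Poisson enrichment detection
#'
#' A windowed enrichment test in the spirit of peak callers built on a
#' local Poisson model: the expected IP count per window is
#' `lambda = max(genome-wide rate, gene-local rate)`, where the genome-wide
#' rate is the IP total over tested windows divided by the number of
#' windows, and the gene-local rate is the gene's Input window total scaled
#' to the IP library, divided by the gene's window count. The upper-tail
#' Poisson p-value P(X >= x) is BH-adjusted across windows; a window passes
#' at `q < qmax`. Externally generated peak calls (e.g. a narrowPeak file)
#' can stand in for this test via [narrowpeak_to_results()].
#'
#' @inheritParams fisher_detect
#' @param qmax Adjusted-p threshold (default 0.05).
#' @return data.frame of detection results; `statistic` is the q-value,
#'   with extra columns `p` and `lambda`.
#' @export
poisson_enrich_detect <- function(m, ip, input, qmax = 0.05) {
  x <- m$counts[, ip]; b <- m$counts[, input]
  ip_lib <- sum(x); in_lib <- sum(b)
  lambda_bg <- ip_lib / nrow(m$counts)
  scale <- if (in_lib > 0) ip_lib / in_lib else 0
  gene_tot <- tapply(b, m$windows$gene_id, sum)[m$windows$gene_id]
  gene_n <- tapply(b, m$windows$gene_id, length)[m$windows$gene_id]
  lambda_loc <- as.numeric(gene_tot) * scale / as.numeric(gene_n)
  lambda <- pmax(lambda_bg, lambda_loc)
  p <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  detection_result(m$windows$window_id, "macs2like", ip, q, q < qmax,
                   extra = data.frame(p = p, lambda = lambda))
}

#' Map externally detected regions onto the window grid
#'
#' Marks every window overlapping (by at least 1 bp) a detected region as a
#' pass, producing a detection-result table usable as the fourth technique
#' when real MACS2 narrowPeak output is available.
#'
#' @param regions data.frame from [read_narrowpeak()] (or any table with
#'   `chrom`, `start`, `end`, 0-based half-open).
#' @param windows Window data.frame.
#' @param ip_sample_id Sample id to record.
#' @return data.frame of detection results (`statistic` = number of
#'   overlapping regions).
#' @export
narrowpeak_to_results <- function(regions, windows, ip_sample_id) {
  wgr <- windows_to_granges(windows)
  rgr <- GenomicRanges::GRanges(regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end))
  n <- GenomicRanges::countOverlaps(wgr, rgr)
  detection_result(windows$window_id, "macs2like", ip_sample_id,
                   as.numeric(n), n > 0L)
}
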