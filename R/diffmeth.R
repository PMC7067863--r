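#' CPM expression filters
#'
#' Keeps features with at least `min_cpm` counts per million in at least
#' `min_samples` samples. For peak matrices a second, IP-procedure-aware
#' rule can be applied: within every combination of biological condition
#' and IP/sequencing procedure, at least `min_per_cell` samples of each
#' role present in the matrix must reach `min_cpm`, protecting the model
#' from peaks quantified in only one of the two IP procedures.
#'
#' @param counts Feature x sample count matrix.
#' @param lib_sizes Per-sample library sizes (column order of `counts`).
#' @param min_cpm CPM threshold (default 5).
#' @param min_samples Minimum samples for the first rule (default 3).
#' @param metadata Sample metadata (rows aligned with columns) with
#'   `condition`, `ip_procedure` and `role`; required when
#'   `ip_procedure_rule` is TRUE.
#' @param ip_procedure_rule Apply the second rule (default FALSE).
#' @param min_per_cell Minimum qualifying samples per condition x
#'   procedure x role cell (default 2).
#' @return The filtered count matrix.
#' @export
filter_by_cpm <- function(counts, lib_sizes, min_cpm = 5, min_samples = 3L,
                          metadata = NULL, ip_procedure_rule = FALSE,
                          min_per_cell = 2L) {
  cpm <- t(t(counts) / lib_sizes) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (ip_procedure_rule) {
    if (is.null(metadata)) stop("metadata required for ip_procedure_rule")
    cells <- split(seq_len(ncol(counts)),
                   interaction(metadata$condition, metadata$ip_procedure,
                               metadata$role, drop = TRUE))
    for (cols in cells) {
      need <- min(min_per_cell, length(cols))  # small designs: all of the cell
      keep <- keep & rowSums(cpm[, cols, drop = FALSE] >= min_cpm) >= need
    }
  }
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values factors (reference sample = library whose
#' log-count upper quartile is closest to the mean upper quartile; 30% / 5%
#' trim on M / A; factors scaled to geometric mean 1), computed with
#' `edgeR::calcNormFactors`.
#'
#' @param counts Feature x sample count matrix.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Numeric vector of normalization factors (one per sample).
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts)) {
  if (any(colSums(counts) == 0)) stop("all-zero sample column")
  edgeR::calcNormFactors(counts, lib.size = lib_sizes, method = "TMM")
}

#' Precision-weighted log-CPM transform
#'
#' The voom construction: `y = log2((count + 0.5) / (eff_lib + 1) * 1e6)`
#' with `eff_lib = lib_size * factor`; a lowess mean-variance trend is
#' fitted from an initial unweighted fit and inverted into per-observation
#' precision weights. Below `min_features` features the trend is unstable,
#' so unit weights are returned with a warning.
#'
#' @param counts Filtered count matrix.
#' @param design Model design matrix.
#' @param lib_sizes,factors Library sizes and TMM factors.
#' @param span Lowess span (default 0.5).
#' @param min_features Minimum features for trend fitting (default 16).
#' @return list with `y` (log2-CPM matrix) and `weights` (same shape).
#' @export
voomlike_transform <- function(counts, design, lib_sizes = colSums(counts),
                               factors = rep(1, ncol(counts)), span = 0.5,
                               min_features = 16L) {
  eff <- lib_sizes * factors
  if (nrow(counts) < min_features) {
    warning("fewer than ", min_features,
            " features: variance trend not fitted, unit weights used")
    y <- t(log2(t(counts + 0.5) / (eff + 1) * 1e6))
    return(list(y = y, weights = matrix(1, nrow(y), ncol(y),
                                        dimnames = dimnames(y))))
  }
  v <- limma::voom(counts, design, lib.size = eff, span = span)
  list(y = v$E, weights = v$weights)
}

#' Moderated linear model fit per feature
#'
#' Weighted least squares per feature followed by empirical-Bayes variance
#' moderation: the residual variances are shrunk towards a prior
#' `s0^2` with prior degrees of freedom `d0`,
#' `s2_mod = (d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t-statistic
#' uses `d0 + d` degrees of freedom. By default `d0` and `s0^2` are
#' estimated by the method of moments on the log residual variances; a
#' fixed `prior_df` can be supplied (0 recovers the classical t-test, Inf
#' pools all features to the common prior variance).
#'
#' @param y Response matrix (features x samples), e.g. from
#'   [voomlike_transform()].
#' @param design Full-rank design matrix.
#' @param weights Optional precision weights (same shape as `y`).
#' @param coef Column (name or index) of `design` to report (default 2).
#' @param prior_df `NULL` (estimate), a number, 0 or `Inf`.
#' @return data.frame with `feature_id`, `logFC`, `t`, `p`, `df_total`,
#'   plus attributes `df_prior` and `s2_prior`.
#' @export
fit_moderated_lm <- function(y, design, weights = NULL, coef = 2L,
                             prior_df = NULL) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- limma::lmFit(y, design, weights = weights)
  s2 <- fit$sigma^2
  d <- fit$df.residual
  if (is.null(prior_df)) {
    mom <- moment_prior(s2, d)
    d0 <- mom$df_prior; s02 <- mom$s2_prior
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(d0) && d0 == 0) NA_real_
           else moment_prior(s2, d)$s2_prior
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2))
            else if (d0 == 0) s2
            else (d0 * s02 + d * s2) / (d0 + d)
  se <- fit$stdev.unscaled[, coef] * sqrt(s2_mod)
  logFC <- fit$coefficients[, coef]
  tt <- logFC / se
  df_total <- if (is.infinite(d0)) rep(Inf, length(d)) else d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  out <- data.frame(feature_id = rownames(y), logFC = logFC, t = tt, p = p,
                    df_total = df_total, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  out
}

# method-of-moments estimation of the inverse-chisquare prior on residual
# variances, via the moments of log s^2 (Smyth's construction)
moment_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[ok])
  dfo <- if (length(df) == 1L) rep(df, sum(ok)) else df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(dfo / 2))
  if (is.na(evar) || evar <= 0)
    return(list(df_prior = Inf, s2_prior = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, s2_prior = s02)
}

# Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; `NA` p-values are propagated and excluded from
#' the effective number of tests.
#'
#' @param p Vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Significance calls at the published cut-offs
#'
#' A feature is significant when its BH-adjusted p-value is below `alpha`
#' and its absolute log2 fold change exceeds `lfc` (both strict).
#'
#' @param table Result table from [fit_moderated_lm()].
#' @param lfc log2-fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `table` with `p_adj` and `significant` columns added.
#' @export
call_significant <- function(table, lfc = 1, alpha = 0.05) {
  table$p_adj <- bh_adjust(table$p)
  table$significant <- !is.na(table$p_adj) &
    table$p_adj < alpha & abs(table$logFC) > lfc
  table
}

#' Classify differentially methylated peaks against gene expression
#'
#' Joins peak-level differential-methylation calls with gene-level
#' differential-expression calls through the peak-to-gene map and labels
#' each peak `meth_and_expr` (both significant), `meth_only`
#' (methylation-only) or `not_significant`.
#'
#' @param peak_results Peak table from [call_significant()] (feature_id =
#'   peak id).
#' @param gene_results Gene table from [call_significant()] (feature_id =
#'   gene id).
#' @param peak_genes Named character vector mapping peak id to gene id.
#' @return data.frame with `peak_id`, `gene_id`, `category`, plus a
#'   `summary` attribute of category percentages. Peaks with no gene are
#'   excluded with a warning.
#' @export
classify_peaks_vs_expression <- function(peak_results, gene_results,
                                         peak_genes) {
  gid <- peak_genes[peak_results$feature_id]
  drop <- is.na(gid)
  if (any(drop))
    warning(sum(drop), " peak(s) without a host gene excluded")
  pr <- peak_results[!drop, ]
  gid <- gid[!drop]
  gsig <- stats::setNames(gene_results$significant, gene_results$feature_id)[gid]
  gsig[is.na(gsig)] <- FALSE
  category <- ifelse(pr$significant & gsig, "meth_and_expr",
              ifelse(pr$significant, "meth_only", "not_significant"))
  out <- data.frame(peak_id = pr$feature_id, gene_id = gid,
                    category = category, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "summary") <- 100 * prop.table(table(factor(category,
    levels = c("meth_and_expr", "meth_only", "not_significant"))))
  out
}

#' Remove batch-term contributions for ordination
#'
#' Subtracts the fitted contributions of the batch factors from the
#' response matrix while retaining the condition effects, producing values
#' suitable for MDS and heat-map displays. Wraps
#' `limma::removeBatchEffect`.
#'
#' @param y Response matrix (features x samples).
#' @param condition Condition factor (retained).
#' @param batches Named list of batch factors (0 to 3 of them; more are
#'   passed as covariate columns).
#' @return Adjusted matrix, same shape as `y`.
#' @export
remove_batch_effects <- function(y, condition, batches = list()) {
  batches <- Filter(function(b) length(unique(b)) > 1L, batches)
  if (length(batches) == 0L) return(y)
  design <- stats::model.matrix(~ factor(condition))
  args <- list(x = y, design = design)
  args$batch <- batches[[1L]]
  if (length(batches) >= 2L) args$batch2 <- batches[[2L]]
  if (length(batches) >= 3L) {
    cov <- do.call(cbind, lapply(batches[-(1:2)], function(b)
      stats::model.matrix(~ factor(b))[, -1L, drop = FALSE]))
    args$covariates <- cov
  }
  do.call(limma::removeBatchEffect, args)
}
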