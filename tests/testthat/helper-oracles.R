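# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths (and, where possible, the
# distribution functions) used by the package itself.

# one-sided enrichment p for the 2x2 table [[a, A-a], [b, B-b]] by direct
# enumeration of all tables with the same margins, via log-binomials
oracle_fisher_p <- function(a, A, b, B) {
  k <- a + b
  ts <- max(0L, k - B):min(A, k)
  logp <- lchoose(A, ts) + lchoose(B, k - ts) - lchoose(A + B, k)
  sum(exp(logp[ts >= a]))
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-base union of intervals (0-based half-open) on one chromosome
oracle_merge_1chrom <- function(start, end, limit = 1000L) {
  covered <- logical(limit)
  for (i in seq_along(start))
    covered[(start[i] + 1L):end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# upper-tail Poisson probability P(X >= x) by direct series summation of
# the pmf (no ppois)
oracle_poisson_tail <- function(x, lambda, tol = 1e-18) {
  if (x <= 0) return(1)
  # sum pmf from k = x upward until terms vanish
  logterm <- x * log(lambda) - lambda - lgamma(x + 1)
  total <- term <- exp(logterm)
  k <- x
  while (term > tol * max(total, .Machine$double.xmin) && k < x + 10000) {
    k <- k + 1
    term <- term * lambda / k
    total <- total + term
  }
  total
}

# TMM normalization factors recomputed from the definition: M/A values
# against the reference library (upper quartile closest to the mean),
# 30% / 5% two-sided trims on M / A, inverse-variance weighted mean of M,
# factors scaled to geometric mean 1
oracle_tmm <- function(counts, lib = colSums(counts)) {
  uq <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib[j], 0.75, names = FALSE), 0)
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(j) {
    obs <- counts[, j]; refc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (length(M) == 0L || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE))
  }
  f <- vapply(seq_len(ncol(counts)), one, 0)
  f / exp(mean(log(f)))
}
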