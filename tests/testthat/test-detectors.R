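# helper to assemble a window_counts object from raw matrices
wc_fixture <- function(ip, input, ip_lib = sum(ip), in_lib = sum(input),
                       gene_id = "g") {
  n <- length(ip)
  w <- data.frame(window_id = sprintf("w%02d", seq_len(n)),
                  gene_id = rep_len(gene_id, n), chrom = "c", strand = "+",
                  start = seq_len(n) * 50L, end = seq_len(n) * 50L + 100L,
                  stringsAsFactors = FALSE)
  counts <- cbind(sIP = as.integer(ip), sInput = as.integer(input))
  rownames(counts) <- w$window_id
  structure(list(windows = w,
                 samples = data.frame(sample_id = c("sIP", "sInput"),
                                      role = c("IP", "Input"),
                                      stringsAsFactors = FALSE),
                 counts = counts,
                 library_sizes = c(sIP = ip_lib, sInput = in_lib)),
            class = "window_counts")
}

test_that("fisher p-value matches the worked 2x2 example", {
  # table [[2,0],[0,2]]: one-sided p = 1/6
  expect_equal(oracle_fisher_p(2, 2, 0, 2), 1 / 6)
  m <- wc_fixture(ip = c(2), input = c(0), ip_lib = 2, in_lib = 2)
  f <- fisher_detect(m, "sIP", "sInput")
  expect_equal(f$p, 1 / 6, tolerance = 1e-12)
  # zero IP count can never be enriched
  m0 <- wc_fixture(ip = c(0, 5), input = c(3, 2))
  f0 <- fisher_detect(m0, "sIP", "sInput")
  expect_equal(f0$p[1], 1)
  expect_false(f0$pass[1])
})

test_that("fisher p equals exhaustive hypergeometric enumeration (margins <= 30)", {
  # exhaustive over moderate margins here; the full sweep runs in the
  # acceptance suite
  for (A in c(3L, 7L, 12L)) for (B in c(4L, 9L, 15L)) {
    grid <- expand.grid(a = 0:A, b = 0:B)
    p_pkg <- meripeaks:::fisher_p(grid$a, A, grid$b, B)
    p_or <- mapply(oracle_fisher_p, grid$a, A, grid$b, B)
    expect_lt(max(abs(p_pkg - p_or)), 1e-12)
  }
})

test_that("fisher agrees with fisher.test one-sided", {
  set.seed(1)
  for (i in 1:20) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    A <- a + sample(1:30, 1); B <- b + sample(1:30, 1)
    p <- meripeaks:::fisher_p(a, A, b, B)
    pf <- stats::fisher.test(matrix(c(a, A - a, b, B - b), 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(p, pf, tolerance = 1e-10)
  }
})

test_that("rpmf follows the subtraction definition and its invariances", {
  m <- wc_fixture(ip = 400, input = 50, ip_lib = 2e6, in_lib = 1e6)
  r <- rpmf_detect(m, "sIP", "sInput")
  expect_equal(r$statistic, 200 - 50)
  expect_true(r$pass)
  # equal RPM -> 0, fails
  m0 <- wc_fixture(ip = 100, input = 50, ip_lib = 2e6, in_lib = 1e6)
  expect_false(rpmf_detect(m0, "sIP", "sInput")$pass)
  expect_equal(rpmf_detect(m0, "sIP", "sInput")$statistic, 0)
  # joint scaling of counts and library sizes leaves RPMF unchanged
  m2 <- wc_fixture(ip = 800, input = 100, ip_lib = 4e6, in_lib = 2e6)
  expect_equal(rpmf_detect(m2, "sIP", "sInput")$statistic, r$statistic)
  # monotone in the IP count
  mseq <- wc_fixture(ip = c(10, 20, 40), input = c(10, 10, 10),
                     ip_lib = 1e6, in_lib = 1e6)
  expect_true(all(diff(rpmf_detect(mseq, "sIP", "sInput")$statistic) > 0))
})

test_that("poi computes POM/POI with the documented thresholds and conventions", {
  genes <- list(g = gene_model("g", "chrT", "+", rbind(c(0, 400))))
  w <- data.frame(window_id = "g:1", gene_id = "g", chrom = "chrT",
                  strand = "+", start = 0L, end = 100L,
                  stringsAsFactors = FALSE)
  # IP: depth 24 in the window, 4 elsewhere -> gene nonzero median 4
  ip <- track_from_depth(list(chrT = c(rep(24L, 100), rep(4L, 300))),
                         "sIP", "IP", 1000)
  input <- track_from_depth(list(chrT = c(rep(8L, 100), rep(4L, 300))),
                            "sInput", "Input", 1000)
  r <- poi_detect(list(ip, input), genes, w, "sIP", "sInput")
  expect_equal(r$pom_ip, 24 / 4)
  expect_equal(r$pom_input, 8 / 4)
  expect_equal(r$statistic, 3)
  expect_true(r$pass)

  # POM just below 4 is removed before POI
  ip2 <- track_from_depth(list(chrT = c(rep(39L, 100), rep(10L, 300))),
                          "sIP", "IP", 1000)
  r2 <- poi_detect(list(ip2, input), genes, w, "sIP", "sInput")
  expect_true(is.na(r2$statistic))
  expect_false(r2$pass)

  # empty Input -> POI = Inf, pass flagged input_empty
  input0 <- track_from_depth(list(chrT = rep(0L, 400)), "sInput", "Input", 1)
  r3 <- poi_detect(list(ip, input0), genes, w, "sIP", "sInput")
  expect_equal(r3$statistic, Inf)
  expect_true(r3$pass)
  expect_true(r3$input_empty)
})

test_that("poi is invariant under global depth scaling and skips dead genes", {
  genes <- list(g = gene_model("g", "chrT", "+", rbind(c(0, 400))))
  w <- data.frame(window_id = "g:1", gene_id = "g", chrom = "chrT",
                  strand = "+", start = 0L, end = 100L,
                  stringsAsFactors = FALSE)
  ip <- track_from_depth(list(chrT = c(rep(24L, 100), rep(4L, 300))),
                         "sIP", "IP", 1000)
  ip3x <- track_from_depth(list(chrT = 3L * c(rep(24L, 100), rep(4L, 300))),
                           "sIP", "IP", 3000)
  input <- track_from_depth(list(chrT = c(rep(8L, 100), rep(4L, 300))),
                            "sInput", "Input", 1000)
  expect_equal(poi_detect(list(ip3x, input), genes, w, "sIP", "sInput")$statistic,
               poi_detect(list(ip, input), genes, w, "sIP", "sInput")$statistic)
  dead <- track_from_depth(list(chrT = rep(0L, 400)), "sIP", "IP", 1)
  expect_warning(r <- poi_detect(list(dead, input), genes, w, "sIP", "sInput"),
                 "skipped")
  expect_null(r)
})

test_that("poisson enrichment tail matches a series oracle and flags strong windows", {
  expect_equal(stats::ppois(29, 5, lower.tail = FALSE),
               oracle_poisson_tail(30, 5), tolerance = 1e-12)
  expect_lt(oracle_poisson_tail(30, 5), 1e-10)
  # 30 reads where ~5 expected passes; a window at its expectation does not
  ip <- c(30L, rep(5L, 99L))
  input <- rep(5L, 100L)
  m <- wc_fixture(ip = ip, input = input)
  r <- poisson_enrich_detect(m, "sIP", "sInput")
  expect_true(r$pass[1])
  expect_false(any(r$pass[-1]))
  expect_equal(r$p, stats::ppois(ip - 1, r$lambda, lower.tail = FALSE))
})

test_that("injected narrowPeak regions mark exactly the overlapping windows", {
  w <- data.frame(window_id = sprintf("g:%d", 1:7), gene_id = "g",
                  chrom = "chr1", strand = "+",
                  start = seq(0L, 300L, 50L), end = seq(100L, 400L, 50L),
                  stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chr1", start = 100L, end = 350L)
  r <- narrowpeak_to_results(regions, w, "sIP")
  # windows [50,150) ... [250,350) overlap [100,350)
  expect_equal(r$pass, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
})

test_that("BH adjustment reproduces the hand step-up example and oracle", {
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(bh_adjust(p), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(p), oracle_bh(p))
  set.seed(42)
  for (i in 1:10) {
    pv <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(pv), oracle_bh(pv), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
})

test_that("null multinomial counts keep detector false-positive rates low", {
  m <- simulate_null_window_counts(n_windows = 2200L, seed = 21L)
  mf <- filter_min_ip_coverage(m, "null_IP", 10L)
  expect_gte(nrow(mf$windows), 2000L)
  expect_lte(mean(fisher_detect(mf, "null_IP", "null_Input")$pass), 0.005)
  expect_lte(mean(rpmf_detect(mf, "null_IP", "null_Input")$pass), 0.01)
})

test_that("each technique recovers spiked windows on one simulated pair", {
  s <- default_sim()
  cfg <- merip_config()
  windows <- generate_windows(s$tx$genes)
  md <- s$ex$metadata
  # a condition-C2 pair: all sites enriched at the full fold there
  ip <- md$sample_id[md$role == "IP" & md$condition == "C2"][1]
  pair <- md$pair_id[md$sample_id == ip]
  input <- md$sample_id[md$role == "Input" & md$pair_id == pair]
  m <- count_reads_in_windows(s$ex$tracks, windows, samples = md)
  m$library_sizes <- stats::setNames(md$library_size, md$sample_id)
  mf <- filter_min_ip_coverage(m, ip, cfg$min_ip_reads)
  # spiked windows: fully inside a truth site
  tr <- s$ex$truth
  spiked <- mf$windows$window_id[vapply(seq_len(nrow(mf$windows)), function(i) {
    any(tr$chrom == mf$windows$chrom[i] & tr$start <= mf$windows$start[i] &
        tr$end >= mf$windows$end[i])
  }, TRUE)]
  expect_gt(length(spiked), 10)
  res <- list(
    fisher = fisher_detect(mf, ip, input, cfg$fisher_alpha),
    rpmf = rpmf_detect(mf, ip, input, cfg$rpmf_threshold),
    poi = poi_detect(s$ex$tracks, s$tx$genes, mf$windows, ip, input,
                     cfg$pom_min, cfg$poi_min),
    macs2like = poisson_enrich_detect(mf, ip, input, cfg$poisson_qmax))
  for (tech in names(res)) {
    hit <- res[[tech]]$pass[match(spiked, res[[tech]]$window_id)]
    expect_gte(mean(hit, na.rm = TRUE), 0.8)
  }
})
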