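test_that("occurrence filter keeps windows seen in >= 3 IP samples", {
  res <- data.frame(
    window_id = rep(c("w1", "w2", "w3"), each = 6),
    ip_sample_id = rep(paste0("s", 1:6), 3),
    pass = c(rep(TRUE, 3), rep(FALSE, 3),    # w1: 3 samples
             TRUE, TRUE, rep(FALSE, 4),      # w2: 2 samples
             rep(TRUE, 6)),                  # w3: all
    stringsAsFactors = FALSE)
  kept <- occurrence_filter(res, 3L)
  expect_setequal(kept$window_id, c("w1", "w3"))
  expect_equal(kept$occurrence[kept$window_id == "w3"], 6L)
  # min_samples = 1 keeps the union of passes
  expect_setequal(occurrence_filter(res, 1L)$window_id, c("w1", "w2", "w3"))
  # too few IP samples is an error
  expect_error(occurrence_filter(res[res$ip_sample_id %in% c("s1", "s2"), ], 3L),
               "min_samples")
})

test_that("interval merging matches the per-base union oracle", {
  m <- meripeaks:::merge_intervals(c("c", "c"), c(0L, 50L), c(100L, 150L))
  expect_equal(m$start, 0L)
  expect_equal(m$end, 150L)
  # adjacent-but-not-overlapping stay apart
  m2 <- meripeaks:::merge_intervals(c("c", "c"), c(0L, 100L), c(100L, 200L))
  expect_equal(nrow(m2), 2L)
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    start <- sample(0:900, n)
    end <- pmin(start + sample(10:100, n, replace = TRUE), 1000L)
    # a per-base oracle cannot represent book-ended-but-disjoint intervals;
    # nudge those apart (the window grid never produces them)
    while (length(bad <- which(end %in% start)))
      end[bad] <- pmin(end[bad] + 1L, 1000L)
    got <- meripeaks:::merge_intervals(rep("c", n), start, end)
    want <- oracle_merge_1chrom(start, end, 1000L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("recentering places 150-bp sites at the leftmost coverage maximum", {
  w <- data.frame(window_id = c("g:1", "g:2"), gene_id = "g", chrom = "chrT",
                  strand = "+", start = c(200L, 250L), end = c(300L, 350L),
                  stringsAsFactors = FALSE)
  kept <- data.frame(window_id = c("g:1", "g:2"), occurrence = c(3L, 4L))
  depth <- rep(0, 400)
  depth[261] <- 9  # 0-based position 260
  med <- methods::as(list(chrT = S4Vectors::Rle(depth)), "SimpleRleList")
  s <- merge_and_recenter(kept, w, med)
  expect_equal(c(s$region_start, s$region_end), c(200L, 350L))
  expect_equal(s$max_cov_pos, 260L)
  expect_equal(c(s$start, s$end), c(185L, 335L))
  expect_equal(s$occurrence, 4L)
  # tie at 260 and 280: leftmost wins
  depth[281] <- 9
  med2 <- methods::as(list(chrT = S4Vectors::Rle(depth)), "SimpleRleList")
  s2 <- merge_and_recenter(kept, w, med2)
  expect_equal(s2$max_cov_pos, 260L)
  # all-zero coverage: centre of the region, with a warning
  med0 <- methods::as(list(chrT = S4Vectors::Rle(rep(0, 400))), "SimpleRleList")
  expect_warning(s0 <- merge_and_recenter(kept, w, med0), "zero median")
  expect_equal(s0$max_cov_pos, 200L + (350L - 200L) %/% 2L)
})

test_that("technique consensus requires >= 3 techniques and is idempotent", {
  site <- function(start, end) data.frame(
    chrom = "chrT", start = start, end = end, region_start = start,
    region_end = end, max_cov_pos = (start + end) %/% 2L, occurrence = 3L,
    stringsAsFactors = FALSE)
  depth <- rep(1, 1000)
  depth[c(176, 676)] <- 5  # maxima at the candidate-region centres
  med <- methods::as(list(chrT = S4Vectors::Rle(depth)), "SimpleRleList")
  # fisher+rpmf+poi agree on [100,250); macs2like elsewhere
  sites <- list(fisher = site(100L, 250L), rpmf = site(100L, 250L),
                poi = site(100L, 250L), macs2like = site(600L, 750L))
  pk <- combine_techniques(sites, med, genes = NULL)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$n_techniques, 3L)
  expect_equal(pk$end - pk$start, 150L)
  # two techniques only -> nothing
  pk2 <- combine_techniques(sites[c("fisher", "rpmf")], med, NULL)
  expect_equal(nrow(pk2), 0L)
  # four identical 150-bp sites -> one identical consensus peak
  sites4 <- list(fisher = site(100L, 250L), rpmf = site(100L, 250L),
                 poi = site(100L, 250L), macs2like = site(100L, 250L))
  pk4 <- combine_techniques(sites4, med, NULL)
  expect_equal(nrow(pk4), 1L)
  expect_equal(c(pk4$start, pk4$end), c(100L, 250L))
  expect_equal(pk4$n_techniques, 4L)
  # order invariance
  pk4b <- combine_techniques(rev(sites4), med, NULL)
  expect_equal(pk4b[, -1], pk4[, -1], ignore_attr = TRUE)
  # empty input
  expect_equal(nrow(combine_techniques(list(), med, NULL)), 0L)
})

test_that("consensus peaks are 150 bp, centered on max_cov_pos, unless clipped", {
  pk <- default_peaks()
  expect_gt(nrow(pk), 0L)
  full <- !pk$clipped
  expect_true(all(pk$end[full] - pk$start[full] == 150L))
  mid <- pk$start[full] + (pk$end[full] - pk$start[full]) %/% 2L
  expect_true(all(abs(mid - pk$max_cov_pos[full]) <= 1L))
  expect_true(all(pk$n_techniques >= 3L))
})

test_that("region annotation follows the 5UTR > 3UTR > CDS > intron precedence", {
  genes <- tiny_genes()
  mk <- function(start, end, gene) data.frame(
    peak_id = "p", chrom = "chrT", start = start, end = end, strand = "+",
    gene_id = gene, stringsAsFactors = FALSE)
  # fully inside CDS of gplus
  expect_equal(annotate_region(mk(250L, 400L, "gplus"), genes)$region, "CDS")
  # straddles CDS/3UTR junction (1100) -> 3UTR by precedence
  expect_equal(annotate_region(mk(1050L, 1200L, "gplus"), genes)$region, "3UTR")
  # straddles 5UTR/CDS junction (200) -> 5UTR
  expect_equal(annotate_region(mk(150L, 300L, "gplus"), genes)$region, "5UTR")
  # fully intronic ([600,800) is the intron)
  expect_equal(annotate_region(mk(650L, 750L, "gplus"), genes)$region, "intron")
  # no gene overlap -> intergenic with warning
  expect_warning(r <- annotate_region(mk(2500L, 2650L, NA), genes), "no gene")
  expect_equal(r$region, "intergenic")
})

test_that("motif scoring applies the 2/3/5/8 weights on the sense strand", {
  genome <- Biostrings::DNAStringSet(c(chrT = paste0(
    strrep("A", 50), "GGACT", strrep("A", 45),   # GGACT at [50,55)
    "GAACA", "GGACA", strrep("A", 95),           # at [100,105), [105,110)
    strrep("T", 100))))
  mk <- function(start, end, strand = "+") data.frame(
    peak_id = "p", chrom = "chrT", start = start, end = end,
    strand = strand, stringsAsFactors = FALSE)
  expect_equal(motif_score(mk(0L, 100L), genome)$motif_score, 8L)
  expect_equal(motif_score(mk(95L, 150L), genome)$motif_score, 5L)  # 2 + 3
  expect_equal(motif_score(mk(200L, 300L), genome)$motif_score, 0L)
  expect_false(motif_score(mk(200L, 300L), genome)$rgacw_present)
  # minus strand reads the reverse complement: AGTCC on + is GGACT on -
  genome2 <- Biostrings::DNAStringSet(c(chrT = paste0(
    strrep("C", 20), "AGTCC", strrep("C", 75))))
  expect_equal(motif_score(mk(0L, 100L, "-"), genome2)$motif_score, 8L)
  expect_equal(motif_score(mk(0L, 100L, "+"), genome2)$motif_score, 0L)
  # shorter than a motif scores 0
  expect_equal(motif_score(mk(0L, 4L), genome)$motif_score, 0L)
})

test_that("reference overlap fractions behave at the identity and extremes", {
  pk <- data.frame(chrom = "c", start = c(185L, 500L), end = c(335L, 650L))
  ref <- data.frame(chrom = "c", start = 300L, end = 400L)
  ov <- reference_overlap(pk, ref)
  expect_equal(ov$overlap, c(TRUE, FALSE))
  expect_equal(ov$fraction, 0.5)
  expect_equal(reference_overlap(pk, pk)$fraction, 1.0)
  expect_equal(reference_overlap(pk, ref[0, ])$fraction, 0)
})

test_that("metagene positions scale 5UTR/CDS/3UTR to [0,3) strand-aware", {
  genes <- tiny_genes()
  mk <- function(mid, gene) data.frame(
    peak_id = "p", chrom = "chrT", start = mid - 75L, end = mid + 75L,
    gene_id = gene, stringsAsFactors = FALSE)
  # gplus: utr5 [100,200), cds [200,600)+[800,1100), utr3 [1100,1300)
  expect_equal(metagene_positions(mk(200L, "gplus"), genes), 1.0)  # CDS start
  expect_equal(metagene_positions(mk(1200L, "gplus"), genes), 2.5)  # mid 3UTR
  expect_equal(metagene_positions(mk(100L, "gplus"), genes), 0.0)
  # minus-strand gene: genomic-rightmost 5UTR base maps near 0
  expect_equal(metagene_positions(mk(2299L, "gminus"), genes), 0.0)
  # its CDS start (genomic 2199, first CDS base in transcript order) -> 1.0
  expect_equal(metagene_positions(mk(2199L, "gminus"), genes), 1.0)
  # intronic midpoint or no CDS -> NA
  expect_true(is.na(metagene_positions(mk(700L, "gplus"), genes)))
  nocds <- list(g0 = gene_model("g0", "chrT", "+", rbind(c(0, 500))))
  expect_true(is.na(metagene_positions(mk(250L, "g0"), nocds)))
})
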