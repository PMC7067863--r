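# Shared fixtures, built in code. Heavy simulations are memoised so several
# test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# two hand-made genes on one small chromosome:
#   gplus : + strand, 2 exons [100,600) [800,1300), utr5/cds/utr3 split
#   gminus: - strand, 1 exon [1500,2300)
tiny_genes <- function() {
  gplus <- gene_model("gplus", "chrT", "+",
    exons = rbind(c(100, 600), c(800, 1300)),
    utr5 = rbind(c(100, 200)),
    cds = rbind(c(200, 600), c(800, 1100)),
    utr3 = rbind(c(1100, 1300)))
  gminus <- gene_model("gminus", "chrT", "-",
    exons = rbind(c(1500, 2300)),
    utr3 = rbind(c(1500, 1700)),
    cds = rbind(c(1700, 2200)),
    utr5 = rbind(c(2200, 2300)))
  list(gplus = gplus, gminus = gminus)
}

# coverage track from explicit read start positions (0-based), 65-bp reads
track_from_starts <- function(starts, sample_id = "s_IP", role = "IP",
                              chrom = "chrT", chrom_len = 3000L,
                              read_length = 65L) {
  reads <- GenomicRanges::GRanges(rep(chrom, length(starts)),
    IRanges::IRanges(starts + 1L, width = pmin(read_length,
                                               chrom_len - starts)))
  track_from_reads(reads, sample_id, role,
                   seqlengths = stats::setNames(chrom_len, chrom))
}

# depth-only track from a named list of integer depth vectors
track_from_depth <- function(depths, sample_id, role, library_size) {
  coverage_track(sample_id, role,
    methods::as(lapply(depths, S4Vectors::Rle), "SimpleRleList"),
    library_size)
}

# default study-scale simulation (seed 11), shared across test files
default_sim <- function() memo("default_sim", {
  cfg <- sim_config(seed = 11L)
  tx <- simulate_transcriptome(cfg)
  ex <- simulate_experiment(cfg, tx)
  list(cfg = cfg, tx = tx, ex = ex)
})

default_peaks <- function() memo("default_peaks", {
  s <- default_sim()
  call_peaks(s$ex$tracks, s$tx$genes, s$ex$metadata, merip_config(),
             genome = s$tx$genome, chrom_sizes = s$tx$chrom_sizes)
})

# small, fast simulation for unit-level checks
small_sim <- function() memo("small_sim", {
  cfg <- sim_config(seed = 5L, n_genes = 15L, n_sites = 6L,
                    n_diff_sites = 0L, n_diff_expr_genes = 0L)
  tx <- simulate_transcriptome(cfg)
  ex <- simulate_experiment(cfg, tx)
  list(cfg = cfg, tx = tx, ex = ex)
})
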