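---
title: "Consensus m6A peak calling and differential methylation with meripeaks"
author: "meripeaks authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus m6A peak calling and differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripeaks)
```

## The problem

MeRIP-seq (m6A-seq) measures N6-methyladenosine on mRNA by sequencing two
libraries from the same RNA: an antibody-enriched IP library and a
fragmented Input control. A methylation site appears as a localized excess
of IP coverage relative to Input. No single statistic captures all true
sites — absolute enrichment, relative enrichment, and local coverage shape
each miss different classes — so `meripeaks` implements a consensus
design: four detection techniques are run per IP/Input pair on a common
window grid, and only regions supported by several samples *and* several
techniques become peaks.

## The window grid

Protein-coding genes are tiled over their genomic extent with 100-bp
windows whose starts step by 50 bp, so consecutive windows overlap in
their middle. A gene of span $L \ge 100$ carries
$\lfloor (L-100)/50 \rfloor + 1$ windows; genes shorter than 100 bp get a
single window covering the gene. The remainder past the last full window
is deliberately not tiled with a short window: the half-overlap already
covers all interior positions twice, and a deterministic rule is worth
more than the final $<50$ bp of a gene.

Read counting uses union/"nonunique-all" semantics: a read contributes to
every window (or gene, or peak) it overlaps by at least one base, with no
strand filtering. When only per-base coverage is available (bedGraph
input), window counts are approximated as the depth sum over the window
divided by the read length (65 bp by default, the single-end read length
the simulator also uses).

Before detection, each IP sample's windows are filtered to those with
**more than 10 reads** in that IP library. The filter is applied per IP
sample — detection itself is per-pair, and occurrence counting across
samples later needs per-sample calls — rather than "any IP sample";
`min_ip_cov_mode = "any"` exposes the other reading.

## The four techniques

All thresholds are strict inequalities, exactly as printed in
`merip_config()`.

**Fisher exact enrichment.** Per window, the one-sided hypergeometric
test on the 2x2 table $[[n^{IP}_w,\ N^{IP}-n^{IP}_w],
[n^{In}_w,\ N^{In}-n^{In}_w]]$, where $N$ is each library's total mapped
reads; BH adjustment across the tested windows of the sample, pass at
adjusted $p < 0.001$. The table's margins use the full library sizes (the
standard RIP enrichment table): window counts are a vanishing fraction of
the library, so "window versus rest of library" is the well-calibrated
contrast.

**RPM fold (RPMF).** $\mathrm{RPM} = n_w / N \times 10^6$;
$\mathrm{RPMF} = \mathrm{RPM}_{IP} - \mathrm{RPM}_{In}$ (a difference,
despite the name; `rpmf_mode = "ratio"` exposes the other reading), pass
at $\mathrm{RPMF} > 10$. The statistic is invariant under joint scaling of
counts and library sizes but *not* scale-free in depth: at a typical
30-million-read library a window needs roughly 300 excess reads to pass,
which is what makes its null rate negligible.

**Peak-over-input (POM/POI).** On per-base coverage with zero positions
removed: $\mathrm{POM} = $ median window depth / median gene *exonic*
depth (both over non-zero positions; even-length medians are the mid-mean).
Windows with IP POM $< 4$ are removed; $\mathrm{POI} =
\mathrm{POM}_{IP}/\mathrm{POM}_{In}$ passes at $\mathrm{POI} > 2$. A zero
or undefined Input POM yields $\mathrm{POI} = +\infty$ — a pass, but
flagged `input_empty` so downstream users can treat Input dropouts
specially. Windows on genes with no non-zero exonic IP coverage are
skipped with a warning.

**Local Poisson enrichment.** A windowed test in the spirit of
genome-wide peak callers: the expected IP count is
$\lambda = \max(\text{genome-wide rate},\ \text{gene-local Input rate
scaled to the IP library})$, the upper-tail Poisson p-value is
BH-adjusted, pass at $q < 0.05$ (the caller's conventional default; the
threshold is exposed). When real MACS2 narrowPeak output is available,
`narrowpeak_to_results()` maps it onto the window grid and replaces this
test verbatim — the in-package test exists so that the full pipeline runs
self-contained.

The BH family for the two p-value techniques is all windows tested in
that sample after the coverage filter — the natural family, since each
pair is analysed independently.

## From windows to consensus peaks

1. **Occurrence**: per technique, keep windows passing in at least 3 IP
   samples (error if fewer than 3 IP samples exist).
2. **Merge**: overlapping kept windows are merged per technique.
   Book-ended (adjacent but non-overlapping) windows are *not* merged;
   grid windows always overlap by 50 bp, so this only matters for
   external region sets.
3. **Recenter**: within each merged region, the position of maximum
   per-base median coverage across all IP samples is found (leftmost on
   ties — a deterministic choice) and the region becomes the 150-bp
   interval centered there. All-zero regions fall back to their centre
   with a warning.
4. **Technique consensus**: genomic positions covered by sites from at
   least 3 distinct techniques are merged and recentered again, with the
   maximum recomputed on the combined region (the combined region can
   differ from any single technique's region, so reusing per-technique
   maxima would be ill-defined). Peaks may extend past gene bounds after
   recentering and are clipped only at chromosome edges, where they are
   flagged `clipped`.
5. **Annotation**: each peak takes the label of the gene region it
   overlaps with precedence 5'UTR > 3'UTR > CDS > intron (configurable);
   peaks overlapping no gene are `intergenic`. The RGACW m6A consensus
   content is summarised two ways: a weighted score (sense-strand
   occurrence counts of GAACA, GGACA, GAACT, GGACT weighted 2, 3, 5, 8,
   overlaps allowed) and the boolean `rgacw_present` (score > 0), since
   the two answer different questions (motif strength versus presence).
6. **Metagene positions**: peak midpoints map to spliced transcript
   coordinates rescaled piecewise to 5'UTR [0,1), CDS [1,2), 3'UTR [2,3),
   strand-aware; peaks on genes without CDS or with intronic midpoints
   are excluded.

## Differential methylation and expression

Peak-level IP counts and gene-level Input counts are analysed with the
same machinery:

* **Filtering**: at least 5 CPM in at least 3 samples. Peak matrices
  additionally require qualifying samples in every condition x
  IP-procedure cell (at least 2, capped at the cell size for small
  designs — with fewer than 2 samples in a cell the printed rule would
  discard everything).
* **Normalization**: TMM factors (`edgeR::calcNormFactors`).
* **Transform**: `voom`-style log2-CPM with precision weights from the
  lowess mean-variance trend (span 0.5). Below 16 features a trend is
  not estimable, so unit weights are used with a warning.
* **Model**: per feature, weighted least squares on
  `~ condition + sequencing_batch + library_batch + ip_procedure`
  (treatment contrasts, declared reference level), followed by
  empirical-Bayes variance moderation. The prior `d0`, `s0^2` is
  estimated by the method of moments on log residual variances (the
  canonical construction); `prior_df` can be fixed, with 0 recovering
  the classical t-test and `Inf` full pooling — both limits are verified
  numerically in the test suite, and the estimated-moderation path is
  cross-checked against `limma::eBayes`.
* **Calls**: BH-adjusted p < 0.05 **and** |log2FC| > 1, both strict.
* **Classification**: differentially methylated peaks are joined to
  their host gene's expression call — `meth_and_expr`, `meth_only`,
  `not_significant` — mirroring the usual peak-versus-transcript
  display.
* **Ordination support**: `remove_batch_effects()` subtracts fitted
  batch contributions while retaining condition effects, for MDS and
  heat maps (rendering itself is out of scope).

Peak differential analysis models IP counts only. An IP count confounds
methylation change with expression change; peaks on differentially
expressed genes therefore surface as `meth_and_expr` rather than being
corrected away. This matches the upstream convention; an Input-offset
mode was considered and rejected as a default because it changes the
estimand silently.

## The simulator

`sim_config()` defaults define the validation conditions used throughout
the test suite:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 100 | genes on one synthetic chromosome |
| `n_sites` | 50 | spiked 150-bp exonic m6A sites |
| `gamma` | 8 | IP enrichment fold inside a site |
| `n_diff_sites` / `gamma_low` | 10 / 2 | sites enriched 2-fold in C1 vs 8-fold elsewhere (true log2 difference 2) |
| `n_conditions` x `samples_per_condition` | 2 x 3 | 6 IP/Input pairs |
| `depth` | 30 | mean Input exonic coverage (65-bp single-end reads) |
| `dispersion` | 0.05 | NB dispersion of per-gene read totals |
| `batch_sd` | 0.25 | SD of per-gene log2 batch effects |
| `n_diff_expr_genes` / `expr_fold` | 10 / 4 | genes over-expressed in C2 |

Enrichment is a step function on the read-placement rate inside the site
(rate model: IP read rate proportional to expression times
$1 + (\gamma-1)\,\mathbf{1}[\text{pos} \in \text{site}]$), so the raw
IP:Input depth ratio inside a site approaches gamma. Batch effects are
multiplicative per gene (log-additive), matching the linear model's
assumption. The expression fold for differentially expressed genes is 4
(log2 = 2), the same effect size as the differential sites — a fold of 2
would sit exactly on the |log2FC| > 1 call boundary and be undetectable
by construction. Everything is reproducible bit-for-bit from the seed.

What the simulator does *not* emulate: mapping artefacts and multimapping
reads, fragment-length effects, Gaussian/asymmetric peak shapes (a
triangular option was considered and dropped — the step model already
exercises recentering through sampling noise), isoform structure,
sequencing errors, and antibody-specific background. Passing tests on
simulated data therefore demonstrate the statistical machinery, not
robustness to alignment pathology.

A second generator, `simulate_peak_counts()`, produces negative-binomial
peak-count matrices (2000 peaks, 20 with true log2FC 2, 6 samples per
condition, batch effects) to characterize the differential stage on its
own: power and empirical FDR are averaged over 20 seeded replicates.
`simulate_null_window_counts()` draws IP and Input window counts from one
multinomial at transcriptome-realistic library size (30 million reads,
mean window count 60) to measure detector false-positive rates.

## Validation problem sizes

The shipped checks run at: the default 100-gene simulation for spiked-site
recovery (sensitivity and precision both required >= 0.90); 2500-window
multinomial nulls for Fisher (pass fraction <= 0.005) and RPMF (<= 0.01);
a 70-gene unenriched coverage simulation (> 2000 windows) for POI
(<= 0.01); 20 replicates of the 2000-peak count simulation for power
(>= 0.80) and FDR (<= 0.07); and exhaustive oracle sweeps (all Fisher
tables with margins <= 30, random BH/TMM/merge instances). These sizes
give stable estimates while keeping a full run around two minutes.

## Numerical conventions

* Coordinates are 0-based half-open everywhere inside the package; GTF is
  converted at the file boundary, BED written natively.
* Ties in maximum-coverage searches resolve to the leftmost position.
* Medians of even-length vectors are mid-means (`stats::median`).
* All published thresholds are strict (`>10`, `<0.001`, `>10`, `>=4`
  kept / `<4` removed, `>2`, `>=3`, `>=3`, `<0.05`, `>1`).
* `NA` p-values are excluded from the BH family and propagated.

## Known limitations

* Window generation tiles the genomic span (introns included), so long
  intronic stretches generate windows that are usually removed by the
  coverage filter; POM's gene median always uses exonic positions only.
* The local-Poisson technique is a deliberately simple stand-in for an
  external peak caller and does not model fragment shifts, duplicate
  reads, or summit refinement; use the narrowPeak adapter for faithful
  results from such a caller.
* Library sizes for bedGraph input must come from the metadata table —
  per-base depth cannot recover read counts.
* With one IP procedure per condition cell the peak CPM rule reduces to
  "every sample in the cell", which is stricter than intended for
  single-replicate designs; such designs are better analysed with
  `ip_procedure_rule = FALSE`.
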