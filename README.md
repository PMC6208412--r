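# ibless

An R toolkit for analyzing **i-BLESS** sequencing data — direct, in-situ
labeling of DNA double-strand breaks (DSBs) at single-nucleotide resolution
in budding yeast. i-BLESS ligates an 11-nt *proximal* barcode
(`TCGAGGTAGTA`) to the blunted break end and a *distal* barcode
(`TCGAGACGACG`) to the sonicated far end of each fragment; only
proximal-tagged read starts mark true break positions. The package covers
the complete downstream computational pipeline, plus a fully seeded
synthetic-data generator so every stage is testable without any external
data.

## What it does

* **Barcode demultiplexing** (`classify_read`, `classify_pair`,
  `demultiplex`) — Hamming-tolerant, 5'-anchored classification of read
  pairs; selects and trims proximal reads.
* **Break profiling** (`profile_from_alignments`,
  `normalize_per_million`) — strand-aware single-nucleotide break-end
  counts: the 5' end of each proximal read (leftmost base on `+`,
  rightmost on `-`) is the break end.
* **Fragile-region calling** (`call_fragile_regions`) — windowed
  one-sided hypergeometric test of treatment vs control counts. For a
  window with `t` of `T` treatment and `c` of `C` control reads, the
  enrichment P value is `P[X >= t]` with
  `X ~ Hypergeom(N = T + C, K = T, n = t + c)`, Bonferroni-corrected over
  the testable windows (default threshold `p_adj < 0.001`). Mappability
  correction by window exclusion (`compute_mappability`: exact k-mer
  uniqueness across both strands).
* **Nucleosome-periodicity QC** (`autocorrelation`,
  `cross_correlation`, `estimate_period`, `classify_noise`) — Pearson
  correlation as a function of integer shift (1 nt bins, 800 nt range).
  Over-fixation noise shows a ~162 bp autocorrelation period (the yeast
  nucleosome repeat); cross-correlation against linker-enriched MNase-seq
  coverage peaks at 0 for breaks between nucleosomes and at ±80 bp for
  breaks within nucleosomes.
* **G-quadruplex analysis** (`find_g4`, `g4_fragility_report`,
  `loop_breakability`) — intra- and inter-strand G4 motif scanning
  (`G3–5 N1–L G3–5 N1–L G3–5 N1–L G3–5`, loops up to 16 nt), loop-length
  categories (L1–4 / L5–7 / L8–16 and per-k groups), inside-vs-flank
  paired Wilcoxon tests, intra-vs-inter Kolmogorov–Smirnov comparison,
  center-aligned meta-profiles.
* **Endonuclease validation** (`find_sites`, `site_precision`,
  `offtarget_scan`) — IUPAC recognition-site scanning with blunted
  break-end geometry for 5'/3'-overhang and blunt cutters, cut-precision
  fractions (exact and ±1 nt), and ungapped identity scanning for
  degenerate off-target sites.
* **Feature enrichment** (`permutation_test`) — observed/expected
  mappable-nucleotide overlap of a feature with DSB-rich windows, with a
  label-permutation empirical P value
  `P = (1 + #{ratio_perm >= ratio_obs}) / (1 + n_perm)`.
* **Simulation** (`simulate_genome`, `simulate_nucleosomal_background`,
  `simulate_mnase`, `simulate_digest`, `emit_fastq`) — enzyme-cut genomes
  with chosen overhang chemistry, nucleosome-patterned artifact breaks,
  linker-enriched MNase-like coverage, and barcoded read pairs with truth
  alignments.

## Worked example

```r
library(ibless)

# synthetic genome with BamHI cut sites, digested at zero noise
g  <- simulate_genome(1e5, gc = 0.45, seed = 555)
enz <- load_enzymes()
d  <- simulate_digest(g, enz[enz$name == "BamHI", ],
                      n_cells = 500, seed = 556)
fq <- emit_fastq(d$events, g, read_len = 50, error_rate = 0, seed = 557)

dx <- demultiplex(fq$r1, fq$r2)
dx$summary
#>               class count fraction
#> 1   proximal-distal 16042        1
#> 2 proximal-proximal     0        0
#> 3     distal-distal     0        0
#> 4             other     0        0

prof <- profile_from_alignments(fq$truth, g)
site_precision(prof, d$sites)
#> SitePrecision: 16/16 sites detected; 100.0% of reads exact,
#>   100.0% within tolerance
```

Every barcoded fragment carries one proximal and one distal barcode, and
with no background or end jitter every read maps exactly onto an expected
blunted cut coordinate — the same accounting that, on real digests, is
reported as the fraction of reads detected precisely at cutting sites.

A noise diagnostic on simulated nucleosome-associated background:

```r
p  <- simulate_nucleosomal_background(1e6, repeat_len = 162,
                                      jitter_sd = 20, n_breaks = 1e5,
                                      seed = 1, mode = "dyad")
ac <- autocorrelation(p, max_lag = 800)
estimate_period(ac)
#> [1] 162
```

The estimated period is the yeast nucleosome repeat length: a signature
of nucleosome-associated artifact breaks rather than genuine DSB signal.

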