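---
title: "Models and methods behind ibless"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ibless}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical models,
conventions and design choices it implements, in the spirit of the long
methods vignettes of DESeq2 or limma. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The measurement and its coordinate conventions

i-BLESS labels DNA double-strand break (DSB) ends in situ: ends are
blunted, ligated to an 11-nt proximal barcode, fragments are sheared and
their far ends ligated to a distal barcode. Only the proximal-tagged read
starts at the break; its mate starts at a random sonication point. The
package therefore reduces a library to a **break profile**: strand-aware
counts of proximal-read 5' ends at single-nucleotide positions.

Conventions, fixed once and used everywhere:

* Coordinates are 0-based, half-open internally (BED/bedGraph
  convention); 1-based only in printed reports.
* The break end of a `+` strand read is its leftmost aligned base; of a
  `-` strand read its rightmost base (`pos + length - 1`). This is the 5'
  end of the read after barcode removal, which the chemistry places at
  the blunted break.
* Chromosome names match exactly; no `chr` aliasing. Yeast Roman-numeral
  names make silent aliasing dangerous.
* Multi-mapping reads are excluded upstream (the `bowtie -m1`
  philosophy); the package does not attempt rescue.

For endonuclease cuts the *blunted* end coordinates are what i-BLESS
sees. With top-strand cut boundary $g_t$ and bottom-strand boundary $g_b$
(0-based boundaries relative to the chromosome), fill-in of 5' overhangs
and chew-back of 3' overhangs both lead to a `+` strand labeled end at
$g_t$ and a `-` strand labeled end at $g_b - 1$, for every overhang
chemistry including blunt cutters. The bundled enzyme table
(`inst/extdata/enzymes.tsv`; BamHI, NotI, SrfI, AsiSI, I-SceI) is curated
from standard restriction-enzyme references.

## Barcode classification

Barcodes are 5'-anchored: adapters ligate to fragment ends, so an
internal match would be a chimera artifact, not a break label.
Classification compares the first 11 nt against both barcodes under a
Hamming threshold (`max_mismatch`, default 0). The two barcodes differ at
6 of 11 positions (asserted at package load), so thresholds up to 2 can
never make a read match both barcodes equally except through the
explicit tie rule, which classifies it as `none` and counts it as
ambiguous. Reads of 11 nt or less cannot carry a barcode plus insert and
are flagged short. Quality strings pass through untouched apart from the
trimmed prefix. Reads are classified in their stored orientation;
reverse-complement search is deliberately not performed (the sequencer
reads outward from the adapter, so a true barcode is always a prefix).

## Fragile-region calling

For each non-overlapping window (default 1000 nt — gene-scale in yeast;
the window size is a free parameter of the method) with `t` of `T`
treatment reads and `c` of `C` control reads, the null hypothesis is that
the window's `t + c` reads are an exchangeable draw from the pooled
library. The one-sided enrichment P value is the hypergeometric upper
tail

$$P\left[X \ge t\right],\qquad
  X \sim \mathrm{Hypergeom}(N = T + C,\; K = T,\; n = t + c),$$

computed with `stats::phyper` and verified in the tests against
exhaustive combinatorial enumeration. Bonferroni correction multiplies by
the number of *testable* windows and regions are reported at
`p_adj < 0.001`. The control sample is by convention sonicated genomic
DNA input, but any break profile is accepted. Depletion scanning is out
of scope: breaks lost relative to input are dominated by mappability, not
biology.

**Mappability correction.** A position is mappable iff the k-mer starting
there occurs exactly once across both strands (a palindromic k-mer at a
single locus counts once — an aligner reports one alignment there).
Uniqueness is exact-match; mismatch-tolerant uniqueness would be
quadratic and is not implemented (a documented divergence from aligner
`-v1` behavior). Correction is realized as *exclusion*: windows with
fewer than `min_mappable` (default 20) mappable nucleotides are removed
from both testing and the Bonferroni count. No count-rescaling is
attempted — there is no principled per-window rescaling without a read
model, and exclusion is transparent. Whether the multiplier should count
all windows instead is exposed as a flag (`bonferroni = "all"`).

## Correlation QC and the nucleosome signature

The cross-correlation of two positional signals at integer shift $n$ is
the Pearson coefficient between signal A at position $i$ and signal B at
$i + n$, pooled over all positions where both are defined. Chromosomes
are concatenated for pooling but pairs never span a boundary. Computation
uses 1 nt bins over an 800 nt range by default; autocorrelation is the
self case restricted to non-negative lags. No detrending is applied
beyond the centering inherent in Pearson correlation. A lag whose overlap
has zero variance yields a missing value, never 0.

Artifactual breaks from over-fixation colocalize with nucleosomes, so
their autocorrelation is periodic at the nucleosome repeat length
(~162 bp in *S. cerevisiae*), and their cross-correlation with
linker-enriched MNase-seq coverage peaks at ±80 bp (half a repeat);
genuine inter-nucleosomal breaks peak at 0 instead.

**Period estimation.** The autocorrelation is smoothed with a centered
moving average of width 5 — wide enough to suppress single-lag noise,
narrow enough to resolve 80 from 162 — and strict local maxima within
the search range (default 50–400) that exceed a $3/\sqrt{n}$ null band
are collected. The highest maximum wins; maxima within 1% of the best
are treated as ties resolved toward the smallest lag, because a perfectly
periodic signal has equal peaks at every harmonic of the true period.
The reported lag is refined to the unsmoothed maximum within half the
smoothing window. At the acceptance problem size (1 Mb, $10^5$ breaks,
20 nt jitter) the estimator localizes the peak to within ±2 bp of the
repeat.

**Noise classification.** Over lags −400..400: a global maximum within
±20 means breaks between nucleosomes; otherwise the dominant local
maximum on each side of zero must fall in 60–100 bp and clear the null
band for the within-nucleosome verdict; anything else is unpatterned.
Taking the dominant maximum *per side* rather than the two largest
overall is robust to a jagged broad peak contributing two local maxima on
the same side. All three band thresholds are arguments.

## The G-quadruplex scanner

A G4 motif is four guanine tracts of 3–5 nt separated by three loops of
1 to `max_loop` nt (canonical scans use 7; long-loop scans 16).
Configurations:

* `intra+` — all tracts G runs on the plus strand;
* `intra-` — the same pattern on the reverse complement, reported in
  plus-strand coordinates;
* `inter` — tracts are independently G runs (guanines on +) or C runs
  (guanines on −) with at least one of each letter; pure-G/pure-C
  patterns are intra motifs and excluded. The four-tract mixed-letter
  rule is this package's documented interpretation of inter-strand
  topology; finer physical constraints on allowed tract orders are not
  modeled.

**Disambiguation.** One genomic locus should yield one motif. Per
configuration the scanner reports a maximal set of non-overlapping motifs
by leftmost-start greedy selection; among decompositions sharing a start
the preference is applied left to right — longest first tract, then
shortest first loop, then longest second tract, and so on. For the intra
scanner this is precisely PCRE backtracking order of
`G{3,5}([ACGT]{1,L}?G{3,5}){3}`, so the regex engine implements the
policy directly; the inter scanner realizes the same order with an
explicit first-success search over homopolymer-run extents. An
`overlapping = TRUE` mode reports the preferred decomposition at *every*
start, used by the test suite to compare against an exhaustive
decomposition oracle. One consequence of direction-dependent greediness:
intra+/intra− motif sets mirror exactly under reverse complementation
(by construction), while inter selection can differ between directions —
the tests therefore check inter symmetry at the decomposition level.

Loop categories follow the fragility analysis: `L1-4` (all loops ≤ 4),
`L5-7` (all ≤ 7, at least one > 4), `L8-16` (all ≤ 16, at least one
> 7), plus fine groups `Lk` with `k` the longest loop. Flanks are the
adjacent regions of half the motif span on each side (left flank takes
the extra base for odd spans); so both flanks together match the motif
length. DSB densities (reads per nt, combined strands by default) are
compared inside vs flank with the paired Wilcoxon signed-rank test
(`stats::wilcox.test`, which switches between exact and normal
approximation at n = 50 by its own rule), across configurations with the
two-sided Kolmogorov–Smirnov test, and between paired samples (e.g. wild
type vs a pif1 helicase mutant) with the paired Wilcoxon test per motif.
Meta-profiles average the break signal in a 200 bp window centered on
motif centers (even spans center left-of-center) in 10 bp bins.
Loop-level breakability compares mean densities of loops of each length
1–7 against seeded random control regions of the same length.

## Permutation enrichment

With windows tiling the genome and a subset labeled DSB-rich, the
observed overlap is the proportion of *mappable* nucleotides of the
DSB-rich windows inside the feature, the expected overlap the same
proportion over all windows, and the statistic their ratio. The label
multiset is permuted over windows (default 1000 permutations, seeded;
windows are first put in canonical coordinate order so the P value is
invariant to input row order), and the one-sided empirical P in the
observed direction uses the +1 correction
$(1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$, ties counting toward
the tail — conservative and never zero. A helper defines promoters as
500 nt upstream of the TSS (a package convention, flag-adjustable).

## The synthetic-data generator

The generator emulates the study conditions so the pipeline is testable
at desk scale:

* **Genomes** — i.i.d. bases at a chosen GC fraction (default 0.38, the
  yeast average). Real genomes have repeats, homopolymers and skewed
  composition; the mappability module handles those, but most simulated
  genomes are nearly fully unique — tests that need unmappable regions
  construct them explicitly.
* **Nucleosome-patterned background** — dyads placed by a random walk
  with mean step `repeat_len` (default 162 nt) and step sd
  `lattice_jitter_sd` (default 10 nt), breaks drawn at dyads (or linker
  midpoints) with per-break Gaussian jitter (default sd 20 nt). The
  random-walk lattice reproduces the distance-dependent decay of
  nucleosome phasing seen in real chromatin (statistical positioning);
  without it all harmonics of the repeat would have asymptotically equal
  autocorrelation peaks and "the highest maximum" would be ill-defined.
* **MNase-like coverage** — positions drawn with weight
  `enrichment_fold` (default 10) inside linkers and 1 elsewhere, on the
  *same* lattice as the break simulation when given the same seed — the
  property that makes break/MNase cross-correlation meaningful.
* **Digests** — cut events Poisson in total with multinomial site
  assignment, expected per-site count
  `n_cells x dilution x cutting_fraction` (dilution expresses mixing
  cells carrying a cut site into a wild-type excess, e.g. `1e-5` for
  1:100,000); each event yields a `+` end and a `-` end at the blunted
  cut coordinates; uniform Poisson background; optional Gaussian end
  jitter and geometric resection that shifts labeled ends away from the
  cut (off by default).
* **Reads** — sonication fragments from a clipped normal (mean 400 nt,
  sd 80, matching the protocol's target fragment size), proximal read
  from the break end inward, distal read from the sheared end, i.i.d.
  substitution errors. Truth alignments are emitted alongside so tests
  can bypass an external aligner; events too close to a chromosome edge
  to fit a full read are dropped and recorded. PCR/GC bias, optical
  duplicates and indel errors are not modeled — so passing tests
  demonstrate correctness of the accounting, not robustness to every
  real-library artifact.

All outputs are bit-reproducible under a fixed seed; each function
isolates its RNG use so callers' RNG state is untouched.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to make every
stochastic check statistically decisive on a single CPU in well under a
minute per check: 1 Mb genomes with $10^5$ breaks for period estimation;
$10^4$ windows with ~200 reads each for null calibration of the
hypergeometric test (large per-window counts keep the discrete P value
grid fine enough that `P < 0.05` occurs at close to 5%); 100 kb random
sequence for scanner-vs-oracle equality; 200 runs of 199 permutations
for enrichment calibration (the attainable grid makes `P < 0.05` occur
at exactly 9/200 under the null). Degenerate inputs are defined, not
worked around: zero-variance correlation overlaps are missing values, a
paired Wilcoxon with all-zero differences is reported as absent rather
than P = 1, empty profiles yield zero fractions with an explicit
`no_reads` flag, and empty FASTA/BED records are errors with line
numbers.

## Known limitations

* Exact-match mappability is stricter than mismatch-tolerant aligner
  uniqueness; k defaults to the trimmed read length.
* The Bonferroni multiplier counts testable windows; with very sparse
  mappability this is anti-conservative relative to counting all windows
  (flag available).
* Inter-strand G4 topology constraints beyond the mixed-letter rule are
  not modeled.
* Off-target identity is ungapped; indel-containing near-sites score
  low.
* Absolute per-cell DSB frequencies (spike-in calibration) are out of
  scope; all quantities are per-library or per-million-read relative.
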