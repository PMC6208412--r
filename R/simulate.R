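# Synthetic-data generator: genomes, nucleosome-patterned break profiles,
# MNase-like coverage, enzyme digests and barcoded read pairs with known
# ground truth. Every function is deterministic under its seed.

#' Simulate a random genome
#'
#' I.i.d. bases at the requested GC fraction (default 0.38, the budding
#' yeast genome average).
#'
#' @param length Chromosome length(s); a vector yields multiple
#'   chromosomes named \code{chr1}, \code{chr2}, ...
#' @param gc GC fraction in \code{[0, 1]}.
#' @param seed RNG seed.
#' @return Named \code{DNAStringSet}.
#' @export
simulate_genome <- function(length, gc = 0.38, seed) {
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(length, function(n) {
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_along(seqs))
    out
  })
}

# Nucleosome dyad lattice: a random walk with mean step `repeat_len` and
# step sd `lattice_jitter_sd`, starting near repeat_len/2. The random-walk
# construction reproduces the distance-dependent decay of nucleosome
# phasing seen in real chromatin (statistical positioning), which is what
# makes the fundamental period dominate its harmonics in autocorrelation.
# Drawn first in the RNG stream so that break and MNase simulations with
# the same seed share the same lattice.
.nucleosome_lattice <- function(genome_length, repeat_len,
                                lattice_jitter_sd) {
  n_max <- ceiling(genome_length / repeat_len) + 2L
  steps <- repeat_len + stats::rnorm(n_max, 0, lattice_jitter_sd)
  dyads <- round(repeat_len / 2 + cumsum(c(0, steps)))
  dyads[dyads >= 0 & dyads < genome_length]
}

#' Simulate nucleosome-patterned background breaks
#'
#' Artifact breaks tied to nucleosome organization: positions are drawn at
#' nucleosome dyads (\code{mode = "dyad"}, the over-fixation noise
#' signature) or at linker midpoints (\code{mode = "linker"}), with
#' per-break Gaussian jitter. The underlying dyad lattice has the given
#' mean repeat and phasing that decays with distance (see
#' \code{lattice_jitter_sd}).
#'
#' @param genome_length Genome length in nt (single chromosome
#'   \code{chr1}).
#' @param repeat_len Nucleosome repeat length in nt (default 162, the
#'   budding-yeast dyad-to-dyad spacing).
#' @param jitter_sd Per-break Gaussian jitter sd in nt (default 20).
#' @param n_breaks Number of breaks to draw.
#' @param seed RNG seed.
#' @param mode \code{"dyad"} or \code{"linker"}.
#' @param lattice_jitter_sd Sd of the lattice random-walk step (default
#'   10), controlling how fast phasing decays.
#' @return A raw-count \code{BreakProfile} (strands assigned at random).
#' @export
simulate_nucleosomal_background <- function(genome_length,
                                            repeat_len = 162L,
                                            jitter_sd = 20,
                                            n_breaks, seed,
                                            mode = c("dyad", "linker"),
                                            lattice_jitter_sd = 10) {
  mode <- match.arg(mode)
  stopifnot(repeat_len >= 20L, n_breaks >= 1L)
  with_seed(seed, {
    dyads <- .nucleosome_lattice(genome_length, repeat_len,
                                 lattice_jitter_sd)
    centers <- if (mode == "dyad") dyads else
      round((dyads[-length(dyads)] + dyads[-1]) / 2)
    pick <- centers[sample.int(length(centers), n_breaks, replace = TRUE)]
    pos <- round(pick + stats::rnorm(n_breaks, 0, jitter_sd))
    pos <- pmin(pmax(pos, 0L), genome_length - 1L)
    strand <- sample(c("+", "-"), n_breaks, replace = TRUE)
    prof <- break_profile(c(chr1 = genome_length))
    prof$plus$chr1 <- tabulate(pos[strand == "+"] + 1L,
                               nbins = genome_length)
    prof$minus$chr1 <- tabulate(pos[strand == "-"] + 1L,
                                nbins = genome_length)
    prof$total_mapped <- n_breaks
    prof
  })
}

#' Simulate MNase-like linker-enriched coverage
#'
#' Coverage drawn with per-position weight \code{enrichment_fold} inside
#' linker regions (windows of \code{linker_len} nt centered between
#' consecutive nucleosome dyads) and 1 elsewhere — the convention in which
#' MNase signal is elevated in nucleosome-depleted regions. With the same
#' \code{seed}, \code{genome_length}, \code{repeat_len} and
#' \code{lattice_jitter_sd}, the lattice is identical to the one used by
#' \code{\link{simulate_nucleosomal_background}}.
#'
#' @param genome_length Genome length in nt.
#' @param repeat_len Nucleosome repeat length (default 162).
#' @param linker_len Linker width in nt (default 50).
#' @param enrichment_fold Linker:core weight ratio (default 10).
#' @param n_reads Number of coverage reads to draw.
#' @param seed RNG seed.
#' @param lattice_jitter_sd Lattice random-walk step sd (default 10).
#' @return A \code{BreakProfile}-shaped coverage object.
#' @export
simulate_mnase <- function(genome_length, repeat_len = 162L,
                           linker_len = 50L, enrichment_fold = 10,
                           n_reads, seed, lattice_jitter_sd = 10) {
  stopifnot(linker_len < repeat_len)
  with_seed(seed, {
    dyads <- .nucleosome_lattice(genome_length, repeat_len,
                                 lattice_jitter_sd)
    mids <- round((dyads[-length(dyads)] + dyads[-1]) / 2)
    w <- rep(1, genome_length)
    half <- linker_len %/% 2L
    for (m in mids) {
      a <- max(1L, m + 1L - half)
      b <- min(genome_length, m + 1L + half)
      w[a:b] <- enrichment_fold
    }
    pos <- sample.int(genome_length, n_reads, replace = TRUE, prob = w) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    prof <- break_profile(c(chr1 = genome_length))
    prof$plus$chr1 <- tabulate(pos[strand == "+"] + 1L,
                               nbins = genome_length)
    prof$minus$chr1 <- tabulate(pos[strand == "-"] + 1L,
                                nbins = genome_length)
    prof$total_mapped <- n_reads
    prof
  })
}

#' Simulate an endonuclease digest
#'
#' Places labeled break-end events at enzyme cut sites and uniformly
#' distributed background breaks. Each cut event produces two labeled ends:
#' a plus-strand end at the site's \code{plus_end} and a minus-strand end
#' at its \code{minus_end} (blunted coordinates; see
#' \code{\link{find_sites}}). The expected number of cut events per site is
#' \code{n_cells * dilution * cutting_fraction}; the realized total is
#' Poisson and events are assigned to sites multinomially. Optional
#' resection shifts each labeled end geometrically away from the cut.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param enzymes Data frame of enzyme specs
#'   (\code{\link{load_enzymes}} format, with \code{cutting_fraction}).
#' @param n_cells Number of cells carrying the cut site(s).
#' @param dilution Fraction of cells carrying breaks after mixing with
#'   uncut cells (e.g. \code{1e-4} for a 1:10,000 dilution; default 1).
#' @param background_rate Expected background breaks per nucleotide
#'   (default 0).
#' @param end_jitter_sd Gaussian sd of end-position jitter in nt
#'   (default 0).
#' @param seed RNG seed.
#' @param resection_mean If non-\code{NULL}, mean of a geometric resection
#'   length added to each labeled end, moving it away from the cut.
#' @return List with \code{profile} (truth \code{BreakProfile}),
#'   \code{events} (data frame \code{chrom}, \code{pos}, \code{strand},
#'   \code{origin}), and \code{sites} (all sites with expected ends).
#' @export
simulate_digest <- function(genome, enzymes, n_cells = 1e4, dilution = 1,
                            background_rate = 0, end_jitter_sd = 0, seed,
                            resection_mean = NULL) {
  stopifnot(dilution >= 0, dilution <= 1, background_rate >= 0)
  sl <- .genome_seqlengths(genome)
  site_list <- lapply(seq_len(nrow(enzymes)), function(i) {
    s <- find_sites(genome, enzymes[i, ])
    s$cutting_fraction <- enzymes$cutting_fraction[i] %||% 1
    s
  })
  sites <- do.call(rbind, site_list)
  with_seed(seed, {
    events <- list()
    if (!is.null(sites) && nrow(sites)) {
      e_site <- n_cells * dilution * sites$cutting_fraction
      n_events <- stats::rpois(1, sum(e_site))
      if (n_events > 0) {
        pick <- sample.int(nrow(sites), n_events, replace = TRUE,
                           prob = e_site)
        events[[1]] <- data.frame(
          chrom = rep(sites$chrom[pick], 2L),
          pos = c(sites$plus_end[pick], sites$minus_end[pick]),
          strand = rep(c("+", "-"), each = n_events),
          origin = rep(sites$name[pick], 2L),
          site = rep(pick, 2L))
      }
    }
    n_bg <- stats::rpois(1, background_rate * sum(sl))
    if (n_bg > 0) {
      ch <- sample(names(sl), n_bg, replace = TRUE, prob = sl / sum(sl))
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch,
        pos = vapply(ch, function(c0) sample.int(sl[[c0]], 1L) - 1L,
                     numeric(1)),
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        origin = "background", site = NA_integer_)
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(chrom = character(), pos = integer(),
                 strand = character(), origin = character(),
                 site = integer())
    if (nrow(ev)) {
      if (!is.null(resection_mean)) {
        shift <- stats::rgeom(nrow(ev), 1 / (1 + resection_mean))
        ev$pos <- ev$pos + ifelse(ev$strand == "+", shift, -shift)
      }
      if (end_jitter_sd > 0) {
        ev$pos <- round(ev$pos + stats::rnorm(nrow(ev), 0, end_jitter_sd))
      }
      ev$pos <- pmin(pmax(ev$pos, 0L), sl[ev$chrom] - 1L)
    }
    rownames(ev) <- NULL
    prof <- break_profile(sl)
    for (ch in unique(ev$chrom)) {
      for (st in c("+", "-")) {
        sel <- ev$chrom == ch & ev$strand == st
        slot <- if (st == "+") "plus" else "minus"
        prof[[slot]][[ch]] <- tabulate(ev$pos[sel] + 1L, nbins = sl[[ch]])
      }
    }
    prof$total_mapped <- nrow(ev)
    list(profile = prof, events = ev, sites = sites)
  })
}

#' Emit barcoded paired reads for labeled break ends
#'
#' For every labeled end, draws a sonication fragment (clipped normal
#' length, mean 400 nt as in the i-BLESS protocol) extending from the
#' break end into the genome, and emits read 1 = proximal barcode +
#' genomic sequence starting at the break end, read 2 = distal barcode +
#' reverse-complemented sequence from the sheared far end. Substitution
#' errors are applied at \code{error_rate} over the whole read (barcode
#' included). Truth alignments for the trimmed proximal reads are returned
#' so tests can bypass an external aligner.
#'
#' @param events Event data frame from \code{\link{simulate_digest}}
#'   (\code{chrom}, \code{pos}, \code{strand}).
#' @param genome \code{DNAStringSet} or named character vector.
#' @param read_len Genomic read length after barcode trimming
#'   (default 50).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed RNG seed.
#' @param fragment_mean,fragment_sd Sonication fragment length model
#'   (clipped normal; defaults 400 and 80).
#' @return List with \code{r1}, \code{r2} (lists of \code{id}, \code{seq},
#'   \code{qual}), \code{truth}: the proximal-read alignments
#'   (\code{chrom}, \code{pos}, \code{length}, \code{strand}, \code{name})
#'   plus the break position per read, and \code{kept}: indices of the
#'   input events close enough to no chromosome edge for a full read
#'   (others are dropped).
#' @export
emit_fastq <- function(events, genome, read_len = 50L, error_rate = 0,
                       seed, fragment_mean = 400, fragment_sd = 80) {
  stopifnot(error_rate >= 0, error_rate < 1)
  chr <- .genome_chr(genome)
  sl <- vapply(chr, nchar, integer(1))
  # a full proximal read must fit between the break end and the
  # chromosome edge; events too close to an edge are dropped (recorded in
  # `kept`)
  fit <- ifelse(events$strand == "+",
                events$pos + read_len <= sl[events$chrom],
                events$pos - read_len + 1L >= 0L)
  kept <- which(fit)
  events <- events[fit, , drop = FALSE]
  n <- nrow(events)
  with_seed(seed, {
    fl <- pmax(read_len + 1L,
               round(stats::rnorm(n, fragment_mean, fragment_sd)))
    pos <- events$pos
    plus <- events$strand == "+"
    # clip fragments at chromosome ends
    fl <- ifelse(plus, pmin(fl, sl[events$chrom] - pos),
                 pmin(fl, pos + 1L))
    fl <- pmax(fl, read_len)
    r1_start <- ifelse(plus, pos, pos - read_len + 1L)
    far_start <- ifelse(plus, pos + fl - read_len, pos - fl + 1L)
    g1 <- substring(chr[events$chrom], r1_start + 1L,
                    r1_start + read_len)
    g2 <- substring(chr[events$chrom], far_start + 1L,
                    far_start + read_len)
    # read 1 reads off the break end inward; read 2 off the sheared end
    r1_seq <- ifelse(plus, g1, revcomp(g1))
    r2_seq <- ifelse(plus, revcomp(g2), g2)
    ids <- sprintf("sim_%06d", seq_len(n))
    r1 <- paste0(IBLESS_BARCODES[["proximal"]], r1_seq)
    r2 <- paste0(IBLESS_BARCODES[["distal"]], r2_seq)
    if (error_rate > 0) {
      mutate <- function(reads) {
        chars <- strsplit(reads, "", fixed = TRUE)
        vapply(chars, function(x) {
          hit <- stats::runif(length(x)) < error_rate
          if (any(hit)) {
            x[hit] <- vapply(x[hit], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1L)
            }, character(1))
          }
          paste(x, collapse = "")
        }, character(1))
      }
      r1 <- mutate(r1)
      r2 <- mutate(r2)
    }
    qual <- strrep("I", nchar(r1))
    truth <- data.frame(chrom = events$chrom, pos = r1_start,
                        length = read_len, strand = events$strand,
                        name = ids, break_pos = events$pos)
    list(r1 = list(id = ids, seq = r1, qual = qual),
         r2 = list(id = ids, seq = r2, qual = strrep("I", nchar(r2))),
         truth = truth, kept = kept)
  })
}
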