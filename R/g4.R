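# G-quadruplex motif scanning (intra- and inter-strand), loop-length
# classification and DSB-density fragility statistics.

#' G4 scan configuration
#'
#' @param tract_range Guanine-tract length range (default \code{c(3, 5)}).
#' @param max_loop Maximum loop length, 1..16 (default 7 — the canonical
#'   G3-5 N1-7 motif; long-loop scans use up to 16).
#' @param configurations Subset of \code{c("intra+", "intra-", "inter")}.
#' @return List of class \code{G4ScanConfig}.
#' @export
g4_config <- function(tract_range = c(3L, 5L), max_loop = 7L,
                      configurations = c("intra+", "intra-", "inter")) {
  stopifnot(length(tract_range) == 2L, tract_range[1] >= 1L,
            tract_range[2] >= tract_range[1],
            max_loop >= 1L, max_loop <= 16L,
            all(configurations %in% c("intra+", "intra-", "inter")))
  structure(list(tract_range = as.integer(tract_range),
                 max_loop = as.integer(max_loop),
                 configurations = configurations),
            class = "G4ScanConfig")
}

.empty_motifs <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             configuration = character(),
             t1 = integer(), l1 = integer(), t2 = integer(), l2 = integer(),
             t3 = integer(), l3 = integer(), t4 = integer(),
             loop1_start = integer(), loop1_end = integer(),
             loop2_start = integer(), loop2_end = integer(),
             loop3_start = integer(), loop3_end = integer(),
             tract_letters = character())
}

# Assemble motif rows from 0-based starts (on the scanned strand) and the
# seven component lengths; coords are then on the scanned sequence.
.assemble_motifs <- function(chrom, starts0, comp, configuration, letters) {
  t1 <- comp[, 1]; l1 <- comp[, 2]; t2 <- comp[, 3]; l2 <- comp[, 4]
  t3 <- comp[, 5]; l3 <- comp[, 6]; t4 <- comp[, 7]
  loop1_start <- starts0 + t1
  loop2_start <- loop1_start + l1 + t2
  loop3_start <- loop2_start + l2 + t3
  data.frame(chrom = chrom, start = starts0,
             end = starts0 + t1 + l1 + t2 + l2 + t3 + l3 + t4,
             configuration = configuration,
             t1 = t1, l1 = l1, t2 = t2, l2 = l2, t3 = t3, l3 = l3, t4 = t4,
             loop1_start = loop1_start, loop1_end = loop1_start + l1,
             loop2_start = loop2_start, loop2_end = loop2_start + l2,
             loop3_start = loop3_start, loop3_end = loop3_start + l3,
             tract_letters = letters)
}

# Flip motif rows scanned on the reverse complement of a chromosome of
# length L back into + strand coordinates. Component lengths stay in
# scanned (5'->3' on the - strand) order; intervals are mirrored.
.mirror_motifs <- function(m, L) {
  if (!nrow(m)) return(m)
  flip <- function(s, e) list(start = L - e, end = L - s)
  sp <- flip(m$start, m$end)
  l1 <- flip(m$loop1_start, m$loop1_end)
  l2 <- flip(m$loop2_start, m$loop2_end)
  l3 <- flip(m$loop3_start, m$loop3_end)
  m$start <- sp$start; m$end <- sp$end
  m$loop1_start <- l1$start; m$loop1_end <- l1$end
  m$loop2_start <- l2$start; m$loop2_end <- l2$end
  m$loop3_start <- l3$start; m$loop3_end <- l3$end
  m
}

# PCRE for one G4 strand pattern with capture groups per component.
.g4_regex <- function(tract_range, max_loop, letter = "G",
                      overlapping = FALSE) {
  tract <- sprintf("%s{%d,%d}", letter, tract_range[1], tract_range[2])
  loop <- sprintf("([ACGT]{1,%d}?)", max_loop)
  core <- paste0("(", tract, ")", loop, "(", tract, ")", loop,
                 "(", tract, ")", loop, "(", tract, ")")
  if (overlapping) paste0("(?=", core, ")") else core
}

# Run one regex scan, return 0-based starts and 7-column component lengths.
# With the non-overlapping pattern, PCRE's leftmost-match + backtracking
# order (greedy tracts, lazy loops, left to right) implements the
# maximal-tract / shortest-loop disambiguation and the leftmost-start greedy
# non-overlap policy directly.
.scan_regex <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  list(starts0 = cs[, 1] - 1L, comp = cl)
}

#' Scan a genome for intra-strand G4 motifs
#'
#' Matches the four-guanine-tract pattern
#' \code{G\{3,5\}(N\{1,max_loop\}G\{3,5\})\{3\}} on the + strand
#' (configuration \code{intra+}) and on the reverse complement
#' (\code{intra-}, reported in + strand coordinates). Per configuration a
#' maximal set of non-overlapping motifs is reported by leftmost-start
#' greedy selection; among decompositions sharing a start the preference is
#' applied left to right: longest first tract, then shortest first loop,
#' then longest second tract, and so on.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param config A \code{\link{g4_config}}; its \code{configurations} entry
#'   selects \code{intra+} / \code{intra-}.
#' @param overlapping If \code{TRUE}, report the preferred decomposition at
#'   every possible start instead of the greedy non-overlapping set (used
#'   for oracle comparison).
#' @return Motif data frame (0-based half-open \code{start}/\code{end},
#'   component lengths \code{t1..t4}, \code{l1..l3}, genomic loop
#'   sub-intervals, loop \code{category} and \code{group}).
#' @export
find_intrastrand_g4 <- function(genome, config = g4_config(),
                                overlapping = FALSE) {
  stopifnot(inherits(config, "G4ScanConfig"))
  chr <- .genome_chr(genome)
  pat <- .g4_regex(config$tract_range, config$max_loop, "G", overlapping)
  out <- list()
  for (ch in names(chr)) {
    L <- nchar(chr[[ch]])
    if ("intra+" %in% config$configurations) {
      h <- .scan_regex(chr[[ch]], pat)
      if (!is.null(h)) {
        out[[length(out) + 1L]] <-
          .assemble_motifs(ch, h$starts0, h$comp, "intra+", "GGGG")
      }
    }
    if ("intra-" %in% config$configurations) {
      h <- .scan_regex(revcomp(chr[[ch]]), pat)
      if (!is.null(h)) {
        m <- .assemble_motifs(ch, h$starts0, h$comp, "intra-", "GGGG")
        out[[length(out) + 1L]] <- .mirror_motifs(m, L)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_motifs()
  classify_loops(res)
}

# Lengths of homopolymer runs of `letter` extending right from each position.
.run_extents <- function(seq_chars, letter) {
  mask <- seq_chars == letter
  r <- rle(mask)
  ext <- integer(length(mask))
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      ext[pos[i]:(pos[i] + r$lengths[i] - 1L)] <- r$lengths[i]:1L
    }
  }
  ext
}

# First-success decomposition attempt at 1-based start p for the inter
# configuration: each tract is a homopolymer run of G or C (letter fixed by
# the sequence), loops are any 1..max_loop nt, and the four tract letters
# must include both G and C. Iteration order (t1 = 5..3, l1 = 1..max_loop,
# t2 = 5..3, ...) realizes the documented left-to-right preference.
.inter_attempt <- function(gext, cext, letters, p, tract_range, max_loop) {
  n <- length(gext)
  tmax <- tract_range[2]; tmin <- tract_range[1]
  ext1 <- max(gext[p], cext[p])
  if (ext1 < tmin) return(NULL)
  for (t1 in min(tmax, ext1):tmin) {
    for (l1 in 1:max_loop) {
      p2 <- p + t1 + l1
      if (p2 > n) break
      ext2 <- max(gext[p2], cext[p2])
      if (ext2 < tmin) next
      for (t2 in min(tmax, ext2):tmin) {
        for (l2 in 1:max_loop) {
          p3 <- p2 + t2 + l2
          if (p3 > n) break
          ext3 <- max(gext[p3], cext[p3])
          if (ext3 < tmin) next
          for (t3 in min(tmax, ext3):tmin) {
            for (l3 in 1:max_loop) {
              p4 <- p3 + t3 + l3
              if (p4 > n) break
              ext4 <- max(gext[p4], cext[p4])
              if (ext4 < tmin) next
              for (t4 in min(tmax, ext4):tmin) {
                if (p4 + t4 - 1L > n) next
                lets <- letters[c(p, p2, p3, p4)]
                if (all(lets == "G") || all(lets == "C")) next
                return(list(comp = c(t1, l1, t2, l2, t3, l3, t4),
                            letters = paste(lets, collapse = "")))
              }
            }
          }
        }
      }
    }
  }
  NULL
}

#' Scan a genome for inter-strand G4 motifs
#'
#' Inter-strand quadruplexes draw their four guanine tracts from both
#' strands: on the + strand sequence each tract is a run of \code{G}
#' (guanines on +) or of \code{C} (guanines on -), with at least one tract
#' of each letter; pure-G and pure-C patterns are intra-strand motifs and
#' are excluded. Loops and the disambiguation/greedy policy are as in
#' \code{\link{find_intrastrand_g4}}.
#'
#' @inheritParams find_intrastrand_g4
#' @return Motif data frame with \code{configuration = "inter"};
#'   \code{tract_letters} records the tract pattern (e.g. \code{"GCGC"}).
#' @export
find_interstrand_g4 <- function(genome, config = g4_config(),
                                overlapping = FALSE) {
  stopifnot(inherits(config, "G4ScanConfig"))
  chr <- .genome_chr(genome)
  tmin <- config$tract_range[1]
  out <- list()
  for (ch in names(chr)) {
    s <- strsplit(chr[[ch]], "", fixed = TRUE)[[1]]
    gext <- .run_extents(s, "G")
    cext <- .run_extents(s, "C")
    cand <- which(gext >= tmin | cext >= tmin)
    starts <- integer(); comps <- list(); lets <- character()
    nextpos <- 1L
    for (p in cand) {
      if (!overlapping && p < nextpos) next
      hit <- .inter_attempt(gext, cext, s, p, config$tract_range,
                            config$max_loop)
      if (is.null(hit)) next
      starts[length(starts) + 1L] <- p - 1L
      comps[[length(comps) + 1L]] <- hit$comp
      lets[length(lets) + 1L] <- hit$letters
      if (!overlapping) nextpos <- p + sum(hit$comp)
    }
    if (length(starts)) {
      out[[length(out) + 1L]] <-
        .assemble_motifs(ch, starts, do.call(rbind, comps), "inter", lets)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_motifs()
  classify_loops(res)
}

#' Scan for G4 motifs in all requested configurations
#'
#' @inheritParams find_intrastrand_g4
#' @return Combined motif data frame, sorted by chromosome and start.
#' @export
find_g4 <- function(genome, config = g4_config(), overlapping = FALSE) {
  parts <- list()
  if (any(c("intra+", "intra-") %in% config$configurations)) {
    parts[[1]] <- find_intrastrand_g4(genome, config, overlapping)
  }
  if ("inter" %in% config$configurations) {
    parts[[length(parts) + 1L]] <- find_interstrand_g4(genome, config,
                                                       overlapping)
  }
  res <- do.call(rbind, parts)
  res <- res[order(res$chrom, res$start, res$configuration), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify G4 motifs by loop length
#'
#' Adds the three-way loop category (\code{L1-4}: all loops <= 4 nt;
#' \code{L5-7}: all <= 7 nt, at least one > 4; \code{L8-16}: all <= 16, at
#' least one > 7) and the fine-grained group \code{Lk}, where \code{k} is
#' the longest loop.
#'
#' @param motifs Motif data frame with columns \code{l1}, \code{l2},
#'   \code{l3}.
#' @return The input with columns \code{category} and \code{group} added.
#' @export
classify_loops <- function(motifs) {
  if (!nrow(motifs)) {
    motifs$category <- character(0)
    motifs$group <- character(0)
    return(motifs)
  }
  mx <- pmax(motifs$l1, motifs$l2, motifs$l3)
  motifs$category <- cut(mx, breaks = c(0, 4, 7, 16),
                         labels = c("L1-4", "L5-7", "L8-16"))
  motifs$category <- as.character(motifs$category)
  motifs$group <- paste0("L", mx)
  motifs
}

#' Flanking regions of G4 motifs
#'
#' Left and right regions adjacent to each motif, each half the motif span
#' (the left flank takes the extra base for odd spans), truncated at
#' chromosome ends with a flag.
#'
#' @param motifs Motif data frame.
#' @param seqlengths Named chromosome lengths, or a genome object.
#' @return Data frame with \code{left_start}, \code{left_end},
#'   \code{right_start}, \code{right_end}, \code{truncated}.
#' @export
g4_flanks <- function(motifs, seqlengths) {
  if (inherits(seqlengths, "DNAStringSet") || is.character(seqlengths)) {
    seqlengths <- .genome_seqlengths(seqlengths)
  }
  span <- motifs$end - motifs$start
  left_len <- ceiling(span / 2)
  right_len <- span - left_len
  sl <- seqlengths[motifs$chrom]
  ls <- pmax(0L, motifs$start - left_len)
  re <- pmin(as.integer(sl), motifs$end + right_len)
  data.frame(chrom = motifs$chrom,
             left_start = ls, left_end = motifs$start,
             right_start = motifs$end, right_end = re,
             truncated = (ls > motifs$start - left_len) |
               (re < motifs$end + right_len))
}

#' Long-format table of G4 loop sub-intervals
#'
#' @param motifs Motif data frame.
#' @return Data frame with one row per loop: \code{chrom}, \code{start},
#'   \code{end}, \code{length}, \code{loop_index}, \code{motif_row},
#'   \code{configuration}.
#' @export
g4_loops <- function(motifs) {
  n <- nrow(motifs)
  if (!n) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      loop_index = integer(), motif_row = integer(),
                      configuration = character()))
  }
  out <- data.frame(
    chrom = rep(motifs$chrom, 3L),
    start = c(motifs$loop1_start, motifs$loop2_start, motifs$loop3_start),
    end = c(motifs$loop1_end, motifs$loop2_end, motifs$loop3_end),
    loop_index = rep(1:3, each = n),
    motif_row = rep(seq_len(n), 3L),
    configuration = rep(motifs$configuration, 3L)
  )
  out$length <- out$end - out$start
  out[order(out$motif_row, out$loop_index), ]
}

#' DSB density of genomic intervals
#'
#' Number of (combined-strand) break-profile counts in an interval divided
#' by its length. If the profile is normalized, the density is in
#' normalized units.
#'
#' @param profile A \code{BreakProfile}.
#' @param chrom,start,end Parallel interval vectors (0-based half-open), or
#'   a data frame in \code{chrom}.
#' @return Numeric vector of densities (counts per nucleotide).
#' @export
dsb_density <- function(profile, chrom, start = NULL, end = NULL) {
  stopifnot(inherits(profile, "BreakProfile"))
  if (is.data.frame(chrom)) {
    start <- chrom$start; end <- chrom$end; chrom <- chrom$chrom
  }
  if (any(end - start <= 0)) stop("zero-length interval in dsb_density")
  counts <- combined_counts(profile)
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    v <- counts[[ch]]
    if (is.null(v)) stop("unknown chromosome in dsb_density: ", ch)
    cs <- c(0, cumsum(v))
    sel <- which(chrom == ch)
    out[sel] <- (cs[end[sel] + 1L] - cs[start[sel] + 1L]) /
      (end[sel] - start[sel])
  }
  out
}

#' Averaged break signal around G4 centers (meta-profile)
#'
#' Aligns all motif centers (even spans center on the left-of-center base)
#' and averages the per-position break signal in a window of
#' \code{window} nt using \code{bin}-nt bins. Motifs whose window exceeds a
#' chromosome boundary are dropped.
#'
#' @param profile A \code{BreakProfile}.
#' @param motifs Motif data frame.
#' @param window Window width centered on motif centers (default 200).
#' @param bin Bin width (default 10).
#' @return Data frame with \code{bin_start} (position of bin start relative
#'   to the center), \code{mean_signal}, \code{n_motifs}.
#' @export
g4_meta_profile <- function(profile, motifs, window = 200L, bin = 10L) {
  stopifnot(inherits(profile, "BreakProfile"), window %% bin == 0)
  counts <- combined_counts(profile)
  half <- window %/% 2L
  centers <- motifs$start + (motifs$end - motifs$start) %/% 2L
  ok <- centers - half >= 0 &
    centers + half <= profile$seqlengths[motifs$chrom]
  centers <- centers[ok]
  chroms <- motifs$chrom[ok]
  nb <- window %/% bin
  acc <- matrix(0, nrow = length(centers), ncol = nb)
  for (i in seq_along(centers)) {
    v <- counts[[chroms[i]]][(centers[i] - half + 1L):(centers[i] + half)]
    acc[i, ] <- colMeans(matrix(v, nrow = bin))
  }
  data.frame(bin_start = seq.int(-half, half - 1L, by = bin),
             mean_signal = if (length(centers)) colMeans(acc) else
               rep(NA_real_, nb),
             n_motifs = length(centers))
}

#' G4 fragility report
#'
#' Per-motif DSB densities inside the motif and in its flanks, with the
#' classical tests used for G4 fragility analysis: paired Wilcoxon
#' signed-rank (inside vs flank, per loop category and overall; and wt vs
#' paired sample inside motifs when \code{paired_profile} is given), a
#' two-sided Kolmogorov-Smirnov comparison of intra- vs inter-strand inside
#' densities, and the center-aligned meta-profile.
#'
#' @param profile A \code{BreakProfile} (per-million normalization upstream
#'   recommended when comparing replicates).
#' @param motifs Motif data frame from \code{\link{find_g4}}.
#' @param paired_profile Optional second \code{BreakProfile} (e.g. a
#'   pif1-m2 mutant) for the paired per-motif comparison.
#' @param window,bin Meta-profile window and bin width.
#' @return List with \code{per_motif} (densities), \code{tests} (named list
#'   of \code{htest} results and P values), and \code{meta} (meta-profile
#'   data frame).
#' @export
g4_fragility_report <- function(profile, motifs, paired_profile = NULL,
                                window = 200L, bin = 10L) {
  if (nrow(motifs) < 2L) {
    stop("at least 2 motifs are required for fragility statistics")
  }
  fl <- g4_flanks(motifs, profile$seqlengths)
  inside <- dsb_density(profile, motifs)
  flank_counts <- function(prof) {
    cs <- lapply(combined_counts(prof), function(v) c(0, cumsum(v)))
    take <- function(ch, s, e) {
      ifelse(e > s, mapply(function(c0, s0, e0) cs[[c0]][e0 + 1L] -
                             cs[[c0]][s0 + 1L], ch, s, e), 0)
    }
    lc <- take(fl$chrom, fl$left_start, fl$left_end)
    rc <- take(fl$chrom, fl$right_start, fl$right_end)
    len <- (fl$left_end - fl$left_start) + (fl$right_end - fl$right_start)
    (lc + rc) / pmax(len, 1L)
  }
  flank <- flank_counts(profile)
  per_motif <- data.frame(motifs[, c("chrom", "start", "end",
                                     "configuration", "category")],
                          inside = inside, flank = flank)
  tests <- list()
  safe_wilcox <- function(x, y, ...) {
    if (all(x == y)) return(NULL)  # degenerate: no nonzero differences
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, ...))
  }
  tests$inside_vs_flank <- safe_wilcox(inside, flank,
                                       alternative = "greater")
  for (cat in unique(per_motif$category)) {
    sel <- per_motif$category == cat
    if (sum(sel) >= 2) {
      tests[[paste0("inside_vs_flank_", cat)]] <-
        safe_wilcox(inside[sel], flank[sel], alternative = "greater")
    }
  }
  is_intra <- motifs$configuration %in% c("intra+", "intra-")
  if (any(is_intra) && any(!is_intra)) {
    tests$intra_vs_inter <- suppressWarnings(
      stats::ks.test(inside[is_intra], inside[!is_intra]))
  }
  if (!is.null(paired_profile)) {
    inside2 <- dsb_density(paired_profile, motifs)
    per_motif$inside_paired <- inside2
    tests$paired_profiles <- safe_wilcox(inside2, inside)
  }
  list(per_motif = per_motif, tests = tests,
       meta = g4_meta_profile(profile, motifs, window, bin))
}

#' Loop breakability by loop length
#'
#' For each loop length, the mean DSB density over all G4 loops of that
#' length, compared with the mean density of randomly placed control
#' regions of the same length (restricted to mappable positions when a
#' track is given).
#'
#' @param profile A \code{BreakProfile}.
#' @param motifs Motif data frame carrying loop sub-intervals.
#' @param n_controls Number of random control regions per length
#'   (default 1000).
#' @param seed RNG seed for control placement (required for
#'   reproducibility).
#' @param lengths Loop lengths to tabulate (default \code{1:7}).
#' @param mappability Optional \code{MappabilityTrack} restricting control
#'   region starts.
#' @return Data frame with \code{length}, \code{n_loops}, \code{loop_mean},
#'   \code{control_mean}, \code{missing} (no loops of that length).
#' @export
loop_breakability <- function(profile, motifs, n_controls = 1000L, seed,
                              lengths = 1:7, mappability = NULL) {
  stopifnot(inherits(profile, "BreakProfile"))
  loops <- g4_loops(motifs)
  sl <- profile$seqlengths
  with_seed(seed, {
    res <- lapply(lengths, function(len) {
      sel <- loops$length == len
      loop_mean <- if (any(sel)) {
        mean(dsb_density(profile, loops[sel, c("chrom", "start", "end")]))
      } else NA_real_
      # controls: uniform over valid starts, same length
      ctl_chrom <- sample(names(sl), n_controls, replace = TRUE,
                          prob = sl / sum(sl))
      ctl_start <- vapply(ctl_chrom, function(ch) {
        ok <- sl[[ch]] - len
        s <- sample.int(ok, 1L) - 1L
        if (!is.null(mappability)) {
          mp <- which(mappability$mappable[[ch]][seq_len(ok)])
          if (length(mp)) s <- mp[sample.int(length(mp), 1L)] - 1L
        }
        s
      }, numeric(1))
      ctl <- data.frame(chrom = ctl_chrom, start = ctl_start,
                        end = ctl_start + len)
      data.frame(length = len, n_loops = sum(sel), loop_mean = loop_mean,
                 control_mean = mean(dsb_density(profile, ctl)),
                 missing = !any(sel))
    })
    do.call(rbind, res)
  })
}

#' Write G4 motifs as BED6+
#'
#' Name column is \code{configuration:category}; extra columns carry tract
#' and loop lengths.
#'
#' @param motifs Motif data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_g4_bed <- function(motifs, path) {
  strand <- ifelse(motifs$configuration == "intra+", "+",
                   ifelse(motifs$configuration == "intra-", "-", "."))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d,%d,%d,%d\t%d,%d,%d",
                     motifs$chrom, motifs$start, motifs$end,
                     paste0(motifs$configuration, ":", motifs$category),
                     strand, motifs$t1, motifs$t2, motifs$t3, motifs$t4,
                     motifs$l1, motifs$l2, motifs$l3),
             path)
  invisible(path)
}
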