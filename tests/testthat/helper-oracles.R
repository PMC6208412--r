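# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths (and where feasible the library
# calls) of the functions they check.

# --- hypergeometric upper tail by exhaustive pmf enumeration -------------
# P[X >= t], X ~ Hypergeom(N = TT + CC, K = TT, n = t + c), via choose().
oracle_hyper_upper <- function(t, c, TT, CC) {
  n <- t + c
  xs <- t:min(TT, n)
  xs <- xs[n - xs <= CC]
  if (!length(xs)) return(0)
  sum(exp(lchoose(TT, xs) + lchoose(CC, n - xs) - lchoose(TT + CC, n)))
}

# --- k-mer mappability by dictionary counting ----------------------------
# Reverse complement without Biostrings.
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# For every position of every chromosome: mappable iff the k-mer there
# occurs at exactly one genomic location considering both strands
# (inclusion-exclusion handles palindromes: a palindromic k-mer at one
# locus is one location).
oracle_mappability <- function(genome_chr, k) {
  all_kmers <- list()
  for (ch in names(genome_chr)) {
    n <- nchar(genome_chr[[ch]])
    if (n < k) { all_kmers[[ch]] <- character(); next }
    st <- seq_len(n - k + 1L)
    all_kmers[[ch]] <- substring(genome_chr[[ch]], st, st + k - 1L)
  }
  fwd <- unlist(all_kmers, use.names = FALSE)
  rcs <- oracle_revcomp(fwd)
  uq <- unique(fwd)
  cf <- tabulate(match(fwd, uq), nbins = length(uq))
  cr <- tabulate(match(rcs, uq), nbins = length(uq))
  cp <- tabulate(match(fwd[fwd == rcs], uq), nbins = length(uq))
  j <- match(fwd, uq)
  loc <- cf[j] + cr[j] - cp[j]   # locations across both strands
  ok <- loc == 1L & !grepl("N", fwd, fixed = TRUE)
  out <- list()
  offset <- 0L
  for (ch in names(genome_chr)) {
    n <- nchar(genome_chr[[ch]])
    v <- logical(n)
    nk <- length(all_kmers[[ch]])
    if (nk) {
      v[seq_len(nk)] <- ok[offset + seq_len(nk)]
      offset <- offset + nk
    }
    out[[ch]] <- v
  }
  out
}

# --- G4 exhaustive decomposition enumeration -----------------------------
# Every (start, t1, l1, t2, l2, t3, l3, t4) decomposition of the sequence
# into four homopolymer tracts of allowed letters separated by 1..max_loop
# arbitrary-ACGT loops. Returns a data.frame of all decompositions (1-based
# start), with the tract letter pattern.
oracle_g4_decompositions <- function(seq, letters, tract_range, max_loop) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ext <- lapply(letters, function(L) {
    e <- integer(n)
    run <- 0L
    for (i in n:1) {
      run <- if (chars[i] == L) run + 1L else 0L
      e[i] <- run
    }
    e
  })
  names(ext) <- letters
  tmin <- tract_range[1]; tmax <- tract_range[2]
  rows <- list()
  emit <- function(start, comp, lets) {
    rows[[length(rows) + 1L]] <<- c(start, comp,
                                    paste(lets, collapse = ""))
  }
  recurse <- function(p, depth, comp, lets) {
    if (p > n) return()
    L <- chars[p]
    if (!L %in% letters || ext[[L]][p] < tmin) return()
    for (t in tmin:min(tmax, ext[[L]][p])) {
      if (depth == 4L) {
        emit(comp[1], c(comp[-1], t), c(lets, L))
      } else {
        for (l in 1:max_loop) {
          nxt <- p + t + l
          if (nxt > n) break
          recurse(nxt, depth + 1L, c(comp, t, l), c(lets, L))
        }
      }
    }
  }
  for (p in seq_len(n)) {
    recurse(p, 1L, c(p), character())
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), t1 = integer(), l1 = integer(),
                      t2 = integer(), l2 = integer(), t3 = integer(),
                      l3 = integer(), t4 = integer(),
                      letters = character()))
  }
  m <- do.call(rbind, rows)
  num <- matrix(as.integer(m[, 1:8]), ncol = 8)
  out <- as.data.frame(num)
  names(out) <- c("start", "t1", "l1", "t2", "l2", "t3", "l3", "t4")
  out$letters <- m[, 9]
  out
}

# Preference key: longest tract then shortest loop, applied left to right.
# Among decompositions sharing a start, the best is the first under
# ordering by (-t1, l1, -t2, l2, -t3, l3, -t4).
oracle_g4_select <- function(dec, greedy = TRUE) {
  if (!nrow(dec)) return(dec)
  ord <- order(dec$start, -dec$t1, dec$l1, -dec$t2, dec$l2, -dec$t3,
               dec$l3, -dec$t4)
  dec <- dec[ord, , drop = FALSE]
  best <- dec[!duplicated(dec$start), , drop = FALSE]
  if (!greedy) return(best)
  keep <- logical(nrow(best))
  cur <- 1L
  for (i in seq_len(nrow(best))) {
    if (best$start[i] >= cur) {
      keep[i] <- TRUE
      cur <- best$start[i] + best$t1[i] + best$l1[i] + best$t2[i] +
        best$l2[i] + best$t3[i] + best$l3[i] + best$t4[i]
    }
  }
  best[keep, , drop = FALSE]
}

# Full oracle for one chromosome sequence and one configuration, in the
# scanner's output coordinates (0-based start on the + strand).
oracle_g4_scan <- function(seq, configuration, tract_range = c(3L, 5L),
                           max_loop = 7L, greedy = TRUE) {
  if (configuration == "intra+") {
    dec <- oracle_g4_decompositions(seq, "G", tract_range, max_loop)
    sel <- oracle_g4_select(dec, greedy)
    sel$start0 <- sel$start - 1L
  } else if (configuration == "intra-") {
    rc <- oracle_revcomp(seq)
    dec <- oracle_g4_decompositions(rc, "G", tract_range, max_loop)
    sel <- oracle_g4_select(dec, greedy)
    span <- sel$t1 + sel$l1 + sel$t2 + sel$l2 + sel$t3 + sel$l3 + sel$t4
    sel$start0 <- nchar(seq) - (sel$start - 1L) - span
  } else {
    dec <- oracle_g4_decompositions(seq, c("G", "C"), tract_range,
                                    max_loop)
    dec <- dec[dec$letters != strrep("G", 4) &
                 dec$letters != strrep("C", 4), , drop = FALSE]
    sel <- oracle_g4_select(dec, greedy)
    sel$start0 <- sel$start - 1L
  }
  sel <- sel[order(sel$start0), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

# Compare scanner motifs against the oracle for one chromosome.
expect_g4_equal <- function(motifs, oracle, chrom = "chr1") {
  m <- motifs[motifs$chrom == chrom, , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  expect_equal(nrow(m), nrow(oracle))
  if (nrow(m)) {
    expect_equal(m$start, oracle$start0)
    for (col in c("t1", "l1", "t2", "l2", "t3", "l3", "t4")) {
      expect_equal(m[[col]], oracle[[col]], label = col)
    }
  }
}

# --- misc ---------------------------------------------------------------
# Per-read brute-force profile builder (strand convention oracle).
oracle_profile <- function(records, seqlengths) {
  out <- list(plus = lapply(seqlengths, numeric),
              minus = lapply(seqlengths, numeric))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    p <- if (r$strand == "+") r$pos else r$pos + r$length - 1L
    slot <- if (r$strand == "+") "plus" else "minus"
    out[[slot]][[r$chrom]][p + 1L] <- out[[slot]][[r$chrom]][p + 1L] + 1
  }
  out
}

# Random sparse profile on a small genome, for round-trip tests.
random_profile <- function(seqlengths, n, seed) {
  withr::with_seed(seed, {
    recs <- data.frame(
      chrom = sample(names(seqlengths), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE))
    recs$length <- sample(20:50, n, replace = TRUE)
    recs$pos <- vapply(seq_len(n), function(i) {
      sample.int(seqlengths[[recs$chrom[i]]] - recs$length[i], 1L) - 1L
    }, numeric(1))
    recs
  })
}
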