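test_that("hand-enumerable motifs are found with correct geometry", {
  g <- c(chr1 = "GGGAGGGAGGGAGGG")
  m <- find_intrastrand_g4(g, g4_config(configurations = "intra+"))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 15L))
  expect_equal(unlist(m[, c("t1", "t2", "t3", "t4")], use.names = FALSE),
               rep(3L, 4))
  expect_equal(unlist(m[, c("l1", "l2", "l3")], use.names = FALSE),
               rep(1L, 3))
  expect_equal(m$category, "L1-4")
  expect_equal(m$group, "L1")

  mc <- find_intrastrand_g4(c(chr1 = "CCCTCCCTCCCTCCC"),
                            g4_config(configurations = "intra-"))
  expect_equal(nrow(mc), 1L)
  expect_equal(c(mc$start, mc$end), c(0L, 15L))
  expect_equal(mc$configuration, "intra-")

  expect_equal(nrow(find_intrastrand_g4(c(chr1 = "GGAGGAGGAGG"))), 0L)

  mi <- find_interstrand_g4(c(chr1 = "GGGACCCAGGGACCC"))
  expect_equal(nrow(mi), 1L)
  expect_equal(mi$tract_letters, "GCGC")
  expect_equal(c(mi$start, mi$end), c(0L, 15L))
  # pure-G pattern is never an inter motif
  expect_equal(nrow(find_interstrand_g4(c(chr1 = "GGGAGGGAGGGAGGG"))), 0L)
})

test_that("tract maximization and loop minimization follow the stated order", {
  # GGGG then GGG tracts: first tract takes 4 Gs
  m <- find_intrastrand_g4(c(chr1 = "GGGGAGGGAGGGAGGG"),
                           g4_config(configurations = "intra+"))
  expect_equal(m$t1, 4L)
  expect_equal(m$l1, 1L)
  # run of 6 Gs: greedy t1 = 5, loop absorbs the 6th G
  m2 <- find_intrastrand_g4(c(chr1 = "GGGGGGAGGGAGGGAGGGA"),
                            g4_config(configurations = "intra+"))
  expect_equal(m2$t1, 5L)
})

test_that("scanner equals the exhaustive decomposition oracle", {
  g <- simulate_genome(30000, gc = 0.55, seed = 71)
  seq1 <- as.character(g)[["chr1"]]
  for (ml in c(4L, 16L)) {
    cfg_p <- g4_config(max_loop = ml, configurations = "intra+")
    cfg_m <- g4_config(max_loop = ml, configurations = "intra-")
    cfg_i <- g4_config(max_loop = ml, configurations = "inter")
    expect_g4_equal(find_intrastrand_g4(g, cfg_p),
                    oracle_g4_scan(seq1, "intra+", max_loop = ml))
    expect_g4_equal(find_intrastrand_g4(g, cfg_m),
                    oracle_g4_scan(seq1, "intra-", max_loop = ml))
    expect_g4_equal(find_interstrand_g4(g, cfg_i),
                    oracle_g4_scan(seq1, "inter", max_loop = ml))
    # overlapping (all-starts) mode as well
    expect_g4_equal(find_intrastrand_g4(g, cfg_p, overlapping = TRUE),
                    oracle_g4_scan(seq1, "intra+", max_loop = ml,
                                   greedy = FALSE))
    expect_g4_equal(find_interstrand_g4(g, cfg_i, overlapping = TRUE),
                    oracle_g4_scan(seq1, "inter", max_loop = ml,
                                   greedy = FALSE))
  }
})

test_that("reverse-complementing the genome mirrors the motif sets", {
  g <- simulate_genome(20000, gc = 0.55, seed = 72)
  seq1 <- as.character(g)[["chr1"]]
  rc <- c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq1))))
  L <- nchar(seq1)
  cfg <- g4_config(max_loop = 7)
  # intra+ of the reverse complement is exactly the mirror of intra-
  fwd <- find_intrastrand_g4(c(chr1 = seq1), cfg)
  rev <- find_intrastrand_g4(rc, cfg)
  key <- function(d, cf) {
    d <- d[d$configuration == cf, c("start", "end", "l1", "l2", "l3")]
    d <- d[order(d$start), ]
    rownames(d) <- NULL
    d
  }
  # loop lengths are stored in scan order on both sides, so only the
  # coordinates mirror
  mirror <- function(d) {
    out <- data.frame(start = L - d$end, end = L - d$start,
                      l1 = d$l1, l2 = d$l2, l3 = d$l3)
    out <- out[order(out$start), ]
    rownames(out) <- NULL
    out
  }
  expect_equal(mirror(key(fwd, "intra+")), key(rev, "intra-"))
  expect_equal(mirror(key(fwd, "intra-")), key(rev, "intra+"))
  # inter selection is scan-direction dependent, but every mirrored motif
  # must still be a valid inter decomposition of the forward sequence
  rin <- find_interstrand_g4(rc, cfg)
  dec <- oracle_g4_decompositions(seq1, c("G", "C"), c(3L, 5L), 7L)
  dec <- dec[dec$letters != "GGGG" & dec$letters != "CCCC", ]
  span <- with(dec, t1 + l1 + t2 + l2 + t3 + l3 + t4)
  valid <- paste(dec$start - 1L, dec$start - 1L + span)
  expect_true(all(paste(L - rin$end, L - rin$start) %in% valid))
})

test_that("every motif falls in exactly one category and one Lk group", {
  g <- simulate_genome(30000, gc = 0.6, seed = 73)
  m <- find_g4(g, g4_config(max_loop = 16))
  expect_gt(nrow(m), 0)
  expect_true(all(m$category %in% c("L1-4", "L5-7", "L8-16")))
  mx <- pmax(m$l1, m$l2, m$l3)
  expect_equal(m$group, paste0("L", mx))
  expect_equal(m$category == "L1-4", mx <= 4)
  expect_equal(m$category == "L5-7", mx > 4 & mx <= 7)
  expect_equal(m$category == "L8-16", mx > 7)
  # span consistency
  expect_equal(m$end - m$start,
               m$t1 + m$t2 + m$t3 + m$t4 + m$l1 + m$l2 + m$l3)
})

test_that("flanks are adjacent, half-span each, truncated at ends", {
  mo <- data.frame(chrom = "chr1", start = 100L, end = 120L)
  fl <- g4_flanks(mo, c(chr1 = 1000L))
  expect_equal(c(fl$left_start, fl$left_end), c(90L, 100L))
  expect_equal(c(fl$right_start, fl$right_end), c(120L, 130L))
  expect_false(fl$truncated)

  edge <- g4_flanks(data.frame(chrom = "chr1", start = 0L, end = 20L),
                    c(chr1 = 1000L))
  expect_equal(edge$left_start, edge$left_end)  # empty left flank
  expect_true(edge$truncated)

  odd <- g4_flanks(data.frame(chrom = "chr1", start = 100L, end = 115L),
                   c(chr1 = 1000L))
  expect_equal(odd$left_end - odd$left_start, 8L)
  expect_equal(odd$right_end - odd$right_start, 7L)
})

test_that("dsb_density is counts over length", {
  p <- break_profile(c(chr1 = 100L))
  p$plus$chr1[31:40] <- 1   # 10 reads in [30, 50)
  p$total_mapped <- 10
  expect_equal(dsb_density(p, "chr1", 30L, 50L), 0.5)
  expect_equal(dsb_density(p, "chr1", 60L, 80L), 0)
  expect_error(dsb_density(p, "chr1", 10L, 10L), "zero-length")

  set.seed(74)
  p$plus$chr1 <- rpois(100, 2)
  starts <- sample(0:80, 10)
  ends <- starts + sample(5:20, 10, replace = TRUE)
  got <- dsb_density(p, rep("chr1", 10), starts, ends)
  want <- vapply(1:10, function(i) {
    sum(p$plus$chr1[(starts[i] + 1):ends[i]]) / (ends[i] - starts[i])
  }, numeric(1))
  expect_equal(got, want)
})

test_that("uniform profiles give equal inside/flank densities", {
  g <- simulate_genome(20000, gc = 0.6, seed = 75)
  m <- find_g4(g, g4_config(max_loop = 7))
  m <- m[m$start > 50 & m$end < 19950, ]
  p <- break_profile(c(chr1 = 20000L))
  p$plus$chr1 <- rep(1, 20000)
  p$total_mapped <- 20000
  rep_out <- g4_fragility_report(p, m)
  expect_equal(rep_out$per_motif$inside, rep(1, nrow(m)))
  expect_equal(rep_out$per_motif$flank, rep(1, nrow(m)))
  expect_null(rep_out$tests$inside_vs_flank)  # degenerate: no differences
  expect_equal(unique(rep_out$meta$mean_signal), 1)
})

test_that("fragility report detects spiked motifs and paired increases", {
  set.seed(76)
  len <- 200000L
  g <- simulate_genome(len, gc = 0.6, seed = 76)
  m <- find_g4(g, g4_config(max_loop = 16))
  m <- m[m$start > 100 & m$end < len - 100, ]
  expect_gte(nrow(m), 50)
  base <- rpois(len, 0.05)
  spike <- base
  for (i in seq_len(nrow(m))) {
    idx <- (m$start[i] + 1):m$end[i]
    spike[idx] <- spike[idx] + rpois(length(idx), 0.5)
  }
  p <- break_profile(c(chr1 = len))
  p$plus$chr1 <- spike
  p$total_mapped <- sum(spike)
  rep_out <- g4_fragility_report(p, m)
  expect_lt(rep_out$tests$inside_vs_flank$p.value, 1e-6)
  # paired comparison: doubled profile is significantly higher
  p2 <- p
  p2$plus$chr1 <- p$plus$chr1 + rpois(len, 0.3)
  p2$total_mapped <- sum(p2$plus$chr1)
  rep2 <- g4_fragility_report(p, m, paired_profile = p2)
  expect_lt(rep2$tests$paired_profiles$p.value, 1e-4)
  # meta profile peaks near the center
  meta <- rep_out$meta
  inner <- meta$mean_signal[abs(meta$bin_start + 5) <= 20]
  outer <- meta$mean_signal[abs(meta$bin_start) >= 80]
  expect_gt(mean(inner), mean(outer))
  expect_error(g4_fragility_report(p, m[1, ]), "at least 2")
})

test_that("loop_breakability separates spiked loop lengths and is seeded", {
  g <- simulate_genome(100000, gc = 0.6, seed = 77)
  # one configuration only: motifs are then non-overlapping, so a spike in
  # a length-1 loop can never sit inside another motif's longer loop
  m <- find_intrastrand_g4(g, g4_config(max_loop = 7,
                                        configurations = "intra+"))
  loops <- g4_loops(m)
  p <- break_profile(c(chr1 = 100000L))
  p$plus$chr1 <- rep(1, 100000)   # uniform floor
  l1 <- loops[loops$length == 1, ]
  for (i in seq_len(nrow(l1))) {
    p$plus$chr1[l1$start[i] + 1] <- p$plus$chr1[l1$start[i] + 1] + 50
  }
  p$total_mapped <- sum(p$plus$chr1)
  tb <- loop_breakability(p, m, n_controls = 200, seed = 99)
  expect_gt(tb$loop_mean[tb$length == 1], 10 * tb$control_mean[1])
  for (k in 2:7) {
    if (!tb$missing[k]) {
      # longer loops keep the uniform floor exactly; controls may brush a
      # spiked position occasionally
      expect_equal(tb$loop_mean[k], 1)
      expect_lt(abs(tb$control_mean[k] - 1), 1)
    }
  }
  tb2 <- loop_breakability(p, m, n_controls = 200, seed = 99)
  expect_identical(tb, tb2)
})

test_that("motif BED export round-trips through the BED reader", {
  g <- simulate_genome(20000, gc = 0.6, seed = 78)
  m <- find_g4(g, g4_config(max_loop = 7))
  f <- tempfile(fileext = ".bed")
  write_g4_bed(m, f)
  back <- read_intervals(f)
  expect_equal(back$start, m$start)
  expect_equal(back$end, m$end)
  expect_equal(back$strand == "+", m$configuration == "intra+")
})
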