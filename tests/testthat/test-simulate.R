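test_that("simulate_genome respects GC content and seeding", {
  g1 <- simulate_genome(1000, gc = 0.5, seed = 1)
  g2 <- simulate_genome(1000, gc = 0.5, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  freq <- table(strsplit(as.character(g1)[["chr1"]], "")[[1]])
  gc <- sum(freq[c("C", "G")]) / 1000
  expect_lt(abs(gc - 0.5), 0.05)

  at_only <- simulate_genome(500, gc = 0, seed = 2)
  expect_false(grepl("[GC]", as.character(at_only)[["chr1"]]))
  expect_error(simulate_genome(100, gc = 1.5, seed = 1), "gc")

  multi <- simulate_genome(c(300, 200), gc = 0.4, seed = 3)
  expect_equal(unname(Biostrings::width(multi)), c(300L, 200L))
})

test_that("dyad-mode breaks sit on the lattice when jitter is zero", {
  p <- simulate_nucleosomal_background(10000, 162, jitter_sd = 0,
                                       n_breaks = 2000, seed = 5,
                                       mode = "dyad",
                                       lattice_jitter_sd = 0)
  pos <- which(combined_counts(p)$chr1 > 0) - 1L
  expect_true(all(pos %% 162 == 81))
  expect_equal(p$total_mapped, 2000)
  expect_equal(sum(combined_counts(p)$chr1), 2000)
})

test_that("linker mode is shifted half a repeat from dyad mode", {
  gl <- 2e5
  d <- simulate_nucleosomal_background(gl, 160, 10, 3e4, seed = 6,
                                       mode = "dyad")
  l <- simulate_nucleosomal_background(gl, 160, 10, 3e4, seed = 6,
                                       mode = "linker")
  cc <- cross_correlation(d, l, max_lag = 120)
  best <- cc$lag[which.max(cc$r)]
  expect_lte(abs(abs(best) - 80), 5)
})

test_that("MNase coverage is linker-enriched by the requested fold", {
  gl <- 50000L
  mn <- simulate_mnase(gl, 162, linker_len = 50, enrichment_fold = 10,
                       n_reads = 2e5, seed = 7, lattice_jitter_sd = 0)
  cov <- combined_counts(mn)$chr1
  # deterministic lattice: dyads at 81 + 162 k, linker midpoints halfway
  dyads <- seq(81, gl - 82, by = 162)
  mids <- round((dyads[-length(dyads)] + dyads[-1]) / 2)
  linker_idx <- unique(unlist(lapply(mids, function(m) {
    (m - 24):(m + 25)
  })))
  linker_idx <- linker_idx[linker_idx >= 0 & linker_idx < gl]
  ratio <- mean(cov[linker_idx + 1]) /
    mean(cov[setdiff(seq_len(gl) - 1L, linker_idx) + 1])
  expect_lt(abs(ratio - 10) / 10, 0.15)

  flat <- simulate_mnase(20000, 162, 50, enrichment_fold = 1,
                         n_reads = 1e5, seed = 8)
  covf <- combined_counts(flat)$chr1
  chunk <- colSums(matrix(covf, nrow = 100))
  expect_lt(max(chunk) / min(chunk), 2)  # no systematic structure
})

test_that("digest places every labeled end at the cut when noise is off", {
  g <- simulate_genome(30000, gc = 0.5, seed = 9)
  enz <- load_enzymes()
  bamhi <- enz[enz$name == "BamHI", ]
  d <- simulate_digest(g, bamhi, n_cells = 50, seed = 10)
  sites <- d$sites
  expect_gt(nrow(sites), 0)
  expected <- sort(unique(c(sites$plus_end, sites$minus_end)))
  got <- sort(unique(d$events$pos))
  expect_true(all(got %in% expected))
  # plus events at plus ends, minus events at minus ends
  expect_true(all(d$events$pos[d$events$strand == "+"] %in%
                    sites$plus_end))
  expect_true(all(d$events$pos[d$events$strand == "-"] %in%
                    sites$minus_end))
  # each cut contributes exactly two ends
  expect_equal(sum(d$events$strand == "+"),
               sum(d$events$strand == "-"))
})

test_that("dilution scales the expected number of cut events", {
  g <- simulate_genome(20000, gc = 0.5, seed = 11)
  enz <- load_enzymes()
  bamhi <- enz[enz$name == "BamHI", ]
  bamhi$cutting_fraction <- 0.5
  d <- simulate_digest(g, bamhi, n_cells = 4000, dilution = 0.1,
                       seed = 12)
  n_cuts <- sum(d$events$strand == "+")   # one per cut event
  lambda <- 4000 * 0.1 * 0.5 * nrow(d$sites)
  expect_lt(abs(n_cuts - lambda), 4 * sqrt(lambda))

  # monotone dilution sweep (expected on-site events decrease)
  counts <- vapply(c(1e-1, 1e-2, 1e-3), function(dil) {
    dd <- simulate_digest(g, bamhi, n_cells = 1e5, dilution = dil,
                          seed = 13)
    nrow(dd$events)
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("resection shifts labeled ends away from the cut site", {
  g <- simulate_genome(20000, gc = 0.5, seed = 14)
  enz <- load_enzymes()
  bamhi <- enz[enz$name == "BamHI", ]
  d <- simulate_digest(g, bamhi, n_cells = 500, seed = 15,
                       resection_mean = 100)
  sites <- d$sites
  ep <- d$events[d$events$strand == "+", ]
  em <- d$events[d$events$strand == "-", ]
  plus_shift <- ep$pos - sites$plus_end[ep$site]
  minus_shift <- em$pos - sites$minus_end[em$site]
  expect_true(all(plus_shift >= 0))
  expect_true(all(minus_shift <= 0))
  expect_gt(mean(plus_shift), 50)
})

test_that("emit_fastq round-trips to the truth profile at zero error", {
  g <- simulate_genome(40000, gc = 0.45, seed = 16)
  enz <- load_enzymes()
  bamhi <- enz[enz$name == "BamHI", ]
  d <- simulate_digest(g, bamhi, n_cells = 100, seed = 17)
  fq <- emit_fastq(d$events, g, read_len = 40, error_rate = 0, seed = 18)
  dx <- demultiplex(fq$r1, fq$r2)
  expect_equal(dx$summary$fraction[dx$summary$class == "proximal-distal"],
               1)
  expect_equal(length(dx$proximal$id), length(fq$kept))
  # proximal read sequences equal the genome at the truth alignments
  chr <- as.character(g)[["chr1"]]
  for (i in sample(seq_len(nrow(fq$truth)), 20)) {
    tr <- fq$truth[i, ]
    gseq <- substr(chr, tr$pos + 1, tr$pos + tr$length)
    if (tr$strand == "-") {
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq)))
    }
    expect_equal(dx$proximal$seq[dx$proximal$id == tr$name], gseq)
  }
  # profiling the truth alignments reproduces the kept-event profile
  prof <- profile_from_alignments(fq$truth, g)
  pref <- break_profile(g)
  ke <- d$events[fq$kept, ]
  for (st in c("+", "-")) {
    slot <- if (st == "+") "plus" else "minus"
    pref[[slot]]$chr1 <- tabulate(ke$pos[ke$strand == st] + 1L,
                                  nbins = pref$seqlengths[["chr1"]])
  }
  expect_equal(prof$plus, pref$plus)
  expect_equal(prof$minus, pref$minus)
})

test_that("sequencing errors break barcode matching at the expected rate", {
  g <- simulate_genome(30000, gc = 0.5, seed = 19)
  set.seed(19)
  ev <- data.frame(chrom = "chr1",
                   pos = sample(1000:25000, 3000, replace = TRUE),
                   strand = sample(c("+", "-"), 3000, replace = TRUE))
  fq <- emit_fastq(ev, g, read_len = 30, error_rate = 0.01, seed = 20)
  cls <- classify_read(fq$r1$seq, max_mismatch = 0)
  fail_rate <- mean(cls$barcode_class != "proximal")
  expected <- 1 - 0.99^11
  se <- sqrt(expected * (1 - expected) / 3000)
  expect_lt(abs(fail_rate - expected), 4 * se)
})

test_that("simulator outputs are bit-reproducible under a fixed seed", {
  g <- simulate_genome(10000, gc = 0.5, seed = 21)
  enz <- load_enzymes()
  bamhi <- enz[enz$name == "BamHI", ]
  d1 <- simulate_digest(g, bamhi, n_cells = 100, background_rate = 1e-3,
                        end_jitter_sd = 2, seed = 22)
  d2 <- simulate_digest(g, bamhi, n_cells = 100, background_rate = 1e-3,
                        end_jitter_sd = 2, seed = 22)
  expect_identical(d1$events, d2$events)
  f1 <- emit_fastq(d1$events, g, read_len = 30, error_rate = 0.01,
                   seed = 23)
  f2 <- emit_fastq(d2$events, g, read_len = 30, error_rate = 0.01,
                   seed = 23)
  expect_identical(f1$r1$seq, f2$r1$seq)
  p1 <- simulate_nucleosomal_background(5000, 162, 20, 500, seed = 24)
  p2 <- simulate_nucleosomal_background(5000, 162, 20, 500, seed = 24)
  expect_identical(p1$plus, p2$plus)
})
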