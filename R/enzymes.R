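# Endonuclease recognition-site scanning, cut-precision metrics and
# off-target identity scanning.

#' Load endonuclease specifications
#'
#' Reads the bundled enzyme table (curated from standard restriction-enzyme
#' references) or a user-supplied TSV with columns \code{name},
#' \code{recognition} (IUPAC), \code{cut_top}, \code{cut_bottom} (cut
#' boundaries, 0-based offsets from the recognition start: the top-strand
#' cut falls between offsets \code{cut_top - 1} and \code{cut_top}),
#' \code{overhang} (\code{5prime}/\code{3prime}/\code{blunt}) and optional
#' \code{cutting_fraction}.
#'
#' @param path Optional TSV path; default is the bundled table (BamHI,
#'   NotI, SrfI, AsiSI, I-SceI).
#' @return Data frame of enzyme specifications.
#' @export
load_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "ibless")
  }
  enz <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "recognition", "cut_top", "cut_bottom", "overhang")
  if (!all(req %in% names(enz))) {
    stop("enzyme table must have columns: ", paste(req, collapse = ", "))
  }
  # overhang class must be consistent with the cut offsets
  oh <- ifelse(enz$cut_top < enz$cut_bottom, "5prime",
               ifelse(enz$cut_top > enz$cut_bottom, "3prime", "blunt"))
  if (!all(oh == enz$overhang)) {
    stop("overhang class inconsistent with cut offsets for: ",
         paste(enz$name[oh != enz$overhang], collapse = ", "))
  }
  enz
}

.IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# Is an IUPAC pattern identical to its reverse complement?
.is_palindromic <- function(pattern) {
  pattern == revcomp(pattern)
}

#' Find endonuclease recognition sites
#'
#' Scans both strands of the genome for the (IUPAC) recognition sequence.
#' Palindromic recognition sequences are reported once (one locus, cut on
#' both strands). For each site the expected i-BLESS labeled break-end
#' positions are derived from the cut geometry after blunting: the
#' plus-strand end is the top-strand cut boundary (first base of the
#' downstream fragment) and the minus-strand end is the base left of the
#' bottom-strand cut boundary — fill-in of 5' overhangs and chew-back of 3'
#' overhangs both lead to these coordinates.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param enzyme One row of \code{\link{load_enzymes}} (data frame or list
#'   with \code{recognition}, \code{cut_top}, \code{cut_bottom},
#'   \code{name}).
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (orientation of the recognition sequence; \code{"."}
#'   for palindromes), \code{plus_end}, \code{minus_end}, \code{name}.
#' @export
find_sites <- function(genome, enzyme) {
  rec <- toupper(enzyme$recognition)
  if (grepl(paste0("[^", paste(.IUPAC_OK, collapse = ""), "]"), rec)) {
    stop("recognition sequence contains non-IUPAC letters: ", rec)
  }
  chr <- .genome_chr(genome)
  len <- nchar(rec)
  ct <- as.integer(enzyme$cut_top)
  cb <- as.integer(enzyme$cut_bottom)
  pal <- .is_palindromic(rec)
  scan_one <- function(ch, pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                  Biostrings::DNAString(chr[[ch]]),
                                  fixed = "subject")
    BiocGenerics::start(m) - 1L  # 0-based
  }
  out <- list()
  for (ch in names(chr)) {
    fwd <- scan_one(ch, rec)
    if (length(fwd)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = fwd, end = fwd + len,
        strand = if (pal) "." else "+",
        plus_end = fwd + ct, minus_end = fwd + cb - 1L)
    }
    if (!pal) {
      rev <- scan_one(ch, revcomp(rec))
      if (length(rev)) {
        # mirrored geometry for a site on the - strand
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = rev, end = rev + len, strand = "-",
          plus_end = rev + len - cb, minus_end = rev + len - ct - 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      plus_end = integer(), minus_end = integer(),
                      name = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res$name <- enzyme$name %||% "enzyme"
  res
}

#' Cut-precision metrics at endonuclease sites
#'
#' Fraction of all profile reads falling exactly on the expected labeled
#' break-end positions (strand-aware: plus-strand counts at
#' \code{plus_end}, minus-strand counts at \code{minus_end}), the analogous
#' fraction within a tolerance window, and per-site detection.
#'
#' @param profile A raw-count \code{BreakProfile} on the sites' genome.
#' @param sites Site data frame from \code{\link{find_sites}}.
#' @param tolerance Half-width of the "within" window in nt (default 1).
#' @param detect_min Minimum reads within a site's windows for the site to
#'   count as detected (default 1).
#' @return Object of class \code{SitePrecision}: list with \code{n_sites},
#'   \code{n_detected}, \code{frac_exact}, \code{frac_within},
#'   \code{total_reads}, \code{no_reads} flag and \code{per_site} counts.
#' @export
site_precision <- function(profile, sites, tolerance = 1L,
                           detect_min = 1L) {
  stopifnot(inherits(profile, "BreakProfile"))
  if (!nrow(sites)) stop("no sites supplied")
  if (!all(sites$chrom %in% names(profile$seqlengths))) {
    stop("sites reference chromosomes absent from the profile")
  }
  win_sum <- function(counts, chrom, center, tol) {
    vapply(seq_along(center), function(i) {
      v <- counts[[chrom[i]]]
      a <- max(1L, center[i] + 1L - tol)
      b <- min(length(v), center[i] + 1L + tol)
      sum(v[a:b])
    }, numeric(1))
  }
  exact_p <- win_sum(profile$plus, sites$chrom, sites$plus_end, 0L)
  exact_m <- win_sum(profile$minus, sites$chrom, sites$minus_end, 0L)
  within_p <- win_sum(profile$plus, sites$chrom, sites$plus_end, tolerance)
  within_m <- win_sum(profile$minus, sites$chrom, sites$minus_end,
                      tolerance)
  per_site <- data.frame(sites[, c("chrom", "start", "end", "name")],
                         exact = exact_p + exact_m,
                         within = within_p + within_m)
  total <- sum(vapply(combined_counts(profile), sum, numeric(1)))
  detected <- per_site$within >= detect_min
  no_reads <- total == 0
  structure(list(
    n_sites = nrow(sites),
    n_detected = sum(detected),
    frac_exact = if (no_reads) 0 else sum(per_site$exact) / total,
    frac_within = if (no_reads) 0 else sum(per_site$within) / total,
    total_reads = total,
    no_reads = no_reads,
    per_site = per_site
  ), class = "SitePrecision")
}

#' @export
print.SitePrecision <- function(x, ...) {
  cat(sprintf(
    "SitePrecision: %d/%d sites detected; %.1f%% of reads exact, %.1f%% within tolerance%s\n",
    x$n_detected, x$n_sites, 100 * x$frac_exact, 100 * x$frac_within,
    if (x$no_reads) " [no reads]" else ""))
  invisible(x)
}

#' Per-site read counts for several enzymes
#'
#' Long-format table of reads within \code{tolerance} of each site's
#' expected break ends, one row per site, suitable for box-plot summaries
#' across overhang chemistries.
#'
#' @param profile A \code{BreakProfile}.
#' @param site_lists Named list of site data frames (one per enzyme).
#' @param tolerance Window half-width (default 1).
#' @return Data frame with \code{enzyme}, \code{chrom}, \code{start},
#'   \code{end}, \code{count}.
#' @export
per_site_read_table <- function(profile, site_lists, tolerance = 1L) {
  stopifnot(is.list(site_lists), !is.null(names(site_lists)))
  out <- lapply(names(site_lists), function(nm) {
    sp <- site_precision(profile, site_lists[[nm]], tolerance = tolerance)
    data.frame(enzyme = nm,
               sp$per_site[, c("chrom", "start", "end")],
               count = sp$per_site$within)
  })
  do.call(rbind, out)
}

# Ungapped identity (# matching bases) of `query` against `subject` at every
# offset; returns the best offset and score.
.best_identity <- function(subject_chars, query_chars) {
  n <- length(subject_chars); q <- length(query_chars)
  if (n < q) return(NULL)
  best <- -1L; best_off <- NA_integer_
  for (off in 0:(n - q)) {
    sc <- sum(subject_chars[(off + 1):(off + q)] == query_chars)
    if (sc > best) { best <- sc; best_off <- off }
  }
  list(score = best, offset = best_off)
}

#' Scan candidate regions for off-target identity with a canonical site
#'
#' For each candidate region, slides the canonical recognition sequence
#' (both orientations, ungapped) across the region padded by the canonical
#' length on each side, recording the maximum number of matching bases.
#' Candidates reaching \code{min_identity} are retained — the screen used
#' to find degenerate endonuclease off-target sites.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param canonical_site Canonical recognition sequence (e.g. the I-SceI
#'   18-mer).
#' @param candidate_regions Data frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @param min_identity Minimum matching bases to retain (default 10).
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{best_identity}, \code{best_pos} (0-based genomic start of the
#'   best alignment), \code{best_strand}, \code{retained}, \code{skipped}.
#' @export
offtarget_scan <- function(genome, canonical_site, candidate_regions,
                           min_identity = 10L) {
  canonical_site <- toupper(canonical_site)
  Lc <- nchar(canonical_site)
  if (Lc < min_identity) {
    stop("canonical site shorter than min_identity")
  }
  chr <- .genome_chr(genome)
  fwd <- strsplit(canonical_site, "")[[1]]
  rev <- strsplit(revcomp(canonical_site), "")[[1]]
  res <- candidate_regions[, c("chrom", "start", "end")]
  res$best_identity <- NA_integer_
  res$best_pos <- NA_integer_
  res$best_strand <- NA_character_
  res$skipped <- FALSE
  for (i in seq_len(nrow(res))) {
    ch <- res$chrom[i]
    a <- max(0L, res$start[i] - Lc)
    b <- min(nchar(chr[[ch]]), res$end[i] + Lc)
    sub <- strsplit(substr(chr[[ch]], a + 1L, b), "")[[1]]
    hf <- .best_identity(sub, fwd)
    hr <- .best_identity(sub, rev)
    if (is.null(hf) && is.null(hr)) {
      res$skipped[i] <- TRUE
      next
    }
    sf <- if (is.null(hf)) -1L else hf$score
    sr <- if (is.null(hr)) -1L else hr$score
    if (sf >= sr) {
      res$best_identity[i] <- sf
      res$best_pos[i] <- a + hf$offset
      res$best_strand[i] <- "+"
    } else {
      res$best_identity[i] <- sr
      res$best_pos[i] <- a + hr$offset
      res$best_strand[i] <- "-"
    }
  }
  res$retained <- !res$skipped & res$best_identity >= min_identity
  res
}
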