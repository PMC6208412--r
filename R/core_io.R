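#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into a \code{DNAStringSet}, uppercasing all sequences.
#' Characters outside \{A, C, G, T, N\} (e.g. IUPAC ambiguity codes) are
#' replaced by \code{N} with a warning, so that downstream scanners operate on
#' a fixed alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}; one element per chromosome, in file
#'   order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("invalid FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no records")
  # FASTA headers may carry descriptions; chromosome name = first word
  nms <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(nms))) stop("empty sequence name in FASTA file")
  if (anyDuplicated(nms)) {
    stop("duplicate sequence names in FASTA file: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-ACGTN characters; ",
            "replaced with N")
    chr[bad] <- gsub("[^ACGTN]", "N", chr[bad])
  }
  if (any(nchar(chr) == 0L)) stop("empty sequence in FASTA file")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- nms
  out
}

#' Construct an empty break profile
#'
#' A \code{BreakProfile} holds strand-aware single-nucleotide break-end counts
#' for a genome: one numeric vector per chromosome and strand (positions are
#' 0-based; element \code{i} of a vector is position \code{i - 1}).
#'
#' @param seqlengths Named integer vector of chromosome lengths, or a genome
#'   (\code{DNAStringSet}/named character) from which lengths are taken.
#' @return An object of class \code{BreakProfile} with zero counts.
#' @export
break_profile <- function(seqlengths) {
  if (inherits(seqlengths, "DNAStringSet") || is.character(seqlengths)) {
    seqlengths <- .genome_seqlengths(seqlengths)
  }
  stopifnot(is.numeric(seqlengths), length(seqlengths) > 0L,
            !is.null(names(seqlengths)), all(seqlengths >= 1))
  sl <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  zero <- lapply(sl, numeric)
  structure(
    list(plus = zero, minus = zero, seqlengths = sl,
         total_mapped = 0, normalized = FALSE, scale_factor = 1),
    class = "BreakProfile"
  )
}

#' @export
print.BreakProfile <- function(x, ...) {
  cat("BreakProfile:", length(x$seqlengths), "chromosome(s),",
      format(sum(x$seqlengths), big.mark = ","), "nt\n")
  cat("  total_mapped:", x$total_mapped,
      if (x$normalized) sprintf("(normalized, scale %.4g)", x$scale_factor)
      else "(raw counts)", "\n")
  invisible(x)
}

#' Combined-strand view of a break profile
#'
#' @param profile A \code{BreakProfile}.
#' @return Named list of numeric vectors: per-chromosome elementwise sum of
#'   plus- and minus-strand counts.
#' @export
combined_counts <- function(profile) {
  stopifnot(inherits(profile, "BreakProfile"))
  mapply(`+`, profile$plus, profile$minus, SIMPLIFY = FALSE)
}

#' Build a break profile from unique-mapping aligned reads
#'
#' Each read contributes a single count at the 5' end of its aligned, trimmed
#' sequence: the leftmost position for a plus-strand read, and the rightmost
#' position (\code{pos + length - 1}) for a minus-strand read. With i-BLESS
#' chemistry the proximal-barcode read starts at the (blunted) break end, so
#' this position is the break end itself. Multi-mapping reads must be excluded
#' upstream (bowtie \code{-m1} convention).
#'
#' @param records Data frame of aligned reads with columns \code{chrom},
#'   \code{pos} (0-based leftmost), \code{length}, \code{strand}
#'   (\code{"+"}/\code{"-"}).
#' @param genome Genome the reads were mapped to (\code{DNAStringSet}, named
#'   character vector, or named integer vector of lengths).
#' @return A raw-count \code{BreakProfile} with
#'   \code{total_mapped = nrow(records)}.
#' @export
profile_from_alignments <- function(records, genome) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "pos", "length", "strand") %in% names(records)))
  prof <- break_profile(genome)
  sl <- prof$seqlengths
  unknown <- setdiff(unique(records$chrom), names(sl))
  if (length(unknown)) {
    stop("alignment on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(records)) {
    if (!all(records$strand %in% c("+", "-"))) {
      stop("alignment strand must be '+' or '-'")
    }
    end5 <- ifelse(records$strand == "+", records$pos,
                   records$pos + records$length - 1L)
    if (any(records$pos < 0L) ||
        any(records$pos + records$length > sl[records$chrom])) {
      stop("alignment outside chromosome bounds")
    }
    for (ch in unique(records$chrom)) {
      for (st in c("+", "-")) {
        sel <- records$chrom == ch & records$strand == st
        if (!any(sel)) next
        slot <- if (st == "+") "plus" else "minus"
        prof[[slot]][[ch]] <- prof[[slot]][[ch]] +
          tabulate(end5[sel] + 1L, nbins = sl[[ch]])
      }
    }
  }
  prof$total_mapped <- nrow(records)
  prof
}

#' Normalize a break profile to one million mapped reads
#'
#' Multiplies every count by \code{1e6 / total_mapped} so that profiles from
#' libraries of different depth are comparable.
#'
#' @param profile A raw-count \code{BreakProfile} with
#'   \code{total_mapped > 0}.
#' @return The normalized \code{BreakProfile}; the combined counts sum to
#'   \code{1e6} up to floating tolerance.
#' @export
normalize_per_million <- function(profile) {
  stopifnot(inherits(profile, "BreakProfile"))
  if (profile$normalized) stop("profile is already normalized")
  if (profile$total_mapped <= 0) {
    stop("cannot normalize a profile with total_mapped = 0")
  }
  f <- 1e6 / profile$total_mapped
  profile$plus <- lapply(profile$plus, `*`, f)
  profile$minus <- lapply(profile$minus, `*`, f)
  profile$normalized <- TRUE
  profile$scale_factor <- f
  profile
}

#' Write a break profile as bedGraph
#'
#' Writes 0-based half-open single-position records for every nonzero
#' position of the selected strand view.
#'
#' @param profile A \code{BreakProfile}.
#' @param path Output file path.
#' @param strand One of \code{"combined"}, \code{"plus"}, \code{"minus"}.
#' @return Invisibly, the path.
#' @export
write_profile <- function(profile, path,
                          strand = c("combined", "plus", "minus")) {
  stopifnot(inherits(profile, "BreakProfile"))
  strand <- match.arg(strand)
  counts <- switch(strand,
                   combined = combined_counts(profile),
                   plus = profile$plus,
                   minus = profile$minus)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(counts)) {
    v <- counts[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, nz - 1L, nz,
                       format(v[nz], trim = TRUE, scientific = FALSE,
                              digits = 15)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph coverage file into a break profile
#'
#' The returned profile carries the file's values as a combined-only view
#' (all mass stored on the plus strand; per-strand information is not present
#' in bedGraph). \code{total_mapped} is the sum of all values.
#'
#' @param path bedGraph file (0-based half-open).
#' @param seqlengths Named integer chromosome lengths (or a genome object).
#' @return A \code{BreakProfile}.
#' @export
read_profile <- function(path, seqlengths) {
  prof <- break_profile(seqlengths)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) stop("malformed bedGraph line ", i, " in ", path)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    val <- suppressWarnings(as.numeric(f[4]))
    if (is.na(start) || is.na(end) || is.na(val) || start < 0 || end <= start) {
      stop("malformed bedGraph line ", i, " in ", path)
    }
    ch <- f[1]
    if (!ch %in% names(prof$seqlengths)) {
      stop("bedGraph line ", i, ": unknown chromosome ", ch)
    }
    if (end > prof$seqlengths[[ch]]) {
      stop("bedGraph line ", i, ": interval exceeds chromosome length")
    }
    prof$plus[[ch]][(start + 1L):end] <- prof$plus[[ch]][(start + 1L):end] + val
  }
  prof$total_mapped <- sum(vapply(prof$plus, sum, numeric(1)))
  prof
}

#' Read genomic intervals from BED
#'
#' Accepts 3- to 6-column BED. Missing columns are filled with \code{"."}
#' (name/strand) and \code{0} (score). Strand is one of \code{"+"},
#' \code{"-"}, \code{"."} (unstranded).
#'
#' @param path BED file path.
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}, \code{strand} (0-based half-open).
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(track|browser|#)", lines) & nzchar(lines))
  if (!length(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L | ncol > 12L)
  if (length(bad)) {
    stop("malformed BED line ", keep[bad[1]], " in ", path)
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  badpos <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(badpos)) {
    stop("malformed BED line ", keep[badpos[1]], " in ", path)
  }
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-")] <- "."
  data.frame(
    chrom = get(1, NA), start = start, end = end,
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = strand
  )
}

#' Write intervals as BED6
#'
#' @param intervals Data frame with at least \code{chrom}, \code{start},
#'   \code{end}; optional \code{name}, \code{score}, \code{strand}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_intervals <- function(intervals, path) {
  n <- nrow(intervals)
  name <- intervals$name %||% rep(".", n)
  score <- intervals$score %||% rep(0, n)
  strand <- intervals$strand %||% rep(".", n)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     intervals$chrom, intervals$start, intervals$end,
                     name, format(score, trim = TRUE), strand),
             path)
  invisible(path)
}

#' Read aligned reads from BED6 or BAM/SAM
#'
#' BED6 alignments (as emitted by the simulator's truth output, or converted
#' with \code{bedtools bamtobed}) are parsed directly; \code{.bam}/\code{.sam}
#' files are read through Rsamtools when available, keeping unique-mapping
#' primary alignments only.
#'
#' @param path Alignment file (\code{.bed}, \code{.bam} or \code{.sam}).
#' @return Data frame with columns \code{chrom}, \code{pos} (0-based
#'   leftmost), \code{length}, \code{strand}, \code{name} — the
#'   \code{AlignedReadRecord} layout used by
#'   \code{\link{profile_from_alignments}}.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bam", "sam")) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM/SAM requires the Rsamtools package")
    }
    bam <- path
    if (ext == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)
    )
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    return(data.frame(chrom = as.character(x$rname),
                      pos = x$pos - 1L,        # SAM is 1-based
                      length = x$qwidth,
                      strand = as.character(x$strand),
                      name = x$qname))
  }
  bed <- read_intervals(path)
  if (any(bed$strand == ".")) {
    stop("alignment BED must carry strand in column 6")
  }
  data.frame(chrom = bed$chrom, pos = bed$start,
             length = bed$end - bed$start,
             strand = bed$strand, name = bed$name)
}
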