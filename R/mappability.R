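#' Compute a k-mer-uniqueness mappability track
#'
#' A position \code{p} is mappable iff the k-mer starting at \code{p} occurs
#' exactly once across both strands of the genome — the condition under which
#' a k-long read from \code{p} maps uniquely (bowtie \code{-m1} philosophy;
#' uniqueness here is exact-match). A k-mer equal to its own reverse
#' complement occupies a single location on both strands and counts once, so
#' a palindromic k-mer at one locus is mappable. k-mers containing \code{N}
#' are unmappable, as are the last \code{k - 1} positions of each chromosome.
#'
#' @param genome \code{DNAStringSet} or named character vector.
#' @param k k-mer length (typically the trimmed read length; default 50).
#' @return Object of class \code{MappabilityTrack}: list with \code{k} and
#'   \code{mappable}, a named list of per-chromosome logical vectors.
#' @export
compute_mappability <- function(genome, k = 50L) {
  stopifnot(k >= 1L)
  chr <- .genome_chr(genome)
  sl <- vapply(chr, nchar, integer(1))
  if (all(sl < k)) {
    warning("k = ", k, " exceeds every chromosome length; ",
            "all positions unmappable")
    return(structure(list(k = as.integer(k),
                          mappable = lapply(sl, function(n) logical(n))),
                     class = "MappabilityTrack"))
  }
  # enumerate every k-mer start on the + strand of every chromosome
  kmers <- lapply(names(chr), function(ch) {
    n <- sl[[ch]]
    if (n < k) return(character())
    starts <- seq_len(n - k + 1L)
    substring(chr[[ch]], starts, starts + k - 1L)
  })
  names(kmers) <- names(chr)
  all_kmers <- unlist(kmers, use.names = FALSE)
  dt <- data.table::data.table(kmer = all_kmers)
  cnt <- dt[, .N, by = "kmer"]
  data.table::setkey(cnt, kmer)
  rc <- revcomp(all_kmers)
  c_fwd <- cnt[data.table::data.table(kmer = all_kmers), on = "kmer"]$N
  c_rev <- cnt[data.table::data.table(kmer = rc), on = "kmer"]$N
  c_rev[is.na(c_rev)] <- 0L
  palindrome <- all_kmers == rc
  occ <- ifelse(palindrome, c_fwd, c_fwd + c_rev)
  ok <- occ == 1L & !grepl("N", all_kmers, fixed = TRUE)
  mappable <- vector("list", length(chr))
  names(mappable) <- names(chr)
  offset <- 0L
  for (ch in names(chr)) {
    n <- sl[[ch]]
    v <- logical(n)
    nk <- length(kmers[[ch]])
    if (nk > 0L) {
      v[seq_len(nk)] <- ok[offset + seq_len(nk)]
      offset <- offset + nk
    }
    mappable[[ch]] <- v
  }
  structure(list(k = as.integer(k), mappable = mappable),
            class = "MappabilityTrack")
}

#' @export
print.MappabilityTrack <- function(x, ...) {
  tot <- sum(vapply(x$mappable, length, integer(1)))
  mp <- sum(vapply(x$mappable, sum, numeric(1)))
  cat(sprintf("MappabilityTrack: k = %d, %d/%d positions mappable (%.1f%%)\n",
              x$k, as.integer(mp), tot, 100 * mp / tot))
  invisible(x)
}

#' Build a constant mappability track
#'
#' Convenience constructor for analyses where no mappability information is
#' available (or where the genome is synthetic and fully unique by design).
#'
#' @param seqlengths Named chromosome lengths, or a genome object.
#' @param value Logical; mappability value for every position.
#' @return A \code{MappabilityTrack} with \code{k = NA}.
#' @export
constant_mappability <- function(seqlengths, value = TRUE) {
  if (inherits(seqlengths, "DNAStringSet") || is.character(seqlengths)) {
    seqlengths <- .genome_seqlengths(seqlengths)
  }
  structure(list(k = NA_integer_,
                 mappable = lapply(seqlengths,
                                   function(n) rep(value, n))),
            class = "MappabilityTrack")
}

#' Count mappable positions in intervals
#'
#' @param track A \code{MappabilityTrack}.
#' @param chrom,start,end Parallel vectors defining 0-based half-open
#'   intervals; alternatively \code{chrom} may be a data frame with those
#'   columns.
#' @return Integer vector of mappable-position counts.
#' @export
mappable_length <- function(track, chrom, start = NULL, end = NULL) {
  stopifnot(inherits(track, "MappabilityTrack"))
  if (is.data.frame(chrom)) {
    start <- chrom$start; end <- chrom$end; chrom <- chrom$chrom
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    v <- track$mappable[[ch]]
    if (is.null(v)) stop("unknown chromosome in mappable_length: ", ch)
    cs <- c(0L, cumsum(v))
    sel <- which(chrom == ch)
    if (any(start[sel] < 0L) || any(end[sel] > length(v)) ||
        any(start[sel] >= end[sel])) {
      stop("invalid interval on chromosome ", ch)
    }
    out[sel] <- cs[end[sel] + 1L] - cs[start[sel] + 1L]
  }
  out
}

#' Mappable blocks as intervals
#'
#' Collapses a mappability track into maximal runs of mappable positions,
#' suitable for BED output.
#'
#' @param track A \code{MappabilityTrack}.
#' @return Data frame with \code{chrom}, \code{start}, \code{end}.
#' @export
mappability_blocks <- function(track) {
  stopifnot(inherits(track, "MappabilityTrack"))
  out <- lapply(names(track$mappable), function(ch) {
    r <- rle(track$mappable[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(chrom = rep(ch, sum(keep)), start = starts[keep],
               end = ends[keep])
  })
  do.call(rbind, out)
}
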