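#' i-BLESS adapter barcodes
#'
#' The 11-nt barcodes ligated during i-BLESS labeling: the proximal barcode
#' marks the read that starts at the (blunted) break end; the distal barcode
#' marks the read from the sonicated far end of the fragment. The two
#' sequences differ at 6 of 11 positions, so classification with up to 2
#' mismatches can never be ambiguous between them.
#'
#' @format Named character vector with elements \code{proximal} and
#'   \code{distal}.
#' @export
IBLESS_BARCODES <- c(proximal = "TCGAGGTAGTA", distal = "TCGAGACGACG")

.BARCODE_LEN <- 11L

# Hamming distance between the first nchar(ref) characters of each sequence
# and ref. Vectorised over sequences; positions beyond length(x) count as
# mismatches (callers exclude short reads anyway).
.prefix_mismatches <- function(x, ref) {
  k <- nchar(ref)
  mm <- integer(length(x))
  for (i in seq_len(k)) {
    mm <- mm + (substr(x, i, i) != substr(ref, i, i))
  }
  mm
}

#' Classify reads by their 5' i-BLESS barcode
#'
#' Compares the first 11 nt of each read to the proximal and distal barcodes
#' (5'-anchored, no internal search) under a Hamming-distance threshold. If
#' both barcodes match within \code{max_mismatch}, the smaller distance wins;
#' an exact tie is ambiguous and classified \code{none}. Reads of 11 nt or
#' shorter cannot carry a barcode plus insert and are classified \code{none}
#' and flagged short.
#'
#' @param sequences Character vector of read sequences.
#' @param max_mismatch Maximum Hamming distance allowed (default 0).
#' @return Data frame with columns \code{sequence}, \code{barcode_class}
#'   (\code{"proximal"}, \code{"distal"}, \code{"none"}), \code{trimmed}
#'   (barcode removed when classified, otherwise the input), \code{short},
#'   and \code{ambiguous}.
#' @export
classify_read <- function(sequences, max_mismatch = 0L) {
  stopifnot(is.character(sequences), max_mismatch >= 0L)
  sequences <- toupper(sequences)
  short <- nchar(sequences) <= .BARCODE_LEN
  mm_p <- .prefix_mismatches(sequences, IBLESS_BARCODES[["proximal"]])
  mm_d <- .prefix_mismatches(sequences, IBLESS_BARCODES[["distal"]])
  hit_p <- mm_p <= max_mismatch
  hit_d <- mm_d <= max_mismatch
  ambiguous <- hit_p & hit_d & mm_p == mm_d & !short
  class <- rep("none", length(sequences))
  class[hit_p & (!hit_d | mm_p < mm_d)] <- "proximal"
  class[hit_d & (!hit_p | mm_d < mm_p)] <- "distal"
  class[ambiguous | short] <- "none"
  trimmed <- ifelse(class == "none", sequences,
                    substr(sequences, .BARCODE_LEN + 1L, nchar(sequences)))
  data.frame(sequence = sequences, barcode_class = class, trimmed = trimmed,
             short = short, ambiguous = ambiguous)
}

#' Classify a read pair into a fragment class
#'
#' An intact i-BLESS fragment carries the proximal barcode on one mate and
#' the distal barcode on the other. Two proximal barcodes can arise from two
#' nearby breaks; any unclassified mate makes the fragment \code{other}.
#'
#' @param class1,class2 Character vectors of per-read barcode classes
#'   (\code{"proximal"}, \code{"distal"}, \code{"none"}).
#' @return Character vector over \{\code{"proximal-distal"},
#'   \code{"proximal-proximal"}, \code{"distal-distal"}, \code{"other"}\}.
#' @export
classify_pair <- function(class1, class2) {
  stopifnot(length(class1) == length(class2))
  out <- rep("other", length(class1))
  out[(class1 == "proximal" & class2 == "distal") |
        (class1 == "distal" & class2 == "proximal")] <- "proximal-distal"
  out[class1 == "proximal" & class2 == "proximal"] <- "proximal-proximal"
  out[class1 == "distal" & class2 == "distal"] <- "distal-distal"
  out
}

#' Demultiplex i-BLESS read pairs and select proximal reads
#'
#' Classifies both mates of each pair by barcode, tabulates fragment classes,
#' and emits every trimmed proximal read (a proximal-proximal pair therefore
#' contributes two reads). Mates must be synchronized: same ids in the same
#' order (a trailing \code{/1}, \code{/2} or \code{" 1..."}, \code{" 2..."}
#' suffix is ignored).
#'
#' @param r1,r2 FASTQ file paths (gzip transparent) or in-memory read sets as
#'   returned by \code{\link{read_fastq}}.
#' @param max_mismatch Maximum Hamming distance for barcode matching.
#' @param out Optional path; trimmed proximal reads are written there as
#'   FASTQ.
#' @param summary_path Optional path; the fragment-class summary is written
#'   there as TSV.
#' @return List with \code{proximal} (list of \code{id}, \code{seq},
#'   \code{qual} for the selected reads), \code{summary} (data frame of
#'   \code{class}, \code{count}, \code{fraction}; fractions sum to 1 when any
#'   pairs are present), and \code{n_pairs}.
#' @export
demultiplex <- function(r1, r2, max_mismatch = 0L, out = NULL,
                        summary_path = NULL) {
  a <- if (is.character(r1) && length(r1) == 1L) read_fastq(r1) else r1
  b <- if (is.character(r2) && length(r2) == 1L) read_fastq(r2) else r2
  if (is.null(a$qual)) a$qual <- strrep("I", nchar(a$seq))
  if (is.null(b$qual)) b$qual <- strrep("I", nchar(b$seq))
  if (length(a$id) != length(b$id)) {
    stop("mate files differ in read count (", length(a$id), " vs ",
         length(b$id), ")")
  }
  strip <- function(id) sub("(/[12]$)|( [12].*$)", "", id)
  ida <- strip(a$id); idb <- strip(b$id)
  bad <- which(ida != idb)
  if (length(bad)) {
    stop("mate id mismatch at record ", bad[1], ": '", ida[bad[1]],
         "' vs '", idb[bad[1]], "'")
  }
  ca <- classify_read(a$seq, max_mismatch)
  cb <- classify_read(b$seq, max_mismatch)
  frag <- classify_pair(ca$barcode_class, cb$barcode_class)
  classes <- c("proximal-distal", "proximal-proximal", "distal-distal",
               "other")
  count <- vapply(classes, function(k) sum(frag == k), integer(1))
  n <- length(frag)
  summary <- data.frame(class = classes, count = unname(count),
                        fraction = if (n > 0) unname(count) / n else
                          rep(0, 4L))
  sel_a <- ca$barcode_class == "proximal"
  sel_b <- cb$barcode_class == "proximal"
  proximal <- list(
    id = c(a$id[sel_a], b$id[sel_b]),
    seq = c(ca$trimmed[sel_a], cb$trimmed[sel_b]),
    qual = c(substr(a$qual[sel_a], .BARCODE_LEN + 1L, nchar(a$qual[sel_a])),
             substr(b$qual[sel_b], .BARCODE_LEN + 1L, nchar(b$qual[sel_b])))
  )
  ord <- order(c(which(sel_a), which(sel_b)))
  proximal <- lapply(proximal, `[`, ord)
  if (!is.null(out)) write_fastq(proximal, out)
  if (!is.null(summary_path)) {
    utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(proximal = proximal, summary = summary, n_pairs = n)
}
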