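# FASTQ reading/writing via Biostrings (gzip transparent).

#' Read a FASTQ file
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return List with character vectors \code{id}, \code{seq}, \code{qual}.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first)) {
    return(list(id = character(), seq = character(), qual = character()))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x),
       seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write reads as FASTQ
#'
#' @param reads List with \code{id}, \code{seq} and optionally \code{qual}
#'   (placeholder qualities \code{"I"} are used when absent).
#' @param path Output path; a \code{.gz} suffix triggers gzip compression.
#' @return Invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(!is.null(reads$id), !is.null(reads$seq),
            length(reads$id) == length(reads$seq))
  qual <- reads$qual
  if (is.null(qual) || !length(qual)) qual <- strrep("I", nchar(reads$seq))
  bad <- nchar(qual) != nchar(reads$seq)
  qual[bad] <- strrep("I", nchar(reads$seq[bad]))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads$id)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  }
  invisible(path)
}
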