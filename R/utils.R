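# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a genome (DNAStringSet or named character vector) to a named,
# uppercase character vector. No alphabet sanitation here; read_genome and
# simulate_genome already guarantee {A,C,G,T,N}.
.genome_chr <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("genome sequences must be named")
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate chromosome names in genome")
  }
  out
}

.genome_seqlengths <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(.genome_chr(genome), nchar, integer(1))
  }
}

# Reverse complement of plain character sequences (vectorised).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
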