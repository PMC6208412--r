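.onLoad <- function(libname, pkgname) {
  # The two adapter barcodes must stay distinguishable under mismatch-
  # tolerant classification: they differ at 6 of 11 positions, so any
  # max_mismatch <= 2 is unambiguous.
  p <- strsplit(IBLESS_BARCODES[["proximal"]], "")[[1]]
  d <- strsplit(IBLESS_BARCODES[["distal"]], "")[[1]]
  if (length(p) != 11L || length(d) != 11L || sum(p != d) != 6L) {
    stop("i-BLESS barcode constants corrupted")
  }
  invisible()
}
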