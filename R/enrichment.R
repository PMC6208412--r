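# Permutation test for enrichment/depletion of genomic features in
# DSB-rich windows (mappable-nucleotide accounting throughout).

# Per-chromosome logical coverage mask from an interval data frame.
.feature_mask <- function(feature, seqlengths) {
  masks <- lapply(seqlengths, function(n) logical(n))
  for (i in seq_len(nrow(feature))) {
    ch <- feature$chrom[i]
    if (is.null(masks[[ch]])) stop("feature on unknown chromosome: ", ch)
    s <- max(0L, feature$start[i])
    e <- min(length(masks[[ch]]), feature$end[i])
    if (e > s) masks[[ch]][(s + 1L):e] <- TRUE
  }
  masks
}

# Per-window mappable length (m) and mappable-AND-feature length (f).
.window_overlap_stats <- function(windows, feature, mappability) {
  sl <- vapply(mappability$mappable, length, integer(1))
  fmask <- .feature_mask(feature, sl)
  m <- mappable_length(mappability, windows)
  f <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    both <- mappability$mappable[[ch]] & fmask[[ch]]
    cs <- c(0L, cumsum(both))
    sel <- which(windows$chrom == ch)
    f[sel] <- cs[windows$end[sel] + 1L] - cs[windows$start[sel] + 1L]
  }
  list(m = m, f = f)
}

#' Observed and expected feature overlap of DSB-rich windows
#'
#' Observed overlap: proportion of mappable nucleotides of the DSB-rich
#' windows that fall inside the feature. Expected overlap: the same
#' proportion over all windows.
#'
#' @param windows Window data frame (\code{chrom}, \code{start},
#'   \code{end}) tiling the analyzed genome.
#' @param labels Logical vector: which windows are DSB-rich.
#' @param feature Feature intervals (\code{chrom}, \code{start},
#'   \code{end}).
#' @param mappability A \code{MappabilityTrack}.
#' @return List with \code{observed}, \code{expected}, \code{ratio} and the
#'   per-window \code{m} (mappable) and \code{f} (mappable-and-feature)
#'   counts.
#' @export
overlap_proportions <- function(windows, labels, feature, mappability) {
  stopifnot(nrow(windows) == length(labels), is.logical(labels))
  st <- .window_overlap_stats(windows, feature, mappability)
  if (sum(st$m[labels]) == 0) {
    stop("zero mappable nucleotides in the DSB-rich window set")
  }
  observed <- sum(st$f[labels]) / sum(st$m[labels])
  expected <- sum(st$f) / sum(st$m)
  list(observed = observed, expected = expected,
       ratio = if (expected > 0) observed / expected else NA_real_,
       m = st$m, f = st$f)
}

#' Permutation test for feature enrichment in DSB-rich windows
#'
#' Permutes the DSB-rich label multiset over the windows \code{n_perm}
#' times (seeded), recomputing the observed/expected overlap ratio each
#' time, and reports the one-sided empirical P value in the observed
#' direction with the +1 correction
#' \eqn{P = (1 + \#\{ratio_{perm} \ge ratio_{obs}\}) / (1 + n_{perm})}
#' (\eqn{\le} for depletion); ties count toward the tail.
#'
#' @inheritParams overlap_proportions
#' @param feature_name Label for the report.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed (required: pipelines must be reproducible).
#' @return Object of class \code{EnrichmentResult}: list with
#'   \code{feature}, \code{observed}, \code{expected}, \code{ratio},
#'   \code{p}, \code{n_perm}, \code{direction}
#'   (\code{"enriched"}/\code{"depleted"}/\code{"none"}) and the permuted
#'   ratios.
#' @export
permutation_test <- function(windows, labels, feature, mappability,
                             n_perm = 1000L, seed,
                             feature_name = "feature") {
  stopifnot(n_perm >= 1L, sum(labels) >= 1L)
  if (all(labels)) stop("all windows labeled DSB-rich; test is degenerate")
  # canonical window order makes the permutation stream — and hence P —
  # invariant under shuffling of the input rows
  ord <- order(windows$chrom, windows$start)
  windows <- windows[ord, , drop = FALSE]
  labels <- labels[ord]
  base <- overlap_proportions(windows, labels, feature, mappability)
  obs <- base$ratio
  m <- base$m; f <- base$f
  k <- sum(labels)
  Fall <- sum(f); Mall <- sum(m)
  exp_ratio_denom <- Fall / Mall
  perm_ratios <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(labels), k)
      (sum(f[idx]) / sum(m[idx])) / exp_ratio_denom
    }, numeric(1))
  })
  direction <- if (obs > 1) "enriched" else if (obs < 1) "depleted" else
    "none"
  p <- if (direction == "depleted") {
    (1 + sum(perm_ratios <= obs, na.rm = TRUE)) / (1 + n_perm)
  } else {
    (1 + sum(perm_ratios >= obs, na.rm = TRUE)) / (1 + n_perm)
  }
  structure(list(feature = feature_name, observed = base$observed,
                 expected = base$expected, ratio = obs, p = p,
                 n_perm = as.integer(n_perm), direction = direction,
                 perm_ratios = perm_ratios),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult '%s': ratio %.3f (obs %.4f / exp %.4f), %s, P = %.4g (%d permutations)\n",
    x$feature, x$ratio, x$observed, x$expected, x$direction, x$p, x$n_perm))
  invisible(x)
}

#' Define promoter intervals upstream of TSS
#'
#' Convenience helper: for each gene interval, the \code{upstream} nt
#' immediately 5' of its transcription start (strand-aware), clipped to the
#' chromosome. The 500-nt default is a package convention.
#'
#' @param genes Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @param seqlengths Named chromosome lengths, or a genome object.
#' @param upstream Promoter length in nt (default 500).
#' @return Data frame of promoter intervals.
#' @export
define_promoters <- function(genes, seqlengths, upstream = 500L) {
  if (inherits(seqlengths, "DNAStringSet") || is.character(seqlengths)) {
    seqlengths <- .genome_seqlengths(seqlengths)
  }
  plus <- genes$strand != "-"
  start <- ifelse(plus, pmax(0L, genes$start - upstream), genes$end)
  end <- ifelse(plus, genes$start,
                pmin(as.integer(seqlengths[genes$chrom]),
                     genes$end + upstream))
  out <- data.frame(chrom = genes$chrom, start = start, end = end,
                    strand = genes$strand)
  out[out$end > out$start, , drop = FALSE]
}
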