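#' Partition a genome into testing windows
#'
#' Tiles each chromosome with non-overlapping windows of \code{window_size}
#' nucleotides (the final partial window is kept). When a mappability track
#' is supplied, windows with fewer than \code{min_mappable} mappable
#' positions are flagged untestable; they are excluded both from the
#' hypergeometric test and from the Bonferroni multiplier.
#'
#' @param seqlengths Named chromosome lengths, or a genome object.
#' @param window_size Window width in nucleotides.
#' @param mappability Optional \code{MappabilityTrack}.
#' @param min_mappable Minimum mappable nucleotides for a window to be
#'   testable (default 20).
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{mappable_len}, \code{testable}.
#' @export
window_partition <- function(seqlengths, window_size, mappability = NULL,
                             min_mappable = 20L) {
  stopifnot(window_size >= 1L)
  if (inherits(seqlengths, "DNAStringSet") || is.character(seqlengths)) {
    seqlengths <- .genome_seqlengths(seqlengths)
  }
  win <- do.call(rbind, lapply(names(seqlengths), function(ch) {
    n <- seqlengths[[ch]]
    starts <- seq.int(0L, n - 1L, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, n))
  }))
  if (is.null(mappability)) {
    win$mappable_len <- win$end - win$start
  } else {
    win$mappable_len <- mappable_length(mappability, win)
  }
  win$testable <- win$mappable_len >= min_mappable
  win
}

#' One-sided hypergeometric enrichment P value for a window
#'
#' Under the null that the window draws its reads at random from the pooled
#' treatment + control read population, the number of treatment reads among
#' the \code{t + c} reads landing in the window is hypergeometric with
#' population \code{T + C}, success count \code{T} and \code{t + c} draws.
#' Returns the upper-tail probability \eqn{P[X \ge t]} (enrichment only).
#'
#' @param t,c Treatment and control read counts in the window.
#' @param T,C Genome-wide treatment and control totals.
#' @return P value(s) in \code{[0, 1]}; vectorised.
#' @export
hypergeom_window_p <- function(t, c, T, C) {
  tt <- t; cc <- c; TT <- T; CC <- C
  if (any(tt < 0) || any(cc < 0) || any(tt > TT) || any(cc > CC) ||
      any(TT + CC <= 0)) {
    stop("require 0 <= t <= T, 0 <= c <= C and T + C > 0")
  }
  stats::phyper(tt - 1, TT, CC, tt + cc, lower.tail = FALSE)
}

#' Call fragile (DSB-rich) regions
#'
#' Windowed hypergeometric test of treatment versus control break counts
#' with Bonferroni correction: for every testable window the one-sided
#' enrichment P value is computed with \code{\link{hypergeom_window_p}},
#' multiplied by the number of testable windows, and windows with adjusted
#' P below \code{alpha} are reported. The mappability correction follows
#' window exclusion: windows with fewer than \code{min_mappable} mappable
#' nucleotides are dropped from both testing and the Bonferroni multiplier.
#'
#' @param treatment,control Raw-count \code{BreakProfile}s on the same
#'   genome; the control is conventionally sonicated gDNA input.
#' @param window_size Window width in nucleotides (default 1000).
#' @param alpha Significance threshold on Bonferroni-adjusted P
#'   (default 0.001).
#' @param mappability Optional \code{MappabilityTrack}.
#' @param min_mappable Minimum mappable nucleotides per testable window.
#' @param bonferroni Count \code{"testable"} windows (default) or
#'   \code{"all"} windows in the multiplier.
#' @param return_all If \code{TRUE}, return every testable window regardless
#'   of significance.
#' @return Data frame with \code{chrom}, \code{start}, \code{end}, \code{t},
#'   \code{c}, \code{ratio} (\eqn{(t/T)/(c/C)}), \code{p_raw}, \code{p_adj},
#'   sorted by \code{p_adj} with coordinate tie-break. The number of
#'   testable windows is attached as attribute \code{"n_tested"}.
#' @export
call_fragile_regions <- function(treatment, control, window_size = 1000L,
                                 alpha = 0.001, mappability = NULL,
                                 min_mappable = 20L,
                                 bonferroni = c("testable", "all"),
                                 return_all = FALSE) {
  stopifnot(inherits(treatment, "BreakProfile"),
            inherits(control, "BreakProfile"))
  bonferroni <- match.arg(bonferroni)
  if (!identical(treatment$seqlengths, control$seqlengths)) {
    stop("treatment and control profiles are on different genomes")
  }
  if (treatment$normalized || control$normalized) {
    stop("fragile-region calling requires raw (unnormalized) counts")
  }
  win <- window_partition(treatment$seqlengths, window_size, mappability,
                          min_mappable)
  tc <- combined_counts(treatment)
  cc <- combined_counts(control)
  wsum <- function(counts) {
    out <- numeric(nrow(win))
    for (ch in names(counts)) {
      cs <- c(0, cumsum(counts[[ch]]))
      sel <- which(win$chrom == ch)
      out[sel] <- cs[win$end[sel] + 1L] - cs[win$start[sel] + 1L]
    }
    out
  }
  win$t <- round(wsum(tc))
  win$c <- round(wsum(cc))
  TT <- sum(win$t)
  CC <- sum(win$c)
  if (CC <= 0) stop("control profile has no reads")
  tw <- win[win$testable, , drop = FALSE]
  m <- if (bonferroni == "testable") nrow(tw) else nrow(win)
  tw$ratio <- (tw$t / TT) / ifelse(tw$c > 0, tw$c / CC, NA)
  tw$p_raw <- hypergeom_window_p(tw$t, tw$c, TT, CC)
  tw$p_adj <- pmin(1, tw$p_raw * m)
  ord <- order(tw$p_adj, tw$chrom, tw$start)
  tw <- tw[ord, c("chrom", "start", "end", "t", "c", "ratio",
                  "p_raw", "p_adj")]
  if (!return_all) tw <- tw[tw$p_adj < alpha, , drop = FALSE]
  rownames(tw) <- NULL
  attr(tw, "n_tested") <- m
  tw
}
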