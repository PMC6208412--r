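# Noise diagnostics: Pearson auto-/cross-correlation of positional signals,
# period estimation, and nucleosomal-noise classification.

# Extract per-chromosome combined numeric signals from a BreakProfile or a
# named list of numeric vectors.
.as_signals <- function(x) {
  if (inherits(x, "BreakProfile")) return(combined_counts(x))
  if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) return(x)
  stop("expected a BreakProfile or a named list of numeric vectors")
}

.bin_signal <- function(v, bin) {
  if (bin == 1L) return(v)
  nb <- length(v) %/% bin
  if (nb == 0L) return(numeric())
  colMeans(matrix(v[seq_len(nb * bin)], nrow = bin))
}

#' Cross-correlation of two positional signals
#'
#' For every integer shift \code{n}, computes the Pearson correlation
#' between signal \code{a} at position \code{i} and signal \code{b} at
#' position \code{i + n}, pooled over every position where both shifted
#' signals are defined. Chromosomes are concatenated into one pooled
#' correlation but pairs never span a chromosome boundary. A lag whose
#' overlap has zero variance in either signal yields a missing \code{r}
#' (never 0).
#'
#' @param a,b \code{BreakProfile}s (combined strands) or named lists of
#'   numeric vectors on the same genome.
#' @param max_lag Maximum absolute shift (default 800); lags run from
#'   \code{-max_lag} to \code{max_lag} unless \code{lags} is given.
#' @param bin Bin size; signals are averaged into \code{bin}-nt bins before
#'   correlating, and lags are then in bins (default 1).
#' @param lags Optional explicit integer lag vector.
#' @return Object of class \code{CorrelationProfile}: data frame with
#'   \code{lag}, \code{r}, \code{n_pairs}.
#' @export
cross_correlation <- function(a, b, max_lag = 800L, bin = 1L, lags = NULL) {
  sa <- .as_signals(a)
  sb <- .as_signals(b)
  if (!identical(names(sa), names(sb)) ||
      !identical(lengths(sa), lengths(sb))) {
    stop("signals are on different genomes")
  }
  stopifnot(bin >= 1L)
  if (bin > 1L) {
    sa <- lapply(sa, .bin_signal, bin = bin)
    sb <- lapply(sb, .bin_signal, bin = bin)
  }
  if (is.null(lags)) lags <- seq.int(-max_lag, max_lag)
  shortest <- min(lengths(sa))
  if (max(abs(lags)) >= shortest) {
    stop("max lag must be smaller than the shortest chromosome (", shortest,
         if (bin > 1L) " bins" else " nt", ")")
  }
  # per-chromosome prefix sums let each lag cost one dot product
  stats_for_lag <- function(n) {
    Sx <- Sy <- Sxx <- Syy <- Sxy <- 0
    np <- 0L
    for (ch in names(sa)) {
      x <- sa[[ch]]; y <- sb[[ch]]
      L <- length(x)
      if (L <= abs(n)) next
      if (n >= 0) {
        xi <- x[seq_len(L - n)]
        yi <- y[seq.int(n + 1L, L)]
      } else {
        xi <- x[seq.int(1L - n, L)]
        yi <- y[seq_len(L + n)]
      }
      Sx <- Sx + sum(xi); Sy <- Sy + sum(yi)
      Sxx <- Sxx + sum(xi * xi); Syy <- Syy + sum(yi * yi)
      Sxy <- Sxy + sum(xi * yi)
      np <- np + length(xi)
    }
    c(Sx, Sy, Sxx, Syy, Sxy, np)
  }
  res <- vapply(lags, stats_for_lag, numeric(6))
  np <- res[6, ]
  vx <- res[3, ] - res[1, ]^2 / np
  vy <- res[4, ] - res[2, ]^2 / np
  cov <- res[5, ] - res[1, ] * res[2, ] / np
  r <- ifelse(np > 1 & vx > 0 & vy > 0, cov / sqrt(vx * vy), NA_real_)
  structure(data.frame(lag = lags, r = r, n_pairs = as.integer(np)),
            class = c("CorrelationProfile", "data.frame"))
}

#' Autocorrelation of a positional signal
#'
#' Cross-correlation of a signal with itself, restricted to non-negative
#' lags (by symmetry \code{r(-n) = r(n)}).
#'
#' @param a \code{BreakProfile} or named list of numeric vectors.
#' @param max_lag Maximum lag (default 800).
#' @param bin Bin size before correlating (default 1).
#' @return A \code{CorrelationProfile} over lags \code{0..max_lag}.
#' @export
autocorrelation <- function(a, max_lag = 800L, bin = 1L) {
  sa <- .as_signals(a)
  if (all(vapply(sa, function(v) stats::var(v) == 0, logical(1)))) {
    stop("zero variance: signal is constant")
  }
  cross_correlation(sa, sa, bin = bin, lags = seq.int(0L, max_lag))
}

# Centered moving average, width w (odd); NA-padded at the edges.
.smooth_ma <- function(x, w = 5L) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# Indices of strict local maxima of v (NA-safe).
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  i <- 2:(n - 1)
  ok <- !is.na(v[i]) & !is.na(v[i - 1]) & !is.na(v[i + 1]) &
    v[i] > v[i - 1] & v[i] > v[i + 1]
  i[ok]
}

#' Estimate the dominant period of an autocorrelation profile
#'
#' Smooths the autocorrelation with a centered moving average (width 5),
#' finds strict local maxima within \code{search_range}, discards maxima not
#' exceeding the null band \code{3 / sqrt(n_pairs)}, and returns the lag of
#' the highest surviving maximum. Near-ties are resolved toward the
#' fundamental: among maxima within \code{tie_tol} (relative) of the best,
#' the smallest lag wins — a perfectly periodic signal has equally high
#' harmonic peaks at 2x, 3x, ... of the true period. The reported lag is
#' refined to the raw-correlation maximum within half the smoothing window
#' of the selected smoothed peak.
#'
#' @param profile A \code{CorrelationProfile} from
#'   \code{\link{autocorrelation}}.
#' @param search_range Two-element numeric; lags searched (default
#'   \code{c(50, 400)}).
#' @param smooth_width Moving-average width (default 5).
#' @param null_factor Multiplier on \code{1/sqrt(n_pairs)} for the null band
#'   (default 3).
#' @param tie_tol Relative tolerance for harmonic tie-breaking
#'   (default 0.01).
#' @return The period (lag) as an integer, or \code{NA} if no local maximum
#'   clears the null band.
#' @export
estimate_period <- function(profile, search_range = c(50, 400),
                            smooth_width = 5L, null_factor = 3,
                            tie_tol = 0.01) {
  stopifnot(inherits(profile, "CorrelationProfile"))
  sm <- .smooth_ma(profile$r, smooth_width)
  idx <- .local_maxima(sm)
  idx <- idx[profile$lag[idx] >= search_range[1] &
               profile$lag[idx] <= search_range[2]]
  if (!length(idx)) return(NA_integer_)
  band <- null_factor / sqrt(profile$n_pairs[idx])
  idx <- idx[sm[idx] > band]
  if (!length(idx)) return(NA_integer_)
  best <- max(sm[idx])
  idx <- idx[sm[idx] >= best * (1 - tie_tol)]
  pick <- idx[which.min(profile$lag[idx])]
  # refine on the unsmoothed correlation around the smoothed peak
  half <- smooth_width %/% 2L
  win <- pick + seq.int(-half, half)
  win <- win[win >= 1L & win <= nrow(profile) &
               profile$lag[win] >= search_range[1] &
               profile$lag[win] <= search_range[2]]
  win <- win[!is.na(profile$r[win])]
  profile$lag[win[which.max(profile$r[win])]]
}

#' Classify nucleosome-related noise in a break profile
#'
#' Cross-correlates the break profile with MNase-seq coverage (convention:
#' MNase signal elevated in nucleosome-depleted/linker regions) over lags
#' \code{-max_lag..max_lag}. A global maximum at \code{|lag| <= center_band}
#' means breaks are enriched between nucleosomes
#' (\code{"inter_nucleosomal"}). Otherwise the dominant local maximum on
#' each side of zero is examined: if both fall at
#' \code{nuc_band[1] <= |lag| <= nuc_band[2]} (necessarily on opposite
#' signs) and clear the null band \code{3/sqrt(n_pairs)}, breaks are
#' enriched within nucleosomes (\code{"nucleosomal_noise"}, the
#' over-fixation artifact signature); anything else is
#' \code{"unpatterned"}.
#'
#' @param break_profile,mnase_profile \code{BreakProfile}s (or named signal
#'   lists) on the same genome.
#' @param max_lag Maximum shift (default 400).
#' @param center_band Half-width of the "between nucleosomes" band
#'   (default 20).
#' @param nuc_band Two-element band for within-nucleosome peaks
#'   (default \code{c(60, 100)}).
#' @param smooth_width Moving-average width for peak calling (default 5).
#' @return List with \code{classification}, \code{peaks} (data frame of
#'   local maxima: lag, smoothed r), and \code{profile} (the
#'   \code{CorrelationProfile}).
#' @export
classify_noise <- function(break_profile, mnase_profile, max_lag = 400L,
                           center_band = 20L, nuc_band = c(60L, 100L),
                           smooth_width = 5L) {
  cc <- cross_correlation(break_profile, mnase_profile, max_lag = max_lag)
  sm <- .smooth_ma(cc$r, smooth_width)
  gmax_i <- which.max(sm)
  idx <- .local_maxima(sm)
  peaks <- data.frame(lag = cc$lag[idx], r = sm[idx],
                      band = 3 / sqrt(cc$n_pairs[idx]))
  peaks <- peaks[order(-peaks$r), , drop = FALSE]
  rownames(peaks) <- NULL
  classification <- "unpatterned"
  if (length(gmax_i) && abs(cc$lag[gmax_i]) <= center_band) {
    classification <- "inter_nucleosomal"
  } else {
    pos <- peaks[peaks$lag > 0, , drop = FALSE]
    neg <- peaks[peaks$lag < 0, , drop = FALSE]
    if (nrow(pos) && nrow(neg)) {
      top <- rbind(pos[1, ], neg[1, ])   # dominant maximum per side
      ok <- abs(top$lag) >= nuc_band[1] & abs(top$lag) <= nuc_band[2] &
        top$r > top$band
      if (all(ok)) classification <- "nucleosomal_noise"
    }
  }
  list(classification = classification, peaks = peaks, profile = cc)
}
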