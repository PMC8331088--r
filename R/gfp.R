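# Global field power and map similarity ------------------------------------

#' Global field power
#'
#' GFP at time t is the standard deviation of the potentials over all
#' electrodes of the average-referenced map at t, using the population
#' divisor (number of channels). It measures the instantaneous strength of
#' the whole-scalp electric field; its local maxima are the moments of
#' highest topographic signal-to-noise ratio.
#'
#' @param frames numeric matrix, channels x samples (or a single map vector).
#' @return numeric vector of per-sample GFP values (>= 0).
#' @export
gfp <- function(frames) {
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  mu <- colMeans(frames)
  sqrt(colMeans(frames^2) - mu^2)
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP curve, with a minimum inter-peak distance.
#' A sample is a candidate peak when it exceeds its left neighbour and is at
#' least as large as its right neighbour, so a run of tied maxima keeps only
#' its earliest sample. Candidates are then thinned greedily in order of
#' decreasing GFP (ties: earlier sample wins) so that retained peaks are at
#' least `min_distance_ms` apart. The first and last samples are never peaks.
#'
#' @param values numeric vector of GFP values (length >= 3).
#' @param fs sampling rate in Hz.
#' @param min_distance_ms minimum separation between retained peaks
#'   (default 10 ms), suppressing noise doublets.
#' @return integer vector of peak sample indices (strictly increasing).
#' @export
find_gfp_peaks <- function(values, fs, min_distance_ms = 10) {
  abort_if(length(values) < 3L, "need at least 3 samples to find peaks")
  check_scalar_number(fs, "fs", lower = 1e-12)
  check_scalar_number(min_distance_ms, "min_distance_ms", lower = 0)
  n <- length(values)
  i <- 2:(n - 1L)
  cand <- i[values[i] > values[i - 1L] & values[i] >= values[i + 1L]]
  if (length(cand) == 0L) return(integer(0))
  min_gap <- min_distance_ms / 1000 * fs
  # greedy keep-highest: order by value desc, index asc
  ord <- cand[order(-values[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (length(kept) == 0L || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels. Under polarity invariance (the
#' default, as in spontaneous-EEG microstate analysis) the absolute value is
#' returned, so a map and its sign-flipped copy are identical.
#'
#' @param m1,m2 numeric vectors of equal length (one value per channel),
#'   neither constant.
#' @param polarity_invariant take `abs()` of the correlation (default TRUE).
#' @return similarity in `[0, 1]` (invariant) or `[-1, 1]`.
#' @export
spatial_correlation <- function(m1, m2, polarity_invariant = TRUE) {
  abort_if(length(m1) != length(m2), "maps must have equal channel counts")
  abort_if(stats::sd(m1) == 0 || stats::sd(m2) == 0,
           "spatial correlation is undefined for a constant map")
  r <- stats::cor(m1, m2)
  if (polarity_invariant) abs(r) else r
}

# correlations of every column of `frames` with every column of `maps`;
# rows of the result index frames, columns index maps. Zero-variance frames
# yield 0 (callers treat them as unassignable).
cor_frames_maps <- function(frames, maps, polarity_invariant = TRUE) {
  fc <- sweep(frames, 2L, colMeans(frames))
  mc <- sweep(maps, 2L, colMeans(maps))
  fn <- sqrt(colSums(fc^2))
  mn <- sqrt(colSums(mc^2))
  r <- crossprod(fc, mc)
  denom <- outer(fn, mn)
  ok <- denom > 0
  r[ok] <- r[ok] / denom[ok]
  r[!ok] <- 0
  if (polarity_invariant) abs(r) else r
}
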