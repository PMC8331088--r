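# Backfitting templates onto continuous data ---------------------------------

# data of x as a list of channels x samples matrices (one per kept epoch)
epoch_matrices <- function(x) {
  if (inherits(x, "eeg_epochs")) {
    lapply(which(x$kept_mask), function(e) x$data[, , e])
  } else if (inherits(x, "eeg_recording")) {
    list(x$data)
  } else stop("expected an eeg_recording or eeg_epochs object", call. = FALSE)
}

# midpoint interpolation of peak labels over one epoch of `n` samples:
# each sample inherits the label of its nearest peak; equidistant samples go
# to the earlier peak; samples outside the first/last peak inherit that peak.
interpolate_peak_labels <- function(n, peaks, peak_labels) {
  out <- rep(NA_integer_, n)
  if (length(peaks) == 0L) return(out)
  bounds <- c(0L, floor((peaks[-length(peaks)] + peaks[-1L]) / 2), n)
  for (j in seq_along(peaks))
    out[(bounds[j] + 1L):bounds[j + 1L]] <- peak_labels[j]
  out
}

#' Backfit templates onto EEG data
#'
#' Every GFP-peak frame is assigned to the template with the highest
#' polarity-invariant spatial correlation. Samples between peaks inherit the
#' label of the nearest peak in time (the inter-peak interval is split at its
#' midpoint; for an odd gap the extra sample goes with the earlier peak), and
#' samples before the first / after the last peak inherit that peak's label.
#' Epochs are processed independently, so labels never bleed across epoch
#' boundaries; an epoch without any GFP peak is left entirely unassigned,
#' with a warning.
#'
#' @param x an average-referenced [eeg_recording()] or [eeg_epochs()] object
#'   (rejected epochs are skipped).
#' @param templates a labeled [template_set()].
#' @param min_distance_ms minimum inter-peak distance for peak detection.
#' @return a [label_sequence()] over the concatenated kept epochs.
#' @export
backfit <- function(x, templates, min_distance_ms = 10) {
  stopifnot(inherits(templates, "template_set"))
  mats <- epoch_matrices(x)
  fs <- x$fs
  labs <- vector("list", length(mats))
  for (e in seq_along(mats)) {
    m <- mats[[e]]
    gv <- gfp(m)
    peaks <- find_gfp_peaks(gv, fs, min_distance_ms)
    if (length(peaks) == 0L) {
      warning(sprintf("epoch %d has no GFP peaks; all samples unassigned", e))
      labs[[e]] <- rep(NA_integer_, ncol(m))
      next
    }
    r <- cor_frames_maps(m[, peaks, drop = FALSE], templates$maps)
    peak_labels <- apply(r, 1L, which.max)
    labs[[e]] <- interpolate_peak_labels(ncol(m), peaks, peak_labels)
  }
  label_sequence(unlist(labs), fs, templates$class_labels,
                 epoch = rep(seq_along(mats), vapply(mats, ncol, 0L)))
}

#' Global explained variance
#'
#' Fraction of GFP-weighted topographic variance explained by the labeling:
#' `GEV = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2`, where `r_t` is the
#' polarity-invariant spatial correlation between the frame at t and the
#' template of its label, and both sums run over the labeled samples of the
#' evaluation set — the GFP peaks by default, or all samples.
#'
#' @param x the average-referenced [eeg_recording()] or [eeg_epochs()] the
#'   labels refer to.
#' @param labels a [label_sequence()] aligned with `x` (as produced by
#'   [backfit()], or a ground-truth sequence).
#' @param templates the labeled [template_set()].
#' @param at `"peaks"` (default) evaluates at GFP peaks only; `"all"` over
#'   every labeled sample.
#' @param min_distance_ms peak-detection spacing (peaks mode).
#' @return GEV in `[0, 1]`.
#' @export
gev <- function(x, labels, templates, at = c("peaks", "all"),
                min_distance_ms = 10) {
  at <- match.arg(at)
  stopifnot(inherits(labels, "label_sequence"), inherits(templates, "template_set"))
  mats <- epoch_matrices(x)
  total <- sum(vapply(mats, ncol, 0L))
  abort_if(total != length(labels$labels),
           sprintf("labels cover %d samples but data has %d",
                   length(labels$labels), total))
  num <- 0; den <- 0
  offset <- 0L
  for (m in mats) {
    gv <- gfp(m)
    idx <- if (at == "peaks") find_gfp_peaks(gv, x$fs, min_distance_ms)
           else seq_len(ncol(m))
    lab <- labels$labels[offset + idx]
    ok <- !is.na(lab) & gv[idx] > 1e-300
    if (any(ok)) {
      sel <- idx[ok]
      r <- cor_frames_cols(m[, sel, drop = FALSE], templates$maps, lab[ok])
      num <- num + sum((gv[sel] * r)^2)
      den <- den + sum(gv[sel]^2)
    }
    offset <- offset + ncol(m)
  }
  abort_if(den == 0, "no labeled, non-degenerate samples to evaluate GEV on")
  num / den
}

# |r| between frame j and maps[, pick[j]] for each column j
cor_frames_cols <- function(frames, maps, pick) {
  fc <- sweep(frames, 2L, colMeans(frames))
  mc <- sweep(maps, 2L, colMeans(maps))
  m <- mc[, pick, drop = FALSE]
  abs(colSums(fc * m) / (sqrt(colSums(fc^2)) * sqrt(colSums(m^2))))
}

#' Subject-level mean map per class
#'
#' Averages the frames assigned to each class — the subject-level topography
#' entering TANOVA. Frames are averaged as-is (the simulator's rectified
#' carrier and group-level analyses keep polarity consistent within a
#' subject).
#'
#' @param x an [eeg_recording()] or [eeg_epochs()] object.
#' @param labels aligned [label_sequence()].
#' @param at `"peaks"` (default) averages peak frames only, `"all"` every
#'   labeled sample.
#' @param min_distance_ms peak-detection spacing (peaks mode).
#' @return channels x K matrix of average-referenced mean maps (columns named
#'   by class); classes that never occur yield `NA` columns.
#' @export
class_mean_maps <- function(x, labels, at = c("peaks", "all"),
                            min_distance_ms = 10) {
  at <- match.arg(at)
  mats <- epoch_matrices(x)
  k <- length(labels$classes)
  nc <- nrow(mats[[1L]])
  acc <- matrix(0, nc, k); cnt <- integer(k)
  offset <- 0L
  for (m in mats) {
    idx <- if (at == "peaks") find_gfp_peaks(gfp(m), x$fs, min_distance_ms)
           else seq_len(ncol(m))
    lab <- labels$labels[offset + idx]
    for (ki in seq_len(k)) {
      sel <- idx[!is.na(lab) & lab == ki]
      if (length(sel)) {
        acc[, ki] <- acc[, ki] + rowSums(m[, sel, drop = FALSE])
        cnt[ki] <- cnt[ki] + length(sel)
      }
    }
    offset <- offset + ncol(m)
  }
  out <- sweep(acc, 2L, pmax(cnt, 1L), "/")
  out[, cnt == 0L] <- NA_real_
  out <- average_reference.default(out)
  colnames(out) <- labels$classes
  out
}
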