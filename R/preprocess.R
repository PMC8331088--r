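# Preprocessing: epoching, filtering, referencing, artifact handling --------

#' Construct an epochs object
#'
#' Epochs are consecutive, non-overlapping, equal-length blocks of a
#' recording, stored as a channels x samples-per-epoch x n-epochs array with a
#' per-epoch keep mask.
#'
#' @param data 3-d numeric array (channels x epoch samples x epochs).
#' @param fs sampling rate (Hz).
#' @param montage the source [montage()].
#' @param kept_mask logical vector, one flag per epoch (default all TRUE).
#' @param subject_id,condition labels carried over from the recording.
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, montage, kept_mask = NULL,
                       subject_id = NA_character_, condition = NA_character_) {
  abort_if(length(dim(data)) != 3L, "epoch data must be a 3-d array")
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(data)[3L])
  abort_if(length(kept_mask) != dim(data)[3L], "one keep flag per epoch required")
  structure(list(data = data, fs = fs, montage = montage,
                 kept_mask = kept_mask,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %s [%s]: %d epochs x %d channels x %d samples @ %g Hz (%d kept)\n",
              x$subject_id, x$condition, d[3L], d[1L], d[2L], x$fs,
              sum(x$kept_mask)))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[3L]
epoch_samples <- function(ep) dim(ep$data)[2L]

#' Split a recording into non-overlapping epochs
#'
#' The recording is cut into `floor(n_samples / (epoch_length * fs))`
#' consecutive blocks; a trailing remainder shorter than one epoch is
#' discarded.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_length epoch length in seconds (default 2 s); `epoch_length *
#'   fs` must be a whole number of samples.
#' @return an [eeg_epochs()] object.
#' @export
epoch_recording <- function(rec, epoch_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar_number(epoch_length, "epoch_length", lower = 1e-12)
  len <- epoch_length * rec$fs
  abort_if(abs(len - round(len)) > 1e-9,
           "epoch_length * fs must be an integer number of samples")
  len <- as.integer(round(len))
  k <- n_samples(rec) %/% len
  dat <- if (k == 0L) array(0, dim = c(nrow(rec$data), len, 0L))
         else array(rec$data[, seq_len(k * len), drop = FALSE],
                    dim = c(nrow(rec$data), len, k))
  eeg_epochs(dat, rec$fs, rec$montage, subject_id = rec$subject_id,
             condition = rec$condition)
}

#' Concatenate kept epochs back into a continuous matrix
#'
#' @param ep an [eeg_epochs()] object.
#' @param kept_only drop rejected epochs (default TRUE).
#' @return channels x samples matrix.
#' @export
concatenate_epochs <- function(ep, kept_only = TRUE) {
  stopifnot(inherits(ep, "eeg_epochs"))
  idx <- if (kept_only) which(ep$kept_mask) else seq_len(n_epochs(ep))
  matrix(ep$data[, , idx], nrow = dim(ep$data)[1L],
         dimnames = list(ep$montage$name, NULL))
}

# zero-phase 4th-order Butterworth band-pass of one channels x samples matrix.
# Each channel is demeaned and padded by odd reflection (about three high-pass
# time constants) before forward-backward filtering, so edge transients decay
# inside the padding rather than in the data.
butter_bandpass_matrix <- function(x, lo, hi, fs, order = 4L) {
  nyq <- fs / 2
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  n <- ncol(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / lo)))
  t(apply(x, 1L, function(ch) {
    mu <- mean(ch)
    ch <- ch - mu
    if (pad > 0L) {
      xp <- c(2 * ch[1L] - ch[(pad + 1L):2L], ch,
              2 * ch[n] - ch[(n - 1L):(n - pad)])
      signal::filtfilt(flt, xp)[(pad + 1L):(pad + n)]
    } else {
      signal::filtfilt(flt, ch)
    }
  }))
}

#' Zero-phase band-pass filter
#'
#' A 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase), so topography timing is preserved. The DC component falls
#' inside the stop band and is removed. Works on recordings (continuous) and
#' on epochs (each epoch filtered independently).
#'
#' @param x an [eeg_recording()] or [eeg_epochs()] object.
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @return object of the same class, filtered.
#' @export
bandpass <- function(x, lo, hi) UseMethod("bandpass")

check_band <- function(lo, hi, fs) {
  check_scalar_number(lo, "lo", lower = 1e-12)
  check_scalar_number(hi, "hi")
  abort_if(!(lo < hi && hi < fs / 2),
           sprintf("invalid band [%g, %g] Hz for fs = %g (need 0 < lo < hi < fs/2)",
                   lo, hi, fs))
}

#' @export
bandpass.eeg_recording <- function(x, lo, hi) {
  check_band(lo, hi, x$fs)
  x$data <- butter_bandpass_matrix(x$data, lo, hi, x$fs)
  rownames(x$data) <- x$montage$name
  x
}

#' @export
bandpass.eeg_epochs <- function(x, lo, hi) {
  check_band(lo, hi, x$fs)
  for (e in seq_len(n_epochs(x)))
    x$data[, , e] <- butter_bandpass_matrix(x$data[, , e], lo, hi, x$fs)
  x
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over channels, so each map has zero
#' channel mean. Idempotent; invariant to adding any common signal to all
#' channels.
#'
#' @param x an [eeg_recording()], [eeg_epochs()] object, or a channels x
#'   samples matrix.
#' @return same class as the input, average-referenced.
#' @export
average_reference <- function(x) UseMethod("average_reference")

#' @export
average_reference.default <- function(x) {
  x <- as.matrix(x)
  abort_if(nrow(x) < 2L, "average reference needs at least 2 channels")
  sweep(x, 2L, colMeans(x))
}

#' @export
average_reference.eeg_recording <- function(x) {
  x$data <- average_reference.default(x$data)
  rownames(x$data) <- x$montage$name
  x
}

#' @export
average_reference.eeg_epochs <- function(x) {
  for (e in seq_len(n_epochs(x)))
    x$data[, , e] <- average_reference.default(x$data[, , e])
  x
}

#' Reject artifact epochs by amplitude threshold
#'
#' Marks as rejected every epoch whose peak absolute voltage exceeds the
#' threshold on any channel (a deterministic stand-in for visual artifact
#' rejection). Data are left untouched; only `kept_mask` changes.
#'
#' @param ep an [eeg_epochs()] object.
#' @param abs_threshold_uv rejection threshold in microvolts (default 100).
#' @return the epochs object with an updated `kept_mask`.
#' @export
reject_epochs <- function(ep, abs_threshold_uv = 100) {
  stopifnot(inherits(ep, "eeg_epochs"))
  check_scalar_number(abs_threshold_uv, "abs_threshold_uv", lower = 1e-12)
  if (n_epochs(ep) == 0L) return(ep)
  peak <- apply(abs(ep$data), 3L, max)
  ep$kept_mask <- ep$kept_mask & (peak <= abs_threshold_uv)
  ep
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of its `k`
#' nearest good channels (Euclidean distance between electrode positions,
#' weights `1/d^p`). Good channels are untouched.
#'
#' @param rec an [eeg_recording()].
#' @param bad_names character vector of channel names to rebuild; must be a
#'   strict subset of the montage.
#' @param k number of neighbours (default 4, capped at the number of good
#'   channels).
#' @param power inverse-distance exponent (default 2).
#' @return the recording with bad channels reconstructed.
#' @export
interpolate_bad_channels <- function(rec, bad_names, k = 4L, power = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad_names) == 0L) return(rec)
  abort_if(!all(bad_names %in% rec$montage$name),
           "bad_names contains channels absent from the montage")
  abort_if(length(unique(bad_names)) >= nrow(rec$montage),
           "cannot interpolate: no good channels left")
  k <- check_count(k, "k")
  pos <- montage_positions(rec$montage)
  bad_idx <- match(unique(bad_names), rec$montage$name)
  good_idx <- setdiff(seq_len(nrow(pos)), bad_idx)
  for (b in bad_idx) {
    d <- sqrt(rowSums((pos[good_idx, , drop = FALSE] -
                         matrix(pos[b, ], length(good_idx), 3, byrow = TRUE))^2))
    nn <- good_idx[order(d)][seq_len(min(k, length(good_idx)))]
    dn <- d[order(d)][seq_len(min(k, length(good_idx)))]
    if (any(dn < 1e-12)) {            # coincident electrode: copy it
      rec$data[b, ] <- rec$data[nn[which.min(dn)], ]
    } else {
      w <- 1 / dn^power
      rec$data[b, ] <- drop(w %*% rec$data[nn, , drop = FALSE]) / sum(w)
    }
  }
  rec
}
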