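# Temporal microstate parameters ---------------------------------------------

#' Run-length segmentation of a label sequence
#'
#' Maximal contiguous runs of one class, computed per epoch (runs never span
#' epoch boundaries). Unassigned samples are excluded and terminate runs.
#'
#' @param labels a [label_sequence()].
#' @return data.frame with columns `epoch`, `class` (class name), `start`
#'   (1-based global sample index) and `length` (samples); zero rows for an
#'   empty or fully unassigned sequence.
#' @export
segment_runs <- function(labels) {
  stopifnot(inherits(labels, "label_sequence"))
  n <- length(labels$labels)
  if (n == 0L)
    return(data.frame(epoch = integer(0), class = character(0),
                      start = integer(0), length = integer(0)))
  # a run breaks where the class changes, the epoch changes, or NA intervenes
  key <- paste(labels$epoch, labels$labels)
  key[is.na(labels$labels)] <- NA
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  data.frame(epoch = labels$epoch[starts[keep]],
             class = labels$classes[labels$labels[starts[keep]]],
             start = starts[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Temporal microstate parameters: duration, occurrence, coverage
#'
#' Per class: mean dwell duration (seconds, pooled over all runs of the
#' subject), occurrence rate (runs per second of labeled time) and coverage
#' (fraction of labeled samples). In the default `inclusive` mode every run
#' counts, so `coverage = duration * occurrence` holds exactly per class. In
#' `trim_edges` mode, each epoch's first and last run — dwells truncated by
#' the epoch boundary — are excluded from duration and occurrence (but not
#' from coverage).
#'
#' A summary row with class `"mean"` reports the overall mean dwell (labeled
#' time / number of runs), the total occurrence rate (sum over classes) and
#' total coverage (1 by construction).
#'
#' @param labels a [label_sequence()].
#' @param mode `"inclusive"` (default) or `"trim_edges"`.
#' @param subject_id,condition identifiers copied into the output table.
#' @return a data.frame of class `microstate_params` with columns
#'   `subject_id`, `condition`, `class`, `duration_s`, `occurrence_hz`,
#'   `coverage`. Classes that never occur get `NA` duration, 0 occurrence and
#'   0 coverage.
#' @export
temporal_parameters <- function(labels, mode = c("inclusive", "trim_edges"),
                                subject_id = NA_character_,
                                condition = NA_character_) {
  mode <- match.arg(mode)
  runs <- segment_runs(labels)
  abort_if(nrow(runs) == 0L, "no labeled runs: cannot compute temporal parameters")
  fs <- labels$fs
  labeled_samples <- sum(runs$length)
  labeled_time <- labeled_samples / fs

  counted <- runs
  if (mode == "trim_edges") {
    first_last <- unlist(lapply(split(seq_len(nrow(runs)), runs$epoch),
                                function(i) unique(c(i[1L], i[length(i)]))))
    counted <- runs[-first_last, , drop = FALSE]
  }
  classes <- labels$classes
  per_class <- lapply(classes, function(cl) {
    cr <- counted[counted$class == cl, , drop = FALSE]
    all_r <- runs[runs$class == cl, , drop = FALSE]
    data.frame(
      subject_id = subject_id, condition = condition, class = cl,
      duration_s = if (nrow(cr)) mean(cr$length) / fs else NA_real_,
      occurrence_hz = nrow(cr) / labeled_time,
      coverage = sum(all_r$length) / labeled_samples,
      stringsAsFactors = FALSE)
  })
  mean_row <- data.frame(
    subject_id = subject_id, condition = condition, class = "mean",
    duration_s = if (nrow(counted)) sum(counted$length) / fs / nrow(counted)
                 else NA_real_,
    occurrence_hz = nrow(counted) / labeled_time,
    coverage = 1,
    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, per_class), mean_row)
  rownames(out) <- NULL
  class(out) <- c("microstate_params", "data.frame")
  out
}
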