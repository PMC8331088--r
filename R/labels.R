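# Per-sample microstate label sequences -------------------------------------

#' Construct a label sequence
#'
#' A per-sample sequence of microstate class indices, with `NA` marking
#' unassigned samples. Each sample belongs to an epoch; runs of one class
#' never span epoch boundaries (a continuous, unepoched sequence is a single
#' epoch).
#'
#' @param labels integer vector of class indices in `1..K`, `NA` = unassigned.
#' @param fs sampling rate (Hz).
#' @param classes character vector of the K class names.
#' @param epoch integer vector assigning each sample to an epoch (same length
#'   as `labels`, non-decreasing), or `NULL` for a single epoch.
#' @return object of class `label_sequence`.
#' @export
label_sequence <- function(labels, fs, classes, epoch = NULL) {
  check_scalar_number(fs, "fs", lower = 1e-12)
  labels <- as.integer(labels)
  k <- length(classes)
  abort_if(any(!is.na(labels) & (labels < 1L | labels > k)),
           "labels must index into `classes`")
  if (is.null(epoch)) epoch <- rep(1L, length(labels))
  abort_if(length(epoch) != length(labels),
           "`epoch` must have one entry per sample")
  abort_if(is.unsorted(epoch), "`epoch` must be non-decreasing")
  structure(list(labels = labels, fs = fs, classes = as.character(classes),
                 epoch = as.integer(epoch)),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, %d classes (%s), %d epoch(s), %d unassigned\n",
              length(x$labels), x$fs, length(x$classes),
              paste(x$classes, collapse = ""), length(unique(x$epoch)),
              sum(is.na(x$labels))))
  invisible(x)
}

#' @export
length.label_sequence <- function(x) length(x$labels)
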