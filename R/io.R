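# Recordings and on-disk formats -------------------------------------------

#' Construct an EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts; rows ordered
#'   and named as in the montage.
#' @param fs sampling rate (Hz).
#' @param montage a [montage()] with one row per data row.
#' @param subject_id subject identifier.
#' @param condition group/condition label (e.g. `HC`, `PD_OFF`, `PD_ON`).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, montage, subject_id = NA_character_,
                          condition = NA_character_) {
  data <- as.matrix(data)
  stopifnot(inherits(montage, "montage"))
  check_scalar_number(fs, "fs", lower = 1e-12)
  abort_if(nrow(data) != nrow(montage),
           sprintf("data has %d rows but montage has %d channels",
                   nrow(data), nrow(montage)))
  abort_if(!all(is.finite(data)), "recording contains non-finite samples")
  dimnames(data) <- list(montage$name, NULL)
  structure(list(data = data, fs = fs, montage = montage,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Read an EEG recording
#'
#' Supported formats, chosen by file extension:
#' * `.edf` — European Data Format (16-bit).
#' * `.csv` / `.tsv` — delimited channels x samples matrix (no header) with a
#'   JSON sidecar `<path>.json` holding `{fs, channel_names}`.
#'
#' Channels are checked against the montage and reordered to match it.
#'
#' @param path data file path.
#' @param montage_path path of a whitespace-delimited montage file
#'   (`name x y z`), or a [montage()] object.
#' @param subject_id,condition labels attached to the recording.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, montage_path, subject_id = NA_character_,
                           condition = NA_character_) {
  abort_if(!file.exists(path), sprintf("recording file not found: %s", path))
  mont <- if (inherits(montage_path, "montage")) montage_path
          else read_montage(montage_path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    edf = read_edf(path),
    csv = read_matrix_sidecar(path, sep = ","),
    tsv = read_matrix_sidecar(path, sep = "\t"),
    stop(sprintf("unknown recording format '.%s' (supported: edf, csv, tsv)", ext),
         call. = FALSE)
  )
  abort_if(!setequal(raw$channel_names, mont$name),
           sprintf("channel names in %s do not match the montage", path))
  data <- raw$data[match(mont$name, raw$channel_names), , drop = FALSE]
  abort_if(!all(is.finite(data)),
           sprintf("non-finite samples in %s", path))
  eeg_recording(data, raw$fs, mont, subject_id, condition)
}

#' Write an EEG recording
#'
#' `.csv`/`.tsv` writes the channels x samples matrix without header plus a
#' JSON sidecar `<path>.json` with the sampling rate and channel names;
#' `.edf` writes 16-bit EDF (microvolt units).
#'
#' @param rec an [eeg_recording()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    edf = write_edf(rec$data, rec$fs, rec$montage$name, path),
    csv = write_matrix_sidecar(rec, path, sep = ","),
    tsv = write_matrix_sidecar(rec, path, sep = "\t"),
    stop(sprintf("unknown recording format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

write_matrix_sidecar <- function(rec, path, sep = ",") {
  utils::write.table(rec$data, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$montage$name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_matrix_sidecar <- function(path, sep = ",") {
  sidecar <- paste0(path, ".json")
  abort_if(!file.exists(sidecar),
           sprintf("missing JSON sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  abort_if(is.null(meta$fs) || !is.numeric(meta$fs),
           sprintf("sidecar %s lacks a numeric `fs` field", sidecar))
  abort_if(is.null(meta$channel_names),
           sprintf("sidecar %s lacks `channel_names`", sidecar))
  data <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(data) <- NULL
  abort_if(nrow(data) != length(meta$channel_names),
           sprintf("%s: %d data rows but %d channel names in sidecar",
                   path, nrow(data), length(meta$channel_names)))
  list(data = data, fs = meta$fs, channel_names = as.character(meta$channel_names))
}
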