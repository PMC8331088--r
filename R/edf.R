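# Minimal European Data Format (EDF) support --------------------------------
#
# Plain EDF, one data record per second, 16-bit samples, physical unit uV.
# Only the subset needed to round-trip continuous multichannel EEG is
# implemented: equal sampling rate across signals, no annotations.

edf_pad <- function(x, width) {
  x <- as.character(x)
  abort_if(any(nchar(x) > width), "EDF header field overflow")
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  edf_pad(s, width)
}

#' Write a channels x samples matrix as EDF
#'
#' @param data numeric matrix (channels x samples), microvolts.
#' @param fs integer sampling rate; the total sample count must be a whole
#'   number of one-second records.
#' @param channel_names one name (<= 16 ASCII characters) per channel.
#' @param path output path.
#' @return `path`, invisibly.
#' @keywords internal
write_edf <- function(data, fs, channel_names, path) {
  data <- as.matrix(data)
  abort_if(fs != round(fs), "EDF writer requires an integer sampling rate")
  abort_if(ncol(data) %% fs != 0,
           "EDF writer requires a whole number of 1-s records; trim the data")
  abort_if(any(nchar(channel_names) > 16L), "EDF channel names are limited to 16 characters")
  ns <- nrow(data)
  n_rec <- ncol(data) %/% fs
  pm <- apply(abs(data), 1L, max)
  pm[pm == 0] <- 1
  # physical max must survive its 8-char ASCII field: use the printed value
  pm <- as.numeric(formatC(pm, format = "g", digits = 6))
  gain <- (2 * pm) / 65535            # (physmax - physmin) / (digmax - digmin)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80), edf_pad("synthetic recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(edf_pad(channel_names, 16), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep("uV", ns), 8), collapse = ""),
    paste(edf_num(-pm), collapse = ""),
    paste(edf_num(pm), collapse = ""),
    paste(edf_pad(rep("-32768", ns), 8), collapse = ""),
    paste(edf_pad(rep("32767", ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep(fs, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  dig <- round(sweep(sweep(data, 1L, -pm), 1L, gain, "/")) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain 16-bit EDF with a
#' common sampling rate across signals)
#'
#' @param path EDF file path.
#' @return list with `data` (channels x samples, physical units), `fs` and
#'   `channel_names`.
#' @keywords internal
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header size (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  abort_if(is.na(ns) || ns < 1L, sprintf("%s: malformed EDF header", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  replicate(ns, rd(80))                  # transducer
  replicate(ns, rd(8))                   # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(80))                  # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(32))
  abort_if(length(unique(spr)) != 1L,
           sprintf("%s: signals with mixed sampling rates are not supported", path))
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1L], ncol = ns)
    data[, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
      t(sweep(sweep(block, 2L, dig_min), 2L, gain, "*") + rep(phys_min, each = spr[1L]))
  }
  list(data = data, fs = fs, channel_names = labels)
}
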