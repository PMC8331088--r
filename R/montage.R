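# Electrode montages ------------------------------------------------------

#' Construct an electrode montage
#'
#' A montage is the set of named electrode positions on (or near) the unit
#' sphere of the head model. Positions use a right-handed coordinate system:
#' +x to the subject's right, +y anterior (nasion), +z up (vertex).
#'
#' @param channel_names character vector of unique channel names.
#' @param positions numeric matrix (n_channels x 3) of x, y, z coordinates.
#' @return an object of class `montage` (data.frame with columns
#'   `name`, `x`, `y`, `z`).
#' @export
montage <- function(channel_names, positions) {
  positions <- as.matrix(positions)
  abort_if(length(channel_names) < 8L, "a montage needs at least 8 channels")
  abort_if(anyDuplicated(channel_names) > 0L, "channel names must be unique")
  abort_if(nrow(positions) != length(channel_names) || ncol(positions) != 3L,
           "`positions` must be an n_channels x 3 matrix")
  abort_if(!all(is.finite(positions)), "positions must be finite")
  abort_if(anyDuplicated(round(positions, 12)) > 0L,
           "no two electrode positions may coincide")
  out <- data.frame(name = as.character(channel_names),
                    x = positions[, 1], y = positions[, 2], z = positions[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("montage", "data.frame")
  out
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... %d more\n", nrow(x) - 6L))
  invisible(x)
}

montage_positions <- function(m) as.matrix(as.data.frame(m)[, c("x", "y", "z")])

#' Generate a quasi-uniform upper-hemisphere montage
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper hemisphere of a
#' unit sphere using a Fibonacci lattice, with a small seeded angular jitter so
#' that different seeds give distinct but comparable montages. Channel names
#' are `E001`, `E002`, ... ordered from vertex outwards.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param seed integer seed; the montage is a pure function of
#'   `(n_channels, seed)`.
#' @return a [montage()].
#' @export
generate_montage <- function(n_channels, seed = 1L) {
  n_channels <- check_count(n_channels, "n_channels", lower = 8L)
  with_seed(seed, {
    i <- seq_len(n_channels) - 0.5
    # z in (0, 1): upper hemisphere only
    z <- 1 - i / n_channels
    golden <- pi * (3 - sqrt(5))
    theta <- golden * (seq_len(n_channels) - 1)
    # small jitter (~1 degree) to decouple seeds without breaking uniformity
    z <- pmin(pmax(z + stats::rnorm(n_channels, 0, 0.005), 0), 1)
    theta <- theta + stats::rnorm(n_channels, 0, 0.02)
    r <- sqrt(pmax(0, 1 - z^2))
    pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
    montage(sprintf("E%03d", seq_len(n_channels)), pos)
  })
}

#' Write / read a montage as whitespace-delimited text
#'
#' The on-disk format is four whitespace-separated columns with a header line:
#' `name x y z`.
#'
#' @param m a [montage()].
#' @param path file path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns a
#'   [montage()].
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  utils::write.table(as.data.frame(m), path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  abort_if(!file.exists(path), sprintf("montage file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  abort_if(!all(c("name", "x", "y", "z") %in% names(tab)),
           sprintf("montage file %s must have columns name x y z", path))
  montage(tab$name, as.matrix(tab[, c("x", "y", "z")]))
}
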