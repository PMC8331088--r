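# Topographic template sets ------------------------------------------------

#' Construct a template set
#'
#' A template set bundles K scalp maps (columns), their class labels, the
#' level at which they were estimated and, once backfitted, the global
#' explained variance on their source data. Maps are stored average-referenced
#' and scaled to unit global field power.
#'
#' @param maps numeric matrix, channels x K.
#' @param class_labels character vector of K unique labels (e.g. A-D).
#' @param level `"individual"` or `"group"`.
#' @param gev optional fraction of variance explained on the source data.
#' @param channel_names optional channel names (rownames of `maps`).
#' @return object of class `template_set`.
#' @export
template_set <- function(maps, class_labels = NULL, level = "individual",
                         gev = NA_real_, channel_names = NULL) {
  maps <- as.matrix(maps)
  k <- ncol(maps)
  if (is.null(class_labels)) class_labels <- default_class_labels(k)
  abort_if(length(class_labels) != k, "one label per map is required")
  abort_if(anyDuplicated(class_labels) > 0L, "class labels must be unique")
  abort_if(!level %in% c("individual", "group"), "level must be individual|group")
  abort_if(!is.na(gev) && (gev < 0 || gev > 1), "gev must lie in [0, 1]")
  maps <- apply(maps, 2L, normalize_map)
  dup <- duplicated(round(t(maps), 10)) | duplicated(round(-t(maps), 10))
  abort_if(any(dup[-1L]), "template maps must be pairwise distinct")
  colnames(maps) <- class_labels
  if (!is.null(channel_names)) rownames(maps) <- channel_names
  structure(list(maps = maps, class_labels = class_labels, level = level,
                 gev = gev),
            class = "template_set")
}

default_class_labels <- function(k) {
  abort_if(k > 26L, "at most 26 classes supported")
  LETTERS[seq_len(k)]
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d maps x %d channels, level=%s, gev=%s\n",
              ncol(x$maps), nrow(x$maps), x$level,
              ifelse(is.na(x$gev), "NA", sprintf("%.3f", x$gev))))
  cat("classes:", paste(x$class_labels, collapse = " "), "\n")
  invisible(x)
}

# average-reference and scale a map to unit GFP
normalize_map <- function(v) {
  v <- v - mean(v)
  g <- sqrt(mean(v^2))
  abort_if(g < 1e-300, "cannot normalize a constant map")
  v / g
}

gaussian_patch <- function(positions, center, sigma) {
  center <- center / sqrt(sum(center^2))
  d2 <- rowSums((positions - matrix(center, nrow(positions), 3, byrow = TRUE))^2)
  exp(-d2 / (2 * sigma^2))
}

# Canonical A-D scalp patterns evaluated on electrode positions.
# A: left-posterior <-> right-anterior diagonal gradient; B: mirrored diagonal;
# C: anterior <-> posterior (occipital positivity, frontal negativity, vertex
# emphasis); D: fronto-central focal positivity. Shape constants were fixed so
# that the four maps stay mutually distinct (|r| <= ~0.4) on quasi-uniform
# montages from 16 to 204 channels.
canonical_patterns <- function(positions) {
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  cbind(
    A = x + 0.7 * y,
    B = -x + 0.7 * y,
    C = gaussian_patch(positions, c(0, -0.8, 0.6), 0.3) -
        gaussian_patch(positions, c(0, 0.9, 0.45), 0.3) + 0.4 * z,
    D = gaussian_patch(positions, c(0, 0.25, 0.97), 0.6)
  )
}

#' Canonical microstate class templates A-D
#'
#' Builds the four canonical resting-state microstate topographies on an
#' arbitrary montage: A (left-posterior to right-anterior diagonal),
#' B (mirror-image diagonal), C (anterior-posterior), D (fronto-central
#' focal). These serve as the reference set for [label_templates()].
#'
#' @param montage a [montage()].
#' @return a `"group"`-level [template_set()] labeled A-D.
#' @export
canonical_templates <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  pat <- canonical_patterns(montage_positions(montage))
  template_set(pat, c("A", "B", "C", "D"), level = "group",
               channel_names = montage$name)
}

#' Generate ground-truth templates for simulation
#'
#' Draws K average-referenced, unit-GFP template maps on a montage. The first
#' four maps start from the canonical A-D patterns, further maps from random
#' smooth patches; each map is perturbed by a seeded smooth random field and
#' the whole set is redrawn until all pairwise polarity-invariant spatial
#' correlations are at most `max_abs_cor`.
#'
#' @param K number of templates (2 <= K <= n_channels).
#' @param montage a [montage()].
#' @param seed integer seed.
#' @param noise_scale relative amplitude of the smooth perturbation field.
#' @param max_abs_cor pairwise separation bound (default 0.5).
#' @param max_tries redraw budget before failing.
#' @return a `"group"`-level [template_set()] labeled A, B, C, D, E, ...
#' @export
generate_templates <- function(K, montage, seed = 1L, noise_scale = 0.3,
                               max_abs_cor = 0.5, max_tries = 50L) {
  stopifnot(inherits(montage, "montage"))
  K <- check_count(K, "K", lower = 2L)
  abort_if(K > nrow(montage), "K must not exceed the number of channels")
  pos <- montage_positions(montage)
  base <- canonical_patterns(pos)
  base <- apply(base, 2L, normalize_map)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      maps <- sapply(seq_len(K), function(k) {
        b <- if (k <= 4L) base[, k] else smooth_field(pos)
        normalize_map(normalize_map(b) + noise_scale * normalize_map(smooth_field(pos)))
      })
      r <- abs(stats::cor(maps))
      if (max(r[upper.tri(r)]) <= max_abs_cor)
        return(template_set(maps, default_class_labels(K), level = "group",
                            channel_names = montage$name))
    }
    stop(sprintf(
      "could not generate %d templates with pairwise |r| <= %.2f in %d tries",
      K, max_abs_cor, max_tries), call. = FALSE)
  })
}

# a smooth random scalp field: random linear gradient plus a few random patches
smooth_field <- function(positions) {
  dir <- stats::rnorm(3)
  v <- positions %*% (dir / sqrt(sum(dir^2)))
  for (i in 1:2) {
    c0 <- stats::rnorm(3); c0[3] <- abs(c0[3])
    v <- v + stats::rnorm(1, 0, 0.8) *
      gaussian_patch(positions, c0 / sqrt(sum(c0^2)), stats::runif(1, 0.4, 0.9))
  }
  drop(v)
}
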