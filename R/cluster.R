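# Atomize-and-agglomerate hierarchical clustering ----------------------------

# polarity-invariant centroid of a set of maps: dominant left singular vector
# of the member matrix, unit-GFP scaled, sign oriented to correlate
# positively with the lowest-index member (reproducible orientation).
aahc_centroid <- function(members) {
  if (ncol(members) == 1L) return(normalize_map(members[, 1L]))
  s <- La.svd(members, nu = 1L, nv = 0L)
  v <- normalize_map(s$u[, 1L])
  if (stats::cor(v, members[, 1L]) < 0) v <- -v
  v
}

#' Atomize-and-agglomerate hierarchical clustering of scalp maps
#'
#' Bottom-up polarity-invariant clustering of (GFP-peak) topographies. Every
#' map starts as its own cluster. At each step the cluster contributing least
#' to the global explained variance is dissolved ("atomized") and each of its
#' members is reassigned to the surviving cluster whose centroid it correlates
#' with most strongly (absolute spatial correlation); affected centroids are
#' then recomputed as the dominant eigenvector of their members (a
#' polarity-safe mean), scaled to unit GFP. The procedure stops at `K`
#' clusters. There is no random initialization; all ties are broken toward
#' the lowest map/cluster index, so the result is a deterministic function of
#' the input order.
#'
#' A cluster's GEV contribution is the sum over its members of
#' `(GFP_i * r_i)^2`, where `r_i` is the polarity-invariant spatial
#' correlation between member map i and the cluster centroid, normalized by
#' the total `sum(GFP^2)` of all maps.
#'
#' @param peak_maps numeric matrix, channels x n_maps: average-referenced,
#'   non-constant maps (typically frames at GFP peaks). Column weights are the
#'   maps' own GFP values.
#' @param K target number of clusters (`1 <= K <= n_maps`).
#' @param level provenance recorded in the result (`"individual"` or
#'   `"group"`).
#' @return a [template_set()] of the K centroids (classes labeled by position,
#'   A, B, ...), with `gev` set to the clustering's total GEV and the final
#'   map-to-cluster assignment in `attr(, "assignment")`.
#' @export
aahc <- function(peak_maps, K, level = "individual") {
  peak_maps <- as.matrix(peak_maps)
  n <- ncol(peak_maps)
  K <- check_count(K, "K")
  abort_if(K > n, sprintf("K = %d exceeds the number of maps (%d)", K, n))
  g <- gfp(peak_maps)
  abort_if(any(g < 1e-300), "peak maps must be non-constant")
  denom <- sum(g^2)

  members <- as.list(seq_len(n))          # cluster -> member map indices
  centroids <- apply(peak_maps, 2L, normalize_map)
  if (!is.matrix(centroids)) centroids <- matrix(centroids, ncol = n)
  # per-map squared contribution (gfp_i * r_i)^2 under current assignment
  contrib <- g^2                          # each map correlates 1 with itself

  cluster_gev <- function(ci) sum(contrib[members[[ci]]])

  while (length(members) > K) {
    worst <- which.min(vapply(seq_along(members), cluster_gev, 0))
    orphans <- members[[worst]]
    members[[worst]] <- NULL
    centroids <- centroids[, -worst, drop = FALSE]
    r <- cor_frames_maps(peak_maps[, orphans, drop = FALSE], centroids,
                         polarity_invariant = TRUE)
    dest <- apply(r, 1L, which.max)       # ties: lowest surviving cluster
    for (j in seq_along(orphans))
      members[[dest[j]]] <- sort(c(members[[dest[j]]], orphans[j]))
    for (ci in unique(dest)) {
      centroids[, ci] <- aahc_centroid(peak_maps[, members[[ci]], drop = FALSE])
      mi <- members[[ci]]
      contrib[mi] <- (g[mi] * cor_frames_maps(peak_maps[, mi, drop = FALSE],
                                              centroids[, ci, drop = FALSE]))^2
    }
  }
  assignment <- integer(n)
  for (ci in seq_along(members)) assignment[members[[ci]]] <- ci
  out <- template_set(centroids, default_class_labels(length(members)),
                      level = level, gev = sum(contrib) / denom,
                      channel_names = rownames(peak_maps))
  attr(out, "assignment") <- assignment
  out
}

#' Two-level (individual then group) clustering
#'
#' Runs [aahc()] on each subject's GFP-peak maps to obtain K individual
#' templates, pools all individual templates, and runs [aahc()] again on the
#' pool to obtain K group templates.
#'
#' @param per_subject_peak_maps list of channels x n_peaks matrices, one per
#'   subject.
#' @param K number of template maps per level.
#' @return a `"group"`-level [template_set()]; the per-subject individual
#'   template sets are attached as `attr(, "individual")`.
#' @export
two_level_cluster <- function(per_subject_peak_maps, K) {
  abort_if(!is.list(per_subject_peak_maps) || length(per_subject_peak_maps) == 0L,
           "need at least one subject's peak maps")
  individual <- lapply(per_subject_peak_maps, aahc, K = K, level = "individual")
  pool <- do.call(cbind, lapply(individual, function(ts) ts$maps))
  out <- aahc(pool, K, level = "group")
  attr(out, "individual") <- individual
  out
}

perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Label templates against a canonical reference set
#'
#' Finds the one-to-one assignment of templates to canonical classes that
#' maximizes the total polarity-invariant spatial correlation, by exhaustive
#' enumeration of the K! permutations (exact for the K <= 8 used in
#' practice). Ties are resolved toward the lexicographically first
#' permutation, so the labeling is deterministic in the input order.
#'
#' @param templates a [template_set()] to relabel.
#' @param canonical the reference [template_set()] (e.g.
#'   [canonical_templates()]), same K and channel count.
#' @return the template set with columns reordered to canonical label order
#'   and `class_labels` taken from `canonical`; the permutation used is in
#'   `attr(, "permutation")` (canonical class -> original template index) and
#'   the achieved total similarity in `attr(, "total_similarity")`.
#' @export
label_templates <- function(templates, canonical) {
  stopifnot(inherits(templates, "template_set"), inherits(canonical, "template_set"))
  k <- ncol(templates$maps)
  abort_if(k != ncol(canonical$maps), "template sets must have equal K")
  abort_if(nrow(templates$maps) != nrow(canonical$maps),
           "template sets must share the channel set")
  abort_if(k > 8L, "exhaustive labeling supports at most K = 8")
  r <- cor_frames_maps(templates$maps, canonical$maps)  # templates x canonical
  pp <- perms(k)
  dimnames(pp) <- NULL
  scores <- apply(pp, 1L, function(p) sum(r[cbind(p, seq_len(k))]))
  best <- as.integer(pp[which.max(scores), ])  # best[j] = template for class j
  out <- templates
  out$maps <- templates$maps[, best, drop = FALSE]
  out$class_labels <- canonical$class_labels
  colnames(out$maps) <- out$class_labels
  attr(out, "permutation") <- best
  attr(out, "total_similarity") <- max(scores)
  attr(out, "assignment") <- NULL
  out
}

#' Extract frames at GFP peaks
#'
#' Convenience used before clustering: collects the topographic maps at the
#' GFP peaks of each kept epoch (or of the whole recording).
#'
#' @param x an [eeg_recording()] or [eeg_epochs()] object.
#' @param min_distance_ms minimum inter-peak distance (see
#'   [find_gfp_peaks()]).
#' @param max_maps optional cap; if more peaks are found, an evenly spaced
#'   subset of this size is kept (keeps individual-level clustering tractable
#'   on long recordings).
#' @return channels x n_peaks matrix of peak maps.
#' @export
gfp_peak_maps <- function(x, min_distance_ms = 10, max_maps = Inf) {
  dat <- if (inherits(x, "eeg_epochs")) {
    fs <- x$fs
    lapply(which(x$kept_mask), function(e) x$data[, , e])
  } else if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    list(x$data)
  } else stop("x must be an eeg_recording or eeg_epochs object", call. = FALSE)
  maps <- lapply(dat, function(m) {
    p <- find_gfp_peaks(gfp(m), fs, min_distance_ms)
    m[, p, drop = FALSE]
  })
  n_ch <- if (inherits(x, "eeg_epochs")) dim(x$data)[1L] else nrow(x$data)
  maps <- if (length(maps)) do.call(cbind, maps)
          else matrix(0, n_ch, 0L)
  if (ncol(maps) > max_maps) {
    keep <- unique(round(seq(1L, ncol(maps), length.out = max_maps)))
    maps <- maps[, keep, drop = FALSE]
  }
  maps
}
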