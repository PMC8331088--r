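# Independent, deliberately plain re-implementations used as oracles.

# population-SD field strength of one map
oracle_gfp1 <- function(v) sqrt(mean((v - mean(v))^2))

# polarity-invariant centroid: first eigenvector of the member outer-product
# sum (eigen() route, vs the package's SVD), unit GFP, sign to first member
oracle_centroid <- function(members) {
  if (ncol(members) == 1L) {
    v <- members[, 1L]
  } else {
    v <- eigen(members %*% t(members), symmetric = TRUE)$vectors[, 1L]
  }
  v <- v - mean(v)
  v <- v / oracle_gfp1(v)
  if (cor(v, members[, 1L]) < 0) v <- -v
  v
}

# step-by-step greedy atomize/reassign clustering, loop-based throughout
oracle_aahc <- function(maps, K) {
  n <- ncol(maps)
  g <- apply(maps, 2L, oracle_gfp1)
  clusters <- lapply(seq_len(n), function(i) i)
  centroids <- lapply(seq_len(n), function(i) {
    v <- maps[, i] - mean(maps[, i]); v / oracle_gfp1(v)
  })
  while (length(clusters) > K) {
    contrib <- sapply(seq_along(clusters), function(ci) {
      sum(sapply(clusters[[ci]], function(i)
        (g[i] * abs(cor(maps[, i], centroids[[ci]])))^2))
    })
    worst <- which.min(contrib)
    orphans <- clusters[[worst]]
    clusters[[worst]] <- NULL
    centroids[[worst]] <- NULL
    for (i in orphans) {
      r <- sapply(centroids, function(ce) abs(cor(maps[, i], ce)))
      d <- which.max(r)
      clusters[[d]] <- sort(c(clusters[[d]], i))
    }
    for (ci in seq_along(clusters))
      centroids[[ci]] <- oracle_centroid(maps[, clusters[[ci]], drop = FALSE])
  }
  assignment <- integer(n)
  for (ci in seq_along(clusters)) assignment[clusters[[ci]]] <- ci
  list(assignment = assignment,
       centroids = do.call(cbind, centroids),
       gev = sum(sapply(seq_len(n), function(i)
         (g[i] * abs(cor(maps[, i], centroids[[assignment[i]]])))^2)) / sum(g^2))
}

# exhaustive between-design randomization distribution of the group-mean GMD
oracle_tanova_between <- function(maps1, maps2) {
  unit <- function(v) { v <- v - mean(v); v / sqrt(mean(v^2)) }
  gmd1 <- function(a, b) sqrt(mean((unit(a) - unit(b))^2))
  pool <- cbind(maps1, maps2)
  n1 <- ncol(maps1); n <- ncol(pool)
  obs <- gmd1(rowMeans(maps1), rowMeans(maps2))
  splits <- combn(n, n1)
  stats <- apply(splits, 2L, function(sel)
    gmd1(rowMeans(pool[, sel, drop = FALSE]),
         rowMeans(pool[, -sel, drop = FALSE])))
  list(observed = obs, p = mean(stats >= obs - 1e-15), stats = stats)
}
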