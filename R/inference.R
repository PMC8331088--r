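# Group statistics: TANOVA, t-tests, clinical correlations --------------------

#' Global map dissimilarity
#'
#' Root-mean-square difference between two maps after each is
#' average-referenced and scaled to unit GFP. Polarity is *not* collapsed:
#' group-mean maps carry consistent polarity, and the maximum dissimilarity 2
#' is reached by a map and its sign-flipped copy. For unit-GFP maps,
#' `gmd^2 = 2 - 2 * r` where r is the (signed) spatial correlation.
#'
#' @param m1,m2 numeric vectors (one value per channel), non-constant.
#' @return dissimilarity in `[0, 2]`.
#' @export
gmd <- function(m1, m2) {
  abort_if(length(m1) != length(m2), "maps must have equal channel counts")
  sqrt(mean((normalize_map(m1) - normalize_map(m2))^2))
}

# column-wise normalize to zero mean / unit GFP
normalize_cols <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  g <- sqrt(colMeans(m^2))
  sweep(m, 2L, pmax(g, 1e-300), "/")
}

# gmd between paired columns of two channels x n matrices
gmd_cols <- function(a, b) sqrt(colMeans((normalize_cols(a) - normalize_cols(b))^2))

#' Topographic randomization test (TANOVA)
#'
#' Nonparametric randomization test on the global map dissimilarity between
#' two group-mean topographies. The observed statistic is the GMD between the
#' mean maps of the two groups (or conditions). The null distribution is
#' built by randomly permuting group membership (between-subject design) or by
#' swapping the two conditions within each subject (within-subject design).
#' The permutation p-value uses the add-one estimator
#' `p = (1 + #permutations >= observed) / (1 + n_permutations)`, so it is
#' never exactly zero. If fewer distinct relabelings exist than requested,
#' the test switches to exhaustive enumeration (p = proportion of all
#' relabelings, including the identity, at or above the observed statistic)
#' and says so in the result.
#'
#' @param maps1,maps2 channels x subjects matrices of subject-level maps (e.g.
#'   [class_mean_maps()] output for one class). For a within design, columns
#'   must be the same subjects in the same order. Subjects with any `NA`
#'   value are dropped pairwise (within) or per group (between).
#' @param design `"between"` or `"within"`.
#' @param n_permutations random permutations requested (default 5000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return list of class `tanova_result`: `observed_gmd`, `p`,
#'   `n_permutations` (actually used), `design`, `exhaustive`, `seed`.
#' @export
tanova <- function(maps1, maps2, design = c("between", "within"),
                   n_permutations = 5000L, seed = 1L) {
  design <- match.arg(design)
  n_permutations <- check_count(n_permutations, "n_permutations")
  maps1 <- as.matrix(maps1); maps2 <- as.matrix(maps2)
  if (design == "within") {
    abort_if(ncol(maps1) != ncol(maps2),
             "within design requires paired subjects (equal columns)")
    ok <- !(colSums(is.na(maps1)) > 0 | colSums(is.na(maps2)) > 0)
    maps1 <- maps1[, ok, drop = FALSE]; maps2 <- maps2[, ok, drop = FALSE]
  } else {
    maps1 <- maps1[, colSums(is.na(maps1)) == 0, drop = FALSE]
    maps2 <- maps2[, colSums(is.na(maps2)) == 0, drop = FALSE]
  }
  n1 <- ncol(maps1); n2 <- ncol(maps2)
  abort_if(n1 < 2L || n2 < 2L, "need at least 2 subjects per cell")
  observed <- gmd(rowMeans(maps1), rowMeans(maps2))

  if (design == "between") {
    pool <- cbind(maps1, maps2)
    n <- n1 + n2
    n_exh <- choose(n, n1)
    if (n_exh <= n_permutations) {
      sel <- utils::combn(n, n1)
      w1 <- matrix(0, n, ncol(sel)); w2 <- matrix(1 / n2, n, ncol(sel))
      for (j in seq_len(ncol(sel))) {
        w1[sel[, j], j] <- 1 / n1
        w2[sel[, j], j] <- 0
      }
      stats <- gmd_cols(pool %*% w1, pool %*% w2)
      p <- mean(stats >= observed - 1e-15)
      return(structure(list(observed_gmd = observed, p = p,
                            n_permutations = ncol(sel), design = design,
                            exhaustive = TRUE, seed = seed),
                       class = "tanova_result"))
    }
    stats <- with_seed(seed, {
      w1 <- matrix(0, n, n_permutations); w2 <- matrix(0, n, n_permutations)
      for (j in seq_len(n_permutations)) {
        sel <- sample.int(n, n1)
        w1[sel, j] <- 1 / n1
        w2[setdiff(seq_len(n), sel), j] <- 1 / n2
      }
      gmd_cols(pool %*% w1, pool %*% w2)
    })
  } else {
    n_exh <- 2^n1
    if (n_exh <= n_permutations) {
      flips <- as.matrix(expand.grid(rep(list(c(0, 1)), n1)))
      m1 <- maps1 %*% t(1 - flips) + maps2 %*% t(flips)
      m2 <- maps2 %*% t(1 - flips) + maps1 %*% t(flips)
      stats <- gmd_cols(m1 / n1, m2 / n1)
      p <- mean(stats >= observed - 1e-15)
      return(structure(list(observed_gmd = observed, p = p,
                            n_permutations = nrow(flips), design = design,
                            exhaustive = TRUE, seed = seed),
                       class = "tanova_result"))
    }
    stats <- with_seed(seed, {
      flips <- matrix(stats::rbinom(n1 * n_permutations, 1L, 0.5),
                      n1, n_permutations)
      m1 <- maps1 %*% (1 - flips) + maps2 %*% flips
      m2 <- maps2 %*% (1 - flips) + maps1 %*% flips
      gmd_cols(m1 / n1, m2 / n1)
    })
  }
  p <- (1 + sum(stats >= observed - 1e-15)) / (1 + n_permutations)
  structure(list(observed_gmd = observed, p = p,
                 n_permutations = n_permutations, design = design,
                 exhaustive = FALSE, seed = seed),
            class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("<tanova> %s design: GMD = %.4f, p = %.4g (%s%d permutations)\n",
              x$design, x$observed_gmd, x$p,
              if (x$exhaustive) "exhaustive, " else "", x$n_permutations))
  invisible(x)
}

#' Relative clinical improvement
#'
#' `(off - on) / off`: the fraction by which the ON-state motor score improved
#' relative to the OFF state (e.g. UPDRS-III with deep-brain stimulation off
#' vs on). Vectorized over subjects.
#'
#' @param off,on scores in the reference (worse) and treated state; `off` must
#'   be non-zero.
#' @return improvement fraction(s).
#' @export
improvement_rate <- function(off, on) {
  abort_if(any(off == 0, na.rm = TRUE), "OFF score of 0: improvement undefined")
  (off - on) / off
}

# t-tests that degrade gracefully on zero-variance input
safe_t <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    if (stats::sd(d) < 1e-12 || length(d) < 2L)
      return(list(statistic = 0, p.value = if (abs(mean(d)) < 1e-12) 1 else 0))
    tt <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12)
      return(list(statistic = 0,
                  p.value = if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0))
    tt <- stats::t.test(x, y)
  }
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

param_value <- function(params, cl, parameter) {
  params[params$class == cl, parameter]
}

#' Compare temporal parameters across groups
#'
#' Per class (including the `"mean"` summary) and per parameter (duration,
#' occurrence, coverage): group means and SDs, an independent two-sided
#' t-test of HC against each patient condition, and a paired two-sided t-test
#' of OFF against ON (subjects matched by `subject_id`).
#'
#' @param params_hc,params_off,params_on row-bound [temporal_parameters()]
#'   tables of the three groups; OFF and ON must contain the same subjects.
#' @param alpha significance threshold recorded in the table (default 0.05).
#' @return data.frame of class `stat_table` with one row per class x
#'   parameter: group means/SDs, the three p-values and significance flags.
#' @export
compare_parameters <- function(params_hc, params_off, params_on, alpha = 0.05) {
  off_ids <- sort(unique(params_off$subject_id))
  on_ids <- sort(unique(params_on$subject_id))
  abort_if(!identical(off_ids, on_ids),
           "paired design: OFF and ON must contain the same subjects")
  classes <- unique(params_hc$class)
  parameters <- c("duration_s", "occurrence_hz", "coverage")
  rows <- list()
  for (parameter in parameters) {
    for (cl in classes) {
      if (parameter == "coverage" && cl == "mean") next  # identically 1
      hc <- param_value(params_hc, cl, parameter)
      off <- params_off[params_off$class == cl, ]
      on <- params_on[params_on$class == cl, ]
      off <- off[order(off$subject_id), parameter]
      on <- on[order(on$subject_id), parameter]
      keep <- stats::complete.cases(off, on)
      hc <- hc[!is.na(hc)]
      t1 <- safe_t(hc, off[!is.na(off)])
      t2 <- safe_t(hc, on[!is.na(on)])
      t3 <- safe_t(off[keep], on[keep], paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parameter, class = cl,
        mean_hc = mean(hc), sd_hc = stats::sd(hc),
        mean_off = mean(off, na.rm = TRUE), sd_off = stats::sd(off[!is.na(off)]),
        mean_on = mean(on, na.rm = TRUE), sd_on = stats::sd(on[!is.na(on)]),
        p_hc_off = t1$p.value, p_hc_on = t2$p.value, p_off_on = t3$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$sig_hc_off <- out$p_hc_off < alpha
  out$sig_hc_on <- out$p_hc_on < alpha
  out$sig_off_on <- out$p_off_on < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("stat_table", "data.frame")
  out
}

#' Clinical correlations with FDR control
#'
#' Pearson correlations between per-subject temporal parameters and clinical
#' scores: OFF-state parameters against UPDRS-III (OFF), ON-state parameters
#' against UPDRS-III (ON), and OFF-state parameters against LEDD. p-values
#' are Benjamini-Hochberg adjusted within each family (one target score x one
#' parameter type, across classes) and flagged at adjusted `p < alpha`.
#'
#' @param params_off,params_on row-bound [temporal_parameters()] tables of the
#'   patient conditions.
#' @param clinical data.frame with columns `subject_id`, `updrs_off`,
#'   `updrs_on`, `ledd` (one row per patient).
#' @param alpha significance threshold on adjusted p (default 0.01).
#' @return data.frame of class `stat_table`: `target`, `parameter`, `class`,
#'   `n`, `r`, `p`, `p_adj`, `significant`.
#' @export
clinical_correlations <- function(params_off, params_on, clinical,
                                  alpha = 0.01) {
  jobs <- list(
    list(target = "updrs_off", params = params_off, score = "updrs_off"),
    list(target = "updrs_on", params = params_on, score = "updrs_on"),
    list(target = "ledd", params = params_off, score = "ledd"))
  parameters <- c("duration_s", "occurrence_hz", "coverage")
  rows <- list()
  for (job in jobs) {
    score <- clinical[[job$score]][match(unique(job$params$subject_id),
                                         clinical$subject_id)]
    ids <- unique(job$params$subject_id)
    for (parameter in parameters) {
      for (cl in unique(job$params$class)) {
        if (parameter == "coverage" && cl == "mean") next
        v <- job$params[job$params$class == cl, ]
        v <- v[match(ids, v$subject_id), parameter]
        ok <- stats::complete.cases(v, score)
        abort_if(sum(ok) >= 3L && stats::sd(score[ok]) < 1e-12,
                 sprintf("correlation with a constant %s vector is undefined", job$score))
        if (sum(ok) < 3L || stats::sd(v[ok]) < 1e-12) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(v[ok], score[ok], method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          target = job$target, parameter = parameter, class = cl, n = sum(ok),
          r = r, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (tg in unique(out$target)) for (parameter in parameters) {
    i <- which(out$target == tg & out$parameter == parameter & !is.na(out$p))
    out$p_adj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("stat_table", "data.frame")
  out
}
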