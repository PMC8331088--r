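test_that("GMD closed forms hold for unit-GFP maps", {
  m <- orthogonal_maps(16, 2)
  expect_equal(gmd(m[, 1], m[, 1]), 0)
  expect_equal(gmd(m[, 1], -m[, 1]), 2)
  expect_equal(gmd(m[, 1], m[, 2]), sqrt(2), tolerance = 1e-10)
  # gmd^2 = 2 - 2r for arbitrary non-constant maps
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(16); b <- rnorm(16)
    r <- spatial_correlation(a, b, polarity_invariant = FALSE)
    expect_equal(gmd(a, b)^2, 2 - 2 * r, tolerance = 1e-10)
  }
})

test_that("small between-design TANOVA is solved by exhaustive enumeration", {
  set.seed(10)
  base <- orthogonal_maps(12, 2)
  g1 <- base[, 1] %o% rep(1, 3) + matrix(rnorm(36, sd = 0.5), 12)
  g2 <- base[, 2] %o% rep(1, 3) + matrix(rnorm(36, sd = 0.5), 12)
  res <- tanova(g1, g2, "between", n_permutations = 5000, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, choose(6, 3))
  want <- oracle_tanova_between(g1, g2)
  expect_equal(res$observed_gmd, want$observed, tolerance = 1e-12)
  expect_equal(res$p, want$p, tolerance = 1e-12)
})

test_that("TANOVA is deterministic given its seed and add-one bounded", {
  set.seed(12)
  g1 <- matrix(rnorm(16 * 12), 16)
  g2 <- matrix(rnorm(16 * 12), 16)
  a <- tanova(g1, g2, "between", n_permutations = 500, seed = 7)
  b <- tanova(g1, g2, "between", n_permutations = 500, seed = 7)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 501)
  expect_lte(a$p, 1)
  # identical paired conditions: observed GMD 0, p = 1
  w <- tanova(g1, g1, "within", n_permutations = 200, seed = 3)
  expect_equal(w$observed_gmd, 0)
  expect_equal(w$p, 1)
})

test_that("null TANOVA p-values are uniform (KS) with nominal type-I error", {
  set.seed(20)
  base <- orthogonal_maps(16, 1)[, 1]
  ps <- vapply(1:200, function(i) {
    g1 <- base %o% rep(1, 8) + matrix(rnorm(16 * 8, sd = 1), 16)
    g2 <- base %o% rep(1, 8) + matrix(rnorm(16 * 8, sd = 1), 16)
    tanova(g1, g2, "between", n_permutations = 300, seed = i)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

make_params <- function(subjects, condition, dur, occ, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(subjects, function(s) {
    lab <- label_sequence(sample(1:4, 500, replace = TRUE), 250,
                          c("A", "B", "C", "D"))
    temporal_parameters(lab, subject_id = s, condition = condition)
  }))
}

test_that("identical groups yield p = 1 in every comparison", {
  p_hc <- make_params(sprintf("HC%02d", 1:6), "HC", seed = 2)
  p_off <- make_params(sprintf("PD%02d", 1:6), "PD_OFF", seed = 2)
  p_on <- p_off
  p_on$condition <- "PD_ON"
  tab <- compare_parameters(p_hc, p_off, p_on)
  # paired OFF vs ON on identical data: t = 0 -> p = 1
  expect_true(all(abs(tab$p_off_on - 1) < 1e-12))
  # HC and OFF were built from the same seed, so they are identical too
  expect_true(all(abs(tab$p_hc_off - 1) < 1e-12))
  expect_s3_class(tab, "stat_table")
  expect_true(all(c("duration_s", "occurrence_hz", "coverage") %in% tab$parameter))
})

test_that("clinical correlations recover a built-in positive dwell link", {
  set.seed(31)
  n <- 18
  ids <- sprintf("PD%02d", 1:n)
  dwell <- rnorm(n, 0.075, 0.01)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = ids[i], condition = "PD_OFF",
               class = c("A", "B", "C", "D", "mean"),
               duration_s = dwell[i] + rnorm(5, 0, 0.001),
               occurrence_hz = 1 / dwell[i] + rnorm(5, 0, 0.2),
               coverage = c(rep(0.25, 4), 1))
  }))
  clin <- data.frame(subject_id = ids,
                     updrs_off = 46.5 + 800 * (dwell - 0.075) + rnorm(n, 0, 2),
                     updrs_on = 17.1 + rnorm(n, 0, 2),
                     ledd = rlnorm(n, log(800), 0.2))
  on <- rows
  on$condition <- "PD_ON"
  tab <- clinical_correlations(rows, on, clin, alpha = 0.01)
  dur_off <- tab[tab$target == "updrs_off" & tab$parameter == "duration_s", ]
  expect_true(all(dur_off$r > 0))
  expect_true(any(dur_off$significant))
  # BH is monotone: adjusted ordering preserves raw ordering
  fam <- tab[tab$target == "updrs_off" & tab$parameter == "occurrence_hz", ]
  expect_identical(order(fam$p), order(fam$p_adj, fam$p))
  ok <- !is.na(tab$p_adj)
  expect_true(all(tab$p_adj[ok] >= tab$p[ok] - 1e-15))
  # constant score vector is an error
  clin2 <- clin
  clin2$updrs_off <- 10
  expect_error(clinical_correlations(rows, on, clin2), "constant")
})

test_that("the clinical improvement rate is (off - on) / off", {
  expect_equal(improvement_rate(46.5, 17.1), (46.5 - 17.1) / 46.5)
  expect_equal(improvement_rate(c(40, 50), c(20, 10)), c(0.5, 0.8))
  expect_error(improvement_rate(0, 1), "undefined")
})
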