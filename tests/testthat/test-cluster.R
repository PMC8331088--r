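test_that("AAHC solves the separable case exactly", {
  truth <- orthogonal_maps(19, 4)
  # +/- copies of the four orthogonal templates, various amplitudes
  idx <- rep(1:4, times = 5)
  signs <- rep(c(1, -1), length.out = 20)
  amps <- seq(0.5, 2, length.out = 20)
  maps <- truth[, idx] * rep(signs * amps, each = 19)
  ts <- aahc(maps, 4)
  assign <- attr(ts, "assignment")
  expect_equal(length(unique(assign)), 4L)
  # partition equals ground truth up to cluster renaming
  expect_equal(length(unique(paste(assign, idx))), 4L)
  r <- apply(abs(cor(ts$maps, truth)), 2, max)
  expect_equal(unname(r), rep(1, 4), tolerance = 1e-9)
  expect_equal(ts$gev, 1, tolerance = 1e-9)
})

test_that("K = n_maps is the degenerate identity clustering", {
  maps <- matrix(rnorm(19 * 6), 19)
  maps <- sweep(maps, 2, colMeans(maps))
  ts <- aahc(maps, 6)
  expect_equal(ts$gev, 1, tolerance = 1e-12)
  expect_equal(length(unique(attr(ts, "assignment"))), 6L)
  expect_error(aahc(maps, 7), "exceeds")
})

test_that("AAHC matches an independent step-by-step oracle", {
  set.seed(99)
  for (trial in 1:12) {
    n <- sample(5:10, 1)
    k <- sample(2:4, 1)
    maps <- matrix(rnorm(12 * n), 12)
    maps <- sweep(maps, 2, colMeans(maps))
    got <- aahc(maps, k)
    want <- oracle_aahc(maps, k)
    # same partition (up to cluster numbering)
    expect_equal(length(unique(paste(attr(got, "assignment"), want$assignment))),
                 length(unique(want$assignment)))
    expect_equal(got$gev, want$gev, tolerance = 1e-9)
    r <- abs(cor(got$maps, want$centroids))
    expect_equal(unname(apply(r, 1, max)), rep(1, k), tolerance = 1e-9)
  }
})

test_that("AAHC GEV is non-increasing as K decreases", {
  set.seed(7)
  maps <- matrix(rnorm(16 * 30), 16)
  maps <- sweep(maps, 2, colMeans(maps))
  gevs <- vapply(c(8, 6, 4, 3, 2), function(k) aahc(maps, k)$gev, 0)
  expect_true(all(diff(gevs) <= 1e-12))
})

test_that("clustering is invariant to global sign flips and rescaling", {
  set.seed(11)
  maps <- matrix(rnorm(16 * 25), 16)
  maps <- sweep(maps, 2, colMeans(maps))
  a <- aahc(maps, 3)
  b <- aahc(-2.5 * maps, 3)
  expect_identical(attr(a, "assignment"), attr(b, "assignment"))
  expect_equal(a$gev, b$gev, tolerance = 1e-12)
  expect_equal(abs(diag(cor(a$maps, b$maps))), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two-level clustering with one subject reduces to its templates", {
  set.seed(5)
  maps <- matrix(rnorm(16 * 40), 16)
  maps <- sweep(maps, 2, colMeans(maps))
  grp <- two_level_cluster(list(maps), 4)
  ind <- attr(grp, "individual")[[1]]
  r <- abs(cor(grp$maps, ind$maps))
  expect_equal(unname(apply(r, 1, max)), rep(1, 4), tolerance = 1e-9)
  expect_identical(grp$level, "group")
})

test_that("canonical labeling recovers a known permutation", {
  mont <- fix_montage(19)
  canon <- canonical_templates(mont)
  ident <- label_templates(canon, canon)
  expect_identical(attr(ident, "permutation"), 1:4)
  expect_equal(attr(ident, "total_similarity"), 4, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  shuffled <- template_set(canon$maps[, perm], c("A", "B", "C", "D"),
                           level = "group")
  relab <- label_templates(shuffled, canon)
  # column j of the relabeled set must be canonical class j again
  expect_equal(abs(diag(cor(relab$maps, canon$maps))), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  # determinism on arbitrary maps
  set.seed(3)
  rnd <- matrix(rnorm(19 * 4), 19)
  rnd <- sweep(rnd, 2, colMeans(rnd))
  ts <- template_set(rnd)
  expect_identical(attr(label_templates(ts, canon), "permutation"),
                   attr(label_templates(ts, canon), "permutation"))
})
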