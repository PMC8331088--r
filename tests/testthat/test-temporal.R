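test_that("run segmentation encodes maximal runs and respects epochs", {
  lab <- labels_from_chars(c("A", "A", "A", "B", "B", "A"))
  runs <- segment_runs(lab)
  expect_equal(runs$class, c("A", "B", "A"))
  expect_equal(runs$start, c(1L, 4L, 6L))
  expect_equal(runs$length, c(3L, 2L, 1L))
  # runs never span epoch boundaries
  lab2 <- labels_from_chars(rep("A", 6), epoch = rep(1:2, each = 3))
  expect_equal(nrow(segment_runs(lab2)), 2L)
  # unassigned samples break runs and are excluded
  lab3 <- label_sequence(c(1L, 1L, NA, 1L), 100, "A")
  expect_equal(segment_runs(lab3)$length, c(2L, 1L))
  empty <- label_sequence(integer(0), 100, "A")
  expect_equal(nrow(segment_runs(empty)), 0L)
})

test_that("duration, occurrence and coverage follow their definitions", {
  lab <- labels_from_chars(rep(c("A", "B"), each = 50), fs = 100)
  tp <- temporal_parameters(lab)
  a <- tp[tp$class == "A", ]
  b <- tp[tp$class == "B", ]
  expect_equal(a$duration_s, 0.5)
  expect_equal(b$duration_s, 0.5)
  expect_equal(a$occurrence_hz, 1)
  expect_equal(b$occurrence_hz, 1)
  expect_equal(a$coverage, 0.5)
  expect_equal(b$coverage, 0.5)
  # absent classes: missing duration, zero rates
  cd <- tp[tp$class %in% c("C", "D"), ]
  expect_true(all(is.na(cd$duration_s)))
  expect_true(all(cd$occurrence_hz == 0 & cd$coverage == 0))
})

test_that("coverage identities hold on random sequences", {
  set.seed(2)
  for (i in 1:10) {
    lab <- label_sequence(sample(1:4, 600, replace = TRUE), 250,
                          c("A", "B", "C", "D"),
                          epoch = rep(1:3, each = 200))
    tp <- temporal_parameters(lab)
    cls <- tp[tp$class != "mean", ]
    expect_equal(sum(cls$coverage), 1, tolerance = 1e-12)
    expect_equal(cls$coverage - cls$duration_s * cls$occurrence_hz,
                 rep(0, 4), tolerance = 1e-9)
    tr <- temporal_parameters(lab, mode = "trim_edges")
    expect_equal(sum(tr$coverage[tr$class != "mean"]), 1, tolerance = 1e-12)
  }
})

test_that("parameters are invariant to the sampling rate given label structure", {
  lab1 <- label_sequence(rep(c(1L, 2L, 1L, 3L), times = c(10, 7, 5, 8)), 100,
                         c("A", "B", "C"))
  lab2 <- label_sequence(rep(lab1$labels, each = 2), 200, c("A", "B", "C"))
  t1 <- temporal_parameters(lab1)
  t2 <- temporal_parameters(lab2)
  expect_equal(t1$duration_s, t2$duration_s, tolerance = 1e-9)
  expect_equal(t1$occurrence_hz, t2$occurrence_hz, tolerance = 1e-9)
  expect_equal(t1$coverage, t2$coverage, tolerance = 1e-9)
})

test_that("epoch order does not change the parameters", {
  set.seed(9)
  blocks <- replicate(4, sample(1:4, 100, replace = TRUE), simplify = FALSE)
  mk <- function(ord) label_sequence(unlist(blocks[ord]), 250,
                                     c("A", "B", "C", "D"),
                                     epoch = rep(seq_along(ord), each = 100))
  t1 <- temporal_parameters(mk(1:4))
  t2 <- temporal_parameters(mk(c(3, 1, 4, 2)))
  expect_equal(t1$duration_s, t2$duration_s)
  expect_equal(t1$occurrence_hz, t2$occurrence_hz)
  expect_equal(t1$coverage, t2$coverage)
})

test_that("trim_edges drops boundary-truncated runs from duration/occurrence", {
  # epoch: 5 A | 10 B | 5 A  -> interior run is the single B run
  lab <- labels_from_chars(rep(c("A", "B", "A"), times = c(5, 10, 5)), fs = 100)
  tr <- temporal_parameters(lab, mode = "trim_edges")
  expect_equal(tr$duration_s[tr$class == "B"], 0.10)
  expect_true(is.na(tr$duration_s[tr$class == "A"]))   # only edge runs
  expect_equal(tr$occurrence_hz[tr$class == "A"], 0)
  # coverage still counts everything
  expect_equal(tr$coverage[tr$class == "A"], 0.5)
  inc <- temporal_parameters(lab)
  expect_equal(inc$duration_s[inc$class == "A"], 0.05)
})
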