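make_rec <- function(data, fs = 100, n = nrow(data)) {
  eeg_recording(data, fs, generate_montage(n, 1), "S", "HC")
}

test_that("epoching gives floor(samples / epoch_samples) epochs", {
  rec <- make_rec(matrix(rnorm(8 * 300 * 100), 8), fs = 100)
  expect_equal(dim(epoch_recording(rec, 2)$data)[3], 150L)
  rec301 <- make_rec(matrix(rnorm(8 * 301 * 100), 8), fs = 100)
  expect_equal(dim(epoch_recording(rec301, 2)$data)[3], 150L)
  tiny <- make_rec(matrix(rnorm(8 * 30), 8), fs = 100)   # 0.3 s
  expect_equal(dim(epoch_recording(tiny, 2)$data)[3], 0L)
  expect_error(epoch_recording(rec, 1.0001), "integer number of samples")
})

test_that("concatenating epochs reproduces the leading samples exactly", {
  dat <- matrix(rnorm(8 * 450), 8)
  rec <- make_rec(dat, fs = 100)
  ep <- epoch_recording(rec, 1)
  expect_identical(unname(concatenate_epochs(ep)), dat[, 1:400])
})

test_that("the band-pass has the specified frequency response", {
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)[-1]
  slow <- matrix(rep(sin(2 * pi * 0.1 * t), each = 8), 8, byrow = FALSE) *
    (1 + 0.1 * seq_len(8))               # distinct per channel
  rec <- make_rec(slow, fs = fs)
  out <- bandpass(rec, 1, 40)
  expect_lt(mean(out$data^2) / mean(slow^2), 0.01)

  alpha <- matrix(rep(sin(2 * pi * 10 * t), each = 8), 8) * (1 + 0.1 * seq_len(8))
  rec10 <- make_rec(alpha, fs = fs)
  out10 <- bandpass(rec10, 2, 20)
  expect_equal(mean(out10$data^2) / mean(alpha^2), 1, tolerance = 0.05)

  const <- make_rec(matrix(5, 8, 1000), fs = fs)
  expect_lt(max(abs(bandpass(const, 1, 40)$data)), 1e-6)
  expect_error(bandpass(rec, 30, 10), "invalid band")
  expect_error(bandpass(rec, 1, 200), "invalid band")
})

test_that("filtering is linear and preserves length", {
  fs <- 100
  x <- make_rec(matrix(rnorm(8 * 500), 8), fs)
  y <- make_rec(matrix(rnorm(8 * 500), 8), fs)
  combo <- make_rec(2 * x$data + 3 * y$data, fs)
  lhs <- bandpass(combo, 1, 40)$data
  rhs <- 2 * bandpass(x, 1, 40)$data + 3 * bandpass(y, 1, 40)$data
  expect_equal(lhs, rhs, tolerance = 1e-8)
  expect_equal(ncol(lhs), 500L)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  expect_equal(average_reference(matrix(c(1, 3), 2)), matrix(c(-1, 1), 2))
  rec <- make_rec(matrix(rnorm(8 * 200), 8))
  ref <- average_reference(rec)
  expect_equal(colMeans(ref$data), rep(0, 200), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(average_reference(ref)$data, ref$data, tolerance = 1e-12)
  shifted <- rec
  shifted$data <- rec$data + matrix(rnorm(200), 8, 200, byrow = TRUE)
  expect_equal(average_reference(shifted)$data, ref$data, tolerance = 1e-10)
})

test_that("average reference commutes with the band-pass", {
  rec <- make_rec(matrix(rnorm(8 * 500), 8), fs = 100)
  a <- average_reference(bandpass(rec, 1, 40))$data
  b <- bandpass(average_reference(rec), 1, 40)$data
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("amplitude rejection drops exactly the contaminated epochs", {
  dat <- matrix(rnorm(8 * 1000, sd = 10), 8)       # quiet, ~10 uV
  dat[3, 550] <- 500                               # spike in epoch 2 (of 1-s epochs? no: see below)
  rec <- make_rec(dat, fs = 500)                   # 2 epochs of 1 s... keep simple
  ep <- epoch_recording(rec, 1)                    # 2 epochs, spike in epoch 2
  kept <- reject_epochs(ep, 100)$kept_mask
  expect_identical(kept, c(TRUE, FALSE))
  expect_identical(reject_epochs(ep, 1000)$kept_mask, c(TRUE, TRUE))
  # threshold below the signal floor: everything dropped, downstream refuses
  none <- reject_epochs(ep, 1e-3)
  expect_identical(none$kept_mask, c(FALSE, FALSE))
  expect_equal(ncol(gfp_peak_maps(none)), 0L)
  expect_error(aahc(gfp_peak_maps(none), 4), "exceeds")
})

test_that("bad-channel interpolation averages near neighbours", {
  # hand-built montage: channel 3 exactly between channels 1 and 2
  pos <- rbind(c(0.1, 0, 1), c(-0.1, 0, 1), c(0, 0, 1),
               c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0.5, 0.5, 0.5) / sqrt(0.75))
  mont <- montage(paste0("c", 1:8), pos)
  dat <- matrix(rnorm(8 * 100), 8)
  dat[1, ] <- dat[2, ] <- sin(seq_len(100) / 5)
  rec <- eeg_recording(dat, 100, mont)
  fixed <- interpolate_bad_channels(rec, "c3", k = 2)
  expect_equal(unname(fixed$data[3, ]), unname(dat[1, ]), tolerance = 1e-9)
  expect_equal(fixed$data[-3, ], rec$data[-3, ])
  expect_identical(interpolate_bad_channels(rec, character(0)), rec)
  expect_error(interpolate_bad_channels(rec, paste0("c", 1:8)), "no good channels")
  expect_error(interpolate_bad_channels(rec, "nope"), "absent")
})

test_that("more neighbours reconstruct smooth topographies better than one", {
  mont <- generate_montage(32, 1)
  pos <- as.matrix(as.data.frame(mont)[, c("x", "y", "z")])
  smooth <- pos[, 1] + 0.5 * pos[, 2] - 0.3 * pos[, 3]   # smooth gradient map
  dat <- matrix(rep(smooth, 50), 32)
  rec <- eeg_recording(dat, 100, mont)
  bad <- mont$name[5]
  err_k4 <- max(abs(interpolate_bad_channels(rec, bad, k = 4)$data[5, ] - dat[5, ]))
  err_k1 <- max(abs(interpolate_bad_channels(rec, bad, k = 1)$data[5, ] - dat[5, ]))
  expect_lt(err_k4, err_k1)
})
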