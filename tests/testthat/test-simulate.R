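test_that("sim_spec validates its invariants", {
  expect_error(sim_spec(fs = 30, carrier_freq = 10), "4 \\* carrier_freq")
  expect_error(sim_spec(noise_spatial_corr = 1.5), "noise_spatial_corr")
  expect_error(sim_spec(K = 1), "K")
  expect_error(sim_spec(mean_dwell = list(HC = -0.1, PD_OFF = 0.075, PD_ON = 0.076)),
               "mean_dwell")
  tm <- matrix(1 / 3, 4, 4); diag(tm) <- 0
  tm[1, 2] <- 0.5  # rows no longer sum to 1
  expect_error(sim_spec(transition_matrix = tm), "transition_matrix")
})

test_that("state sequences are semi-Markov with no self-transitions", {
  spec <- fix_spec()
  lab <- generate_state_sequence(spec, "HC", seed = 11)
  expect_length(lab$labels, spec$record_length * spec$fs)
  runs <- rle(lab$labels)
  expect_true(all(diff(runs$values) != 0))
  expect_identical(generate_state_sequence(spec, "HC", seed = 11)$labels,
                   lab$labels)
})

test_that("empirical mean dwell tracks its target over many seeds", {
  spec <- sim_spec(n_channels = 16, fs = 250, record_length = 300,
                   mean_dwell = list(HC = 0.068, PD_OFF = 0.075, PD_ON = 0.076))
  hits <- vapply(1:100, function(s) {
    lab <- generate_state_sequence(spec, "PD_OFF", seed = s)
    d <- mean(rle(lab$labels)$lengths) / spec$fs
    d >= 0.070 && d <= 0.080
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("class coverage is near-uniform for a symmetric spec", {
  spec <- sim_spec(n_channels = 16, fs = 250, record_length = 300)
  covs <- sapply(1:20, function(s) {
    lab <- generate_state_sequence(spec, "HC", seed = 1000 + s)
    tabulate(lab$labels, 4) / length(lab$labels)
  })
  expect_true(all(abs(covs - 0.25) <= 0.05))
})

test_that("noise-free synthesis reproduces the template at every GFP peak", {
  mont <- fix_montage(16)
  ts <- generate_templates(4, mont, seed = 3)
  spec <- fix_spec(snr_db = Inf)
  lab <- generate_state_sequence(spec, "HC", seed = 2)
  rec <- synthesize_eeg(ts, lab, spec, seed = 4, mont)
  pk <- find_gfp_peaks(gfp(rec$data), spec$fs)
  r <- vapply(pk, function(p)
    abs(cor(rec$data[, p], ts$maps[, lab$labels[p]])), 0)
  expect_equal(r, rep(1, length(pk)), tolerance = 1e-6)
  expect_equal(colMeans(rec$data), rep(0, ncol(rec$data)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the realized signal-to-noise ratio matches the request", {
  mont <- fix_montage(16)
  ts <- generate_templates(4, mont, seed = 3)
  spec_inf <- fix_spec(snr_db = Inf)
  lab <- generate_state_sequence(spec_inf, "HC", seed = 2)
  clean <- synthesize_eeg(ts, lab, spec_inf, seed = 4, mont)$data
  noise_power <- function(snr_db) {
    spec <- fix_spec(snr_db = snr_db)
    noisy <- synthesize_eeg(ts, lab, spec, seed = 4, mont)$data
    mean((noisy - clean)^2)
  }
  p10 <- noise_power(10)
  expect_equal(10 * log10(mean(clean^2) / p10), 10, tolerance = 0.05)
  # doubling the noise scale (-6.02 dB) quadruples the noise power
  expect_equal(noise_power(10 - 20 * log10(2)) / p10, 4, tolerance = 0.02)
})

test_that("cohorts are deterministic and ordered HC < PD_OFF in true dwell", {
  spec <- fix_spec(n_subjects_per_group = 6L, record_length = 60)
  c1 <- generate_cohort(spec, synthesize = FALSE)
  c2 <- generate_cohort(spec, synthesize = FALSE)
  expect_identical(c1$ground_truth$clinical, c2$ground_truth$clinical)
  dwell <- vapply(c1$ground_truth$label_sequences,
                  function(l) mean(rle(l$labels)$lengths) / l$fs, 0)
  grp <- ifelse(grepl("^HC", names(dwell)), "HC",
                ifelse(grepl("_OFF$", names(dwell)), "PD_OFF", "PD_ON"))
  expect_lt(mean(dwell[grp == "HC"]), mean(dwell[grp == "PD_OFF"]))
  # patients carry both scores, controls none
  clin <- c1$ground_truth$clinical
  expect_true(all(is.na(clin$updrs_off[clin$group == "HC"])))
  expect_true(all(!is.na(clin$updrs_off[clin$group == "PD"])))
})

test_that("a zero clinical slope leaves dwell and UPDRS uncorrelated", {
  rs <- vapply(1:20, function(s) {
    spec <- sim_spec(n_subjects_per_group = 8L, n_channels = 16, fs = 250,
                     record_length = 30,
                     clinical_model = list(slope = 0, noise_sd = 4,
                                           mean_updrs = c(PD_OFF = 46.5, PD_ON = 17.1)),
                     seed = 2000 + s)
    ch <- generate_cohort(spec, synthesize = FALSE)
    ids <- ch$ground_truth$clinical$subject_id[ch$ground_truth$clinical$group == "PD"]
    dwell <- vapply(paste0(ids, "_OFF"), function(id) {
      l <- ch$ground_truth$label_sequences[[id]]
      mean(rle(l$labels)$lengths) / l$fs
    }, 0)
    cor(dwell, ch$ground_truth$clinical$updrs_off[match(ids, ch$ground_truth$clinical$subject_id)])
  }, 0)
  expect_lt(abs(mean(rs)), 0.3)
})
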