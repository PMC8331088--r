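# Synthetic EEG cohort simulation -------------------------------------------

#' Specification of a synthetic microstate cohort
#'
#' Bundles every parameter of the simulator. Defaults emulate a three-group
#' resting-state study (healthy controls and a patient group recorded with
#' deep-brain stimulation OFF and ON): 20 subjects per group, 300 s of EEG at
#' 250 Hz, four shared template maps, and group mean dwell times of 0.068 s
#' (HC), 0.075 s (PD_OFF) and 0.076 s (PD_ON). Motor scores (UPDRS-III) are an
#' affine function of each subject's realized mean dwell plus Gaussian noise,
#' centred on 46.5 (OFF) and 17.1 (ON).
#'
#' @param n_subjects_per_group subjects per group (HC subjects, and patients
#'   who are recorded in both the OFF and ON condition).
#' @param groups condition names; the first is the control group, the
#'   remaining two the paired patient conditions.
#' @param n_channels electrodes (>= 8).
#' @param fs sampling rate, Hz; must be at least `4 * carrier_freq`.
#' @param record_length seconds of EEG per recording.
#' @param K number of template maps.
#' @param mean_dwell named list (one entry per group) of mean dwell times in
#'   seconds; each entry is a scalar (all classes) or a length-K vector.
#' @param dwell_distribution `"gamma"` or `"lognormal"`.
#' @param dwell_shape gamma shape, or lognormal `sdlog`. The gamma default
#'   (shape 2) gives unimodal dwell times without ultrashort runs.
#' @param carrier_freq alpha-band carrier frequency in Hz (default 10); the
#'   microstate amplitude envelope is a rectified sinusoid at this frequency,
#'   mimicking eyes-closed alpha and placing GFP maxima at predictable
#'   instants.
#' @param snr_db signal-to-noise ratio of the average-referenced signal, in
#'   dB; `Inf` disables noise.
#' @param noise_spatial_corr uniform between-channel correlation of the
#'   sensor noise, in `[0, 1]`.
#' @param amplitude_jitter relative SD of the per-half-cycle amplitude jitter.
#' @param base_amplitude_uv peak signal amplitude scale in microvolts.
#' @param subject_dwell_sd between-subject SD of the subject-level mean dwell
#'   offset (seconds); the same offset applies to a patient's OFF and ON
#'   recordings, which makes the design genuinely paired.
#' @param clinical_model list with `slope` (UPDRS-III points per second of
#'   dwell), `noise_sd`, and `mean_updrs` (named vector of group-mean scores
#'   for the patient conditions).
#' @param ledd_meanlog,ledd_sdlog lognormal parameters of the simulated
#'   levodopa-equivalent daily dose (independent of the dynamics).
#' @param transition_matrix optional K x K successor-probability matrix (zero
#'   diagonal, rows summing to 1); `NULL` means uniform over the other K - 1
#'   classes.
#' @param seed master seed; every simulator output is a pure function of
#'   (spec, seed).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects_per_group = 20L,
                     groups = c("HC", "PD_OFF", "PD_ON"),
                     n_channels = 19L,
                     fs = 250,
                     record_length = 300,
                     K = 4L,
                     mean_dwell = list(HC = 0.068, PD_OFF = 0.075, PD_ON = 0.076),
                     dwell_distribution = c("gamma", "lognormal"),
                     dwell_shape = 2,
                     carrier_freq = 10,
                     snr_db = 10,
                     noise_spatial_corr = 0.3,
                     amplitude_jitter = 0.2,
                     base_amplitude_uv = 15,
                     subject_dwell_sd = 0.010,
                     clinical_model = list(slope = 800, noise_sd = 4,
                                           mean_updrs = c(PD_OFF = 46.5, PD_ON = 17.1)),
                     ledd_meanlog = log(800), ledd_sdlog = 0.25,
                     transition_matrix = NULL,
                     seed = 1L) {
  dwell_distribution <- match.arg(dwell_distribution)
  n_subjects_per_group <- check_count(n_subjects_per_group, "n_subjects_per_group")
  n_channels <- check_count(n_channels, "n_channels", lower = 8L)
  K <- check_count(K, "K", lower = 2L)
  check_scalar_number(fs, "fs", lower = 1e-12)
  check_scalar_number(carrier_freq, "carrier_freq", lower = 1e-12)
  abort_if(fs < 4 * carrier_freq, "fs must be at least 4 * carrier_freq")
  check_scalar_number(record_length, "record_length", lower = 1e-12)
  check_scalar_number(noise_spatial_corr, "noise_spatial_corr", 0, 1)
  check_scalar_number(dwell_shape, "dwell_shape", lower = 1e-12)
  abort_if(!is.list(mean_dwell) || !setequal(names(mean_dwell), groups),
           "`mean_dwell` must be a named list with one entry per group")
  for (g in groups) {
    d <- mean_dwell[[g]]
    abort_if(!is.numeric(d) || !length(d) %in% c(1L, K) || any(d <= 0),
             sprintf("mean_dwell$%s must be positive, length 1 or K", g))
  }
  if (!is.null(transition_matrix)) {
    tm <- as.matrix(transition_matrix)
    abort_if(nrow(tm) != K || ncol(tm) != K || any(diag(tm) != 0) ||
               any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9),
             "transition_matrix must be K x K, zero diagonal, rows summing to 1")
  }
  structure(list(n_subjects_per_group = n_subjects_per_group, groups = groups,
                 n_channels = n_channels, fs = fs,
                 record_length = record_length, K = K,
                 mean_dwell = mean_dwell,
                 dwell_distribution = dwell_distribution,
                 dwell_shape = dwell_shape, carrier_freq = carrier_freq,
                 snr_db = snr_db, noise_spatial_corr = noise_spatial_corr,
                 amplitude_jitter = amplitude_jitter,
                 base_amplitude_uv = base_amplitude_uv,
                 subject_dwell_sd = subject_dwell_sd,
                 clinical_model = clinical_model,
                 ledd_meanlog = ledd_meanlog, ledd_sdlog = ledd_sdlog,
                 transition_matrix = transition_matrix, seed = seed),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d subjects/group x %s; %d ch, %g Hz, %g s, K=%d, snr=%g dB\n",
              x$n_subjects_per_group, paste(x$groups, collapse = "/"),
              x$n_channels, x$fs, x$record_length, x$K, x$snr_db))
  invisible(x)
}

group_dwell <- function(spec, group) {
  d <- spec$mean_dwell[[group]]
  if (length(d) == 1L) rep(d, spec$K) else d
}

draw_dwell <- function(n, mean_s, distribution, shape) {
  if (distribution == "gamma") {
    stats::rgamma(n, shape = shape, scale = mean_s / shape)
  } else {
    meanlog <- log(mean_s) - shape^2 / 2
    stats::rlnorm(n, meanlog = meanlog, sdlog = shape)
  }
}

#' Simulate a semi-Markov microstate state sequence
#'
#' States dwell for i.i.d. random durations (gamma or lognormal with the
#' spec's per-class mean), then switch abruptly; the successor class is drawn
#' uniformly among the other K - 1 classes unless the spec carries an explicit
#' transition matrix. The sequence is truncated to `record_length * fs`
#' samples. Consecutive runs never share a class.
#'
#' @param spec a [sim_spec()].
#' @param subject_group which group's dwell targets to use.
#' @param seed integer seed.
#' @param mean_dwell optional length-K override of the group dwell targets
#'   (used for subject-level heterogeneity).
#' @return a ground-truth [label_sequence()].
#' @export
generate_state_sequence <- function(spec, subject_group, seed = 1L,
                                    mean_dwell = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  abort_if(!subject_group %in% spec$groups, "unknown subject group")
  dwell <- if (is.null(mean_dwell)) group_dwell(spec, subject_group)
           else rep_len(mean_dwell, spec$K)
  abort_if(any(dwell <= 0), "mean dwell times must be positive")
  n_total <- as.integer(round(spec$record_length * spec$fs))
  K <- spec$K
  with_seed(seed, {
    labels <- integer(n_total)
    filled <- 0L
    state <- sample.int(K, 1L)
    while (filled < n_total) {
      d <- draw_dwell(1L, dwell[state], spec$dwell_distribution, spec$dwell_shape)
      len <- max(1L, as.integer(round(d * spec$fs)))
      len <- min(len, n_total - filled)
      labels[(filled + 1L):(filled + len)] <- state
      filled <- filled + len
      state <- next_state(state, K, spec$transition_matrix)
    }
    label_sequence(labels, spec$fs, default_class_labels(K))
  })
}

next_state <- function(state, K, transition_matrix) {
  if (is.null(transition_matrix)) {
    others <- seq_len(K)[-state]
    others[sample.int(K - 1L, 1L)]
  } else {
    sample.int(K, 1L, prob = transition_matrix[state, ])
  }
}

#' Synthesize an EEG recording from templates and a state sequence
#'
#' The clean signal at sample t is `template[label(t)] * a(t)`, where `a(t)`
#' is a rectified sinusoid at the carrier frequency whose amplitude is
#' jittered once per half-cycle (lognormal, relative SD
#' `amplitude_jitter`). Gaussian sensor noise with uniform between-channel
#' correlation `noise_spatial_corr` is scaled so that the average-referenced
#' signal-to-noise power ratio equals `snr_db`; `snr_db = Inf` disables noise.
#' The output is average-referenced.
#'
#' @param templates a [template_set()] with K maps.
#' @param labels a ground-truth [label_sequence()] over the same K classes.
#' @param spec a [sim_spec()] (carrier, jitter, snr, noise correlation,
#'   amplitude scale).
#' @param seed integer seed.
#' @param montage the [montage()] the templates live on.
#' @param subject_id,condition labels for the resulting recording.
#' @return an [eeg_recording()].
#' @export
synthesize_eeg <- function(templates, labels, spec, seed = 1L, montage,
                           subject_id = NA_character_,
                           condition = NA_character_) {
  stopifnot(inherits(templates, "template_set"),
            inherits(labels, "label_sequence"),
            inherits(spec, "sim_spec"))
  abort_if(length(templates$class_labels) != length(labels$classes),
           "template and label class sets do not match")
  n <- length(labels$labels)
  nc <- nrow(templates$maps)
  t_sec <- (seq_len(n) - 1L) / labels$fs
  with_seed(seed, {
    phase <- 2 * pi * spec$carrier_freq * t_sec
    half_cycle <- floor(phase / pi) + 1L
    jit <- exp(stats::rnorm(max(half_cycle), 0, spec$amplitude_jitter))
    a <- abs(sin(phase)) * jit[half_cycle] * spec$base_amplitude_uv
    sig <- templates$maps[, labels$labels, drop = FALSE] *
      matrix(a, nc, n, byrow = TRUE)
    sig <- average_reference.default(sig)
    if (is.finite(spec$snr_db)) {
      rho <- spec$noise_spatial_corr
      noise <- sqrt(1 - rho) * matrix(stats::rnorm(nc * n), nc, n) +
        sqrt(rho) * matrix(stats::rnorm(n), nc, n, byrow = TRUE)
      noise <- average_reference.default(noise)
      p_sig <- mean(sig^2)
      p_noise <- mean(noise^2)
      target <- p_sig / 10^(spec$snr_db / 10)
      if (p_noise > 0) noise <- noise * sqrt(target / p_noise)
      sig <- sig + noise
    }
    eeg_recording(sig, labels$fs, montage, subject_id, condition)
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws a shared montage and template set, then per-subject ground-truth
#' state sequences and EEG recordings for every group. Patients (`PD_OFF` /
#' `PD_ON`) are the same subjects recorded twice, sharing a subject-level
#' dwell offset, so paired designs are meaningful. A clinical table with
#' UPDRS-III OFF/ON scores (affine in the subject's realized mean dwell, plus
#' noise) and LEDD is generated alongside.
#'
#' @param spec a [sim_spec()].
#' @param out_dir optional directory; when given, recordings
#'   (`<id>.csv` + JSON sidecar, or EDF), the montage (`montage.txt`) and the
#'   clinical table (`clinical.csv`) are written there.
#' @param format on-disk recording format, `"csv"` or `"edf"`.
#' @param synthesize set `FALSE` to skip EEG synthesis and return ground truth
#'   only (label sequences, clinical table); the clinical table is identical
#'   either way because each random draw has its own derived seed. Useful for
#'   statistical power studies of the label-level machinery.
#' @return a list with `recordings` (named list of [eeg_recording()]; empty
#'   when `synthesize = FALSE`), `ground_truth` (list: `templates`,
#'   `label_sequences`, `clinical`, `montage`, `subject_table`).
#' @export
generate_cohort <- function(spec, out_dir = NULL, format = c("csv", "edf"),
                            synthesize = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  format <- match.arg(format)
  mont <- generate_montage(spec$n_channels, seed = child_seed(spec$seed, 0))
  templates <- generate_templates(spec$K, mont, seed = child_seed(spec$seed, 1))
  n <- spec$n_subjects_per_group
  control <- spec$groups[1L]
  patient_groups <- spec$groups[-1L]

  subjects <- data.frame(
    subject_id = c(sprintf("HC%02d", seq_len(n)), sprintf("PD%02d", seq_len(n))),
    group = rep(c("HC", "PD"), each = n), stringsAsFactors = FALSE)
  recs <- list(); seqs <- list()
  rows <- list()
  stream <- 10L
  for (i in seq_len(n)) {   # controls
    sid <- sprintf("HC%02d", i)
    offset <- with_seed(child_seed(spec$seed, stream), stats::rnorm(1, 0, spec$subject_dwell_sd))
    dw <- pmax(group_dwell(spec, control) + offset, 0.02)
    lab <- generate_state_sequence(spec, control, child_seed(spec$seed, stream + 1L), dw)
    id <- sid
    if (synthesize)
      recs[[id]] <- synthesize_eeg(templates, lab, spec,
                                   child_seed(spec$seed, stream + 2L),
                                   mont, sid, control)
    seqs[[id]] <- lab
    rows[[sid]] <- data.frame(subject_id = sid, group = "HC",
                              updrs_off = NA_real_, updrs_on = NA_real_,
                              ledd = NA_real_, stringsAsFactors = FALSE)
    stream <- stream + 5L
  }
  for (i in seq_len(n)) {   # patients, one recording per condition
    sid <- sprintf("PD%02d", i)
    offset <- with_seed(child_seed(spec$seed, stream), stats::rnorm(1, 0, spec$subject_dwell_sd))
    updrs <- c(PD_OFF = NA_real_, PD_ON = NA_real_)
    sub_stream <- stream + 1L
    realized <- numeric(0)
    for (g in patient_groups) {
      dw <- pmax(group_dwell(spec, g) + offset, 0.02)
      lab <- generate_state_sequence(spec, g, child_seed(spec$seed, sub_stream), dw)
      id <- paste0(sid, "_", sub("^PD_", "", g))
      if (synthesize)
        recs[[id]] <- synthesize_eeg(templates, lab, spec,
                                     child_seed(spec$seed, sub_stream + 1L),
                                     mont, sid, g)
      seqs[[id]] <- lab
      realized[g] <- mean_true_dwell(lab)
      sub_stream <- sub_stream + 2L
    }
    cm <- spec$clinical_model
    for (g in patient_groups) {
      mu <- cm$mean_updrs[[g]]
      if (!is.null(mu) && !is.na(mu)) {
        e <- with_seed(child_seed(spec$seed, sub_stream), stats::rnorm(1, 0, cm$noise_sd))
        updrs[g] <- mu + cm$slope * (realized[[g]] - mean(group_dwell(spec, g))) + e
        sub_stream <- sub_stream + 1L
      }
    }
    ledd <- with_seed(child_seed(spec$seed, sub_stream),
                      stats::rlnorm(1, spec$ledd_meanlog, spec$ledd_sdlog))
    rows[[sid]] <- data.frame(subject_id = sid, group = "PD",
                              updrs_off = unname(updrs["PD_OFF"]),
                              updrs_on = unname(updrs["PD_ON"]),
                              ledd = ledd, stringsAsFactors = FALSE)
    stream <- stream + 20L
  }
  clinical <- do.call(rbind, rows)
  rownames(clinical) <- NULL
  out <- list(recordings = recs,
              ground_truth = list(templates = templates,
                                  label_sequences = seqs,
                                  clinical = clinical,
                                  montage = mont,
                                  subject_table = subjects))
  if (!is.null(out_dir)) write_cohort(out, out_dir, format)
  out
}

# subject-level mean dwell (seconds) of a ground-truth label sequence
mean_true_dwell <- function(lab) {
  runs <- rle(lab$labels)
  mean(runs$lengths) / lab$fs
}

write_cohort <- function(cohort, out_dir, format = "csv") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- dir.exists(out_dir)
  abort_if(!ok, sprintf("could not create cohort directory: %s", out_dir))
  write_montage(cohort$ground_truth$montage, file.path(out_dir, "montage.txt"))
  utils::write.csv(cohort$ground_truth$clinical,
                   file.path(out_dir, "clinical.csv"), row.names = FALSE)
  for (id in names(cohort$recordings)) {
    path <- file.path(out_dir, paste0(id, ".", format))
    write_recording(cohort$recordings[[id]], path)
  }
  invisible(out_dir)
}
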