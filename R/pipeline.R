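# End-to-end pipeline ---------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every setting of the simulate -> preprocess -> cluster -> backfit
#' -> parameters -> statistics pipeline. Defaults follow standard
#' resting-state microstate practice: 2-s epochs, a 1-40 Hz cleaning band, a
#' 2-20 Hz clustering band, four microstate classes, 100 uV artifact
#' threshold, 5000 permutations, significance at 0.05 (temporal parameters,
#' TANOVA) and 0.01 (FDR-adjusted clinical correlations).
#'
#' @param sim a [sim_spec()] to simulate the cohort, or `NULL` to read
#'   recordings from `input_dir`.
#' @param input_dir directory with `montage.txt`, `clinical.csv` and
#'   per-recording files named `HCnn.*`, `PDnn_OFF.*`, `PDnn_ON.*` (csv/edf).
#'   Ignored when `sim` is given.
#' @param epoch_length epoch length, seconds.
#' @param clean_band,cluster_band band-pass edges (Hz) for artifact cleaning
#'   (applied to the continuous recording) and for clustering/backfitting
#'   (applied per epoch).
#' @param K number of microstate classes.
#' @param reject_uv artifact rejection threshold, microvolts.
#' @param exclude_channels channel names dropped from every recording before
#'   analysis (generic montage reduction).
#' @param min_peak_distance_ms GFP peak spacing, milliseconds.
#' @param max_cluster_maps cap on GFP-peak maps entering individual-level
#'   clustering per subject (evenly subsampled above it).
#' @param param_mode `"inclusive"` or `"trim_edges"` (see
#'   [temporal_parameters()]).
#' @param gev_at `"peaks"` or `"all"` (see [gev()]).
#' @param n_permutations TANOVA permutations.
#' @param alpha significance level for parameter comparisons and TANOVA.
#' @param alpha_clinical significance level on FDR-adjusted clinical
#'   correlations.
#' @param write_recordings also write the simulated recordings (+ montage,
#'   clinical table) under the run directory.
#' @param seed master seed; per-stage seeds are derived with [child_seed()].
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL,
                            epoch_length = 2,
                            clean_band = c(1, 40), cluster_band = c(2, 20),
                            K = 4L, reject_uv = 100,
                            exclude_channels = character(0),
                            min_peak_distance_ms = 10,
                            max_cluster_maps = 1000L,
                            param_mode = "inclusive",
                            gev_at = "peaks",
                            n_permutations = 5000L,
                            alpha = 0.05, alpha_clinical = 0.01,
                            write_recordings = FALSE,
                            seed = 1L) {
  abort_if(is.null(sim) && is.null(input_dir),
           "either `sim` or `input_dir` must be given")
  abort_if(!is.null(sim) && !inherits(sim, "sim_spec"),
           "`sim` must be a sim_spec")
  K <- check_count(K, "K", lower = 2L)
  check_scalar_number(epoch_length, "epoch_length", lower = 1e-12)
  abort_if(length(clean_band) != 2L || length(cluster_band) != 2L ||
             any(clean_band <= 0) || any(cluster_band <= 0) ||
             clean_band[1] >= clean_band[2] || cluster_band[1] >= cluster_band[2],
           "bands must be increasing positive pairs (lo, hi)")
  check_scalar_number(reject_uv, "reject_uv", lower = 1e-12)
  abort_if(!param_mode %in% c("inclusive", "trim_edges"), "bad param_mode")
  abort_if(!gev_at %in% c("peaks", "all"), "bad gev_at")
  n_permutations <- check_count(n_permutations, "n_permutations")
  check_scalar_number(alpha, "alpha", 0, 1)
  check_scalar_number(alpha_clinical, "alpha_clinical", 0, 1)
  structure(list(sim = sim, input_dir = input_dir,
                 epoch_length = epoch_length,
                 clean_band = as.numeric(clean_band),
                 cluster_band = as.numeric(cluster_band),
                 K = K, reject_uv = reject_uv,
                 exclude_channels = as.character(exclude_channels),
                 min_peak_distance_ms = min_peak_distance_ms,
                 max_cluster_maps = max_cluster_maps,
                 param_mode = param_mode, gev_at = gev_at,
                 n_permutations = n_permutations,
                 alpha = alpha, alpha_clinical = alpha_clinical,
                 write_recordings = isTRUE(write_recordings),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, path))` equals
#' `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  if (!is.null(lst$sim)) {
    lst$sim <- unclass(lst$sim)
    if (!is.null(lst$sim$clinical_model$mean_updrs))
      lst$sim$clinical_model$mean_updrs <-
        as.list(lst$sim$clinical_model$mean_updrs)
  }
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(lst$sim)) {
    s <- lst$sim
    if (!is.null(s$clinical_model$mean_updrs))
      s$clinical_model$mean_updrs <- unlist(s$clinical_model$mean_updrs)
    sim <- do.call(sim_spec, s[setdiff(names(s), character(0))])
  }
  do.call(pipeline_config, c(list(sim = sim),
                             lst[setdiff(names(lst), "sim")]))
}

pipeline_log <- function(run_dir, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = file.path(run_dir, "log.txt"), append = TRUE)
  invisible(line)
}

run_stage <- function(run_dir, name, expr) {
  pipeline_log(run_dir, "stage %s: start", name)
  out <- tryCatch(expr, error = function(e) {
    pipeline_log(run_dir, "stage %s: FAILED (%s)", name, conditionMessage(e))
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  pipeline_log(run_dir, "stage %s: done", name)
  out
}

recording_id <- function(rec) {
  if (rec$condition %in% c("PD_OFF", "PD_ON"))
    paste0(rec$subject_id, "_", sub("^PD_", "", rec$condition))
  else rec$subject_id
}

read_cohort_dir <- function(input_dir) {
  abort_if(!dir.exists(input_dir), sprintf("input directory not found: %s", input_dir))
  mont_path <- file.path(input_dir, "montage.txt")
  clin_path <- file.path(input_dir, "clinical.csv")
  abort_if(!file.exists(mont_path), sprintf("missing montage file: %s", mont_path))
  abort_if(!file.exists(clin_path), sprintf("missing clinical table: %s", clin_path))
  mont <- read_montage(mont_path)
  clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  files <- list.files(input_dir, pattern = "^(HC|PD)[0-9]+(_OFF|_ON)?\\.(csv|tsv|edf)$")
  abort_if(length(files) == 0L, sprintf("no recordings found in %s", input_dir))
  recs <- list()
  for (f in files) {
    id <- tools::file_path_sans_ext(f)
    sid <- sub("_(OFF|ON)$", "", id)
    condition <- if (grepl("_OFF$", id)) "PD_OFF"
                 else if (grepl("_ON$", id)) "PD_ON" else "HC"
    recs[[id]] <- read_recording(file.path(input_dir, f), mont, sid, condition)
  }
  list(recordings = recs, montage = mont, clinical = clinical)
}

write_templates_csv <- function(ts, stem) {
  utils::write.csv(as.data.frame(ts$maps), paste0(stem, ".csv"), row.names = TRUE)
  jsonlite::write_json(list(labels = ts$class_labels, level = ts$level,
                            gev = ts$gev),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Run the full microstate pipeline
#'
#' Orchestrates simulation (or loading), preprocessing, per-group two-level
#' clustering, canonical labeling, backfitting, temporal parameters and group
#' statistics, writing every result table plus a run-metadata JSON and a log
#' into `run_dir`. Deterministic given (config, seed): per-stage seeds are
#' derived from the master seed with a fixed scheme, so reruns are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results: `templates` (per
#'   group), `labels`, `gev`, `params`, `stats` (comparison table, tanova
#'   table, correlations), `clinical`, `run_dir`.
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  cat("", file = file.path(run_dir, "log.txt"))

  cohort <- run_stage(run_dir, "simulate/load", {
    if (!is.null(config$sim)) {
      spec <- config$sim
      spec$seed <- child_seed(config$seed, 1)
      out_dir <- if (config$write_recordings) file.path(run_dir, "data") else NULL
      ch <- generate_cohort(spec, out_dir = out_dir)
      list(recordings = ch$recordings, montage = ch$ground_truth$montage,
           clinical = ch$ground_truth$clinical, ground_truth = ch$ground_truth)
    } else read_cohort_dir(config$input_dir)
  })

  epochs <- run_stage(run_dir, "preprocess", {
    lapply(cohort$recordings, function(rec) {
      if (length(config$exclude_channels)) {
        keep <- !(rec$montage$name %in% config$exclude_channels)
        abort_if(sum(keep) < 8L, "channel exclusion leaves fewer than 8 channels")
        sub_mont <- montage(rec$montage$name[keep],
                            montage_positions(rec$montage)[keep, , drop = FALSE])
        rec <- eeg_recording(rec$data[keep, , drop = FALSE], rec$fs, sub_mont,
                             rec$subject_id, rec$condition)
      }
      rec <- bandpass(rec, config$clean_band[1], config$clean_band[2])
      ep <- epoch_recording(rec, config$epoch_length)
      ep <- reject_epochs(ep, config$reject_uv)
      abort_if(sum(ep$kept_mask) == 0L,
               sprintf("%s: no epochs survive artifact rejection", recording_id(rec)))
      ep <- bandpass(ep, config$cluster_band[1], config$cluster_band[2])
      average_reference(ep)
    })
  })

  conditions <- vapply(cohort$recordings, function(r) r$condition, "")
  canon <- canonical_templates(epochs[[1L]]$montage)

  templates <- run_stage(run_dir, "cluster", {
    out <- list()
    for (g in unique(conditions)) {
      subj_maps <- lapply(epochs[conditions == g], gfp_peak_maps,
                          min_distance_ms = config$min_peak_distance_ms,
                          max_maps = config$max_cluster_maps)
      ts <- two_level_cluster(subj_maps, config$K)
      out[[g]] <- label_templates(ts, canon)
      write_templates_csv(out[[g]], file.path(run_dir, paste0("templates_", g)))
    }
    out
  })

  fits <- run_stage(run_dir, "backfit", {
    lapply(names(epochs), function(id) {
      g <- conditions[[id]]
      lab <- backfit(epochs[[id]], templates[[g]], config$min_peak_distance_ms)
      list(labels = lab,
           gev = gev(epochs[[id]], lab, templates[[g]], at = config$gev_at,
                     min_distance_ms = config$min_peak_distance_ms))
    })
  })
  names(fits) <- names(epochs)
  labels <- lapply(fits, `[[`, "labels")
  gev_tab <- data.frame(id = names(fits), condition = unname(conditions),
                        gev = vapply(fits, `[[`, 0, "gev"),
                        stringsAsFactors = FALSE)
  utils::write.csv(gev_tab, file.path(run_dir, "gev.csv"), row.names = FALSE)
  for (id in names(labels)) {
    utils::write.csv(
      data.frame(epoch = labels[[id]]$epoch, label = labels[[id]]$labels),
      file.path(run_dir, paste0("labels_", id, ".csv")), row.names = FALSE)
  }

  params <- run_stage(run_dir, "params", {
    tabs <- lapply(names(labels), function(id) {
      temporal_parameters(labels[[id]], mode = config$param_mode,
                          subject_id = sub("_(OFF|ON)$", "", id),
                          condition = conditions[[id]])
    })
    out <- do.call(rbind, tabs)
    utils::write.csv(out, file.path(run_dir, "params.csv"), row.names = FALSE)
    out
  })

  stats_out <- run_stage(run_dir, "stats", {
    by_cond <- split(params, params$condition)
    comparison <- compare_parameters(by_cond[["HC"]], by_cond[["PD_OFF"]],
                                     by_cond[["PD_ON"]], alpha = config$alpha)
    utils::write.csv(comparison, file.path(run_dir, "comparison.csv"),
                     row.names = FALSE)
    for (parameter in unique(comparison$parameter)) {
      utils::write.csv(comparison[comparison$parameter == parameter, ],
                       file.path(run_dir, paste0("table_", sub("_.*$", "", parameter), ".csv")),
                       row.names = FALSE)
    }
    # subject-level class maps for TANOVA
    cls_maps <- lapply(names(epochs), function(id)
      class_mean_maps(epochs[[id]], labels[[id]],
                      min_distance_ms = config$min_peak_distance_ms))
    names(cls_maps) <- names(epochs)
    tanova_rows <- list()
    seed_t <- child_seed(config$seed, 7)
    for (ki in seq_len(config$K)) {
      take <- function(ids) sapply(ids, function(id) cls_maps[[id]][, ki])
      hc_ids <- names(epochs)[conditions == "HC"]
      off_ids <- sort(names(epochs)[conditions == "PD_OFF"])
      on_ids <- sort(names(epochs)[conditions == "PD_ON"])
      cl <- templates[[1L]]$class_labels[ki]
      t_between <- tanova(take(hc_ids), take(off_ids), "between",
                          config$n_permutations, seed = child_seed(seed_t, ki))
      t_within <- tanova(take(off_ids), take(on_ids), "within",
                         config$n_permutations,
                         seed = child_seed(seed_t, 100 + ki))
      tanova_rows[[length(tanova_rows) + 1L]] <- data.frame(
        class = cl, design = c("between", "within"),
        comparison = c("HC_vs_PD_OFF", "PD_OFF_vs_PD_ON"),
        observed_gmd = c(t_between$observed_gmd, t_within$observed_gmd),
        p = c(t_between$p, t_within$p),
        n_permutations = c(t_between$n_permutations, t_within$n_permutations),
        exhaustive = c(t_between$exhaustive, t_within$exhaustive),
        stringsAsFactors = FALSE)
    }
    tanova_tab <- do.call(rbind, tanova_rows)
    utils::write.csv(tanova_tab, file.path(run_dir, "tanova.csv"), row.names = FALSE)
    correlations <- clinical_correlations(by_cond[["PD_OFF"]], by_cond[["PD_ON"]],
                                          cohort$clinical,
                                          alpha = config$alpha_clinical)
    utils::write.csv(correlations, file.path(run_dir, "correlations.csv"),
                     row.names = FALSE)
    list(comparison = comparison, tanova = tanova_tab,
         correlations = correlations)
  })

  meta <- list(package_version = as.character(utils::packageVersion("microstate")),
               seed = config$seed,
               settings = unclass(config)[setdiff(names(config), "sim")],
               groups = unname(unique(conditions)),
               n_recordings = length(cohort$recordings))
  jsonlite::write_json(meta, file.path(run_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(cohort$clinical, file.path(run_dir, "clinical.csv"),
                   row.names = FALSE)
  pipeline_log(run_dir, "pipeline complete")
  invisible(list(templates = templates, labels = labels, gev = gev_tab,
                 params = params, stats = stats_out,
                 clinical = cohort$clinical, run_dir = run_dir,
                 ground_truth = cohort$ground_truth))
}

#' Summarize a completed pipeline run
#'
#' Reads the result tables of a [run_pipeline()] directory and renders a
#' plain-text summary: per-group mean duration / occurrence / coverage, GEV
#' mean and SD, significant parameter comparisons, and TANOVA p per class.
#'
#' @param run_dir a completed run directory.
#' @return the summary, invisibly, as a character vector (also printed).
#' @export
report <- function(run_dir) {
  need <- c("params.csv", "gev.csv", "comparison.csv", "tanova.csv",
            "correlations.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  abort_if(length(missing) > 0L,
           sprintf("run directory %s is missing artifacts: %s",
                   run_dir, paste(missing, collapse = ", ")))
  params <- utils::read.csv(file.path(run_dir, "params.csv"))
  gev_tab <- utils::read.csv(file.path(run_dir, "gev.csv"))
  comparison <- utils::read.csv(file.path(run_dir, "comparison.csv"))
  tanova_tab <- utils::read.csv(file.path(run_dir, "tanova.csv"))
  correlations <- utils::read.csv(file.path(run_dir, "correlations.csv"))

  lines <- c(sprintf("Microstate pipeline report: %s", run_dir), "")
  m <- params[params$class == "mean", ]
  for (g in unique(m$condition)) {
    mg <- m[m$condition == g, ]
    lines <- c(lines, sprintf(
      "%-7s mean duration %.4f s | total occurrence %.2f /s | GEV %.3f (SD %.3f)",
      g, mean(mg$duration_s), mean(mg$occurrence_hz),
      mean(gev_tab$gev[gev_tab$condition == g]),
      stats::sd(gev_tab$gev[gev_tab$condition == g])))
  }
  sig <- comparison[comparison$sig_hc_off | comparison$sig_hc_on |
                      comparison$sig_off_on, ]
  lines <- c(lines, "", sprintf("Significant parameter comparisons (alpha = %s): %d",
                                attr(comparison, "alpha") %||% "0.05", nrow(sig)))
  if (nrow(sig)) {
    lines <- c(lines, sprintf(
      "  %s [%s]: p(HC|OFF)=%.3g p(HC|ON)=%.3g p(OFF|ON)=%.3g",
      sig$parameter, sig$class, sig$p_hc_off, sig$p_hc_on, sig$p_off_on))
  }
  lines <- c(lines, "", "TANOVA (topography, global map dissimilarity):",
             sprintf("  class %s %s: GMD=%.3f p=%.4g", tanova_tab$class,
                     tanova_tab$comparison, tanova_tab$observed_gmd, tanova_tab$p))
  nsig <- sum(correlations$significant, na.rm = TRUE)
  lines <- c(lines, "", sprintf("Clinical correlations flagged (FDR-adjusted): %d", nsig))
  if (nsig) {
    cs <- correlations[which(correlations$significant), ]
    lines <- c(lines, sprintf("  %s ~ %s [%s]: r=%.3f p_adj=%.3g",
                              cs$parameter, cs$target, cs$class, cs$r, cs$p_adj))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
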