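# Pipeline configuration, run manifest and the end-to-end driver.

pipeline_schema <- function() {
  list(
    paths = c("out_dir", "psd_table", "edf_files", "bounds_file",
              "params_file"),
    band = c("f_min", "f_max", "df"),
    welch = c("window_s"),
    artifacts = c("amp_thresh", "flat_thresh", "bad_channel_frac"),
    mcmc = c("n_iter", "burn_in", "thin", "proposal_frac", "adapt",
             "target_accept", "fit_rates"),
    trajectories = c("parameters"),
    cohort = c("n_subjects", "sessions_per_subject", "n_minutes",
               "rot_mean", "rot_sd", "n_segments", "level"),
    seed = NULL, log_level = NULL)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections `paths`, `band`, `welch`, `artifacts`,
#' `mcmc`, `trajectories`, `cohort` plus top-level `seed` and `log_level`.
#' Unknown keys are rejected by name before any stage runs.
#'
#' @param path YAML file.
#' @return validated config list of class `ct_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a configuration list (e.g. already in memory).
#' @export
validate_pipeline_config <- function(cfg) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(schema)) {
    if (!is.null(schema[[sec]]) && !is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
      if (length(bad)) {
        stop("unknown configuration key(s) in '", sec, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$log_level <- cfg$log_level %||% "info"
  structure(cfg, class = "ct_pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(cfg, stage, recording_id = "-", minute = "-", msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[%s] recording=%s minute=%s %s", stage, recording_id,
                  minute, msg))
}

#' Run the full pipeline
#'
#' Executes the configured stages: synthesize or load minute-wise PSDs,
#' fit every minute of every recording, fit gain trajectories, extract
#' regime values, and write tables, per-recording report plots and a run
#' manifest (config hash, input hashes, package version, per-stage seeds).
#' Stage outputs are cached in `out_dir` and reused when the config hash
#' matches. A stage failure halts with the stage name and the offending
#' recording id; completed outputs stay on disk.
#'
#' @param cfg a `ct_pipeline_config` (or path to one).
#' @param seed optional override of the config seed.
#' @return list with `tables` (file paths), `series`, `trajectories`,
#'   `regimes`, `cohort_table` and `manifest`.
#' @export
run_pipeline <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- validate_pipeline_config(cfg)
  seed <- as.integer(seed %||% cfg$seed)
  out_dir <- cfg$paths$out_dir %||% tempfile("ctgain_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- if (!is.null(cfg$paths$params_file)) {
    read_ct_params(cfg$paths$params_file)
  } else ct_default_params()
  bounds <- ct_bounds()
  mc <- cfg$mcmc %||% list()
  control <- ct_control(n_iter = mc$n_iter %||% 20000L,
                        burn_in = mc$burn_in %||% 5000L,
                        thin = mc$thin %||% 10L,
                        proposal_frac = mc$proposal_frac %||% 0.02,
                        adapt = mc$adapt %||% TRUE,
                        target_accept = mc$target_accept %||% 0.3,
                        fit_rates = mc$fit_rates %||% FALSE)
  freqs <- ct_freq_grid(cfg$band$f_min %||% 0.5, cfg$band$f_max %||% 45,
                        cfg$band$df %||% 0.2)

  input_hashes <- character(0)

  # stage 1: obtain minute PSDs (simulate | read table | preprocess EDF)
  psd_cache <- file.path(out_dir, "minute_psds.tsv")
  rot <- NULL
  if (!is.null(cfg$paths$psd_table)) {
    pipeline_log(cfg, "load", msg = paste("reading", cfg$paths$psd_table))
    psds <- read_psd_table(cfg$paths$psd_table)
    input_hashes <- tools::md5sum(cfg$paths$psd_table)
  } else if (!is.null(cfg$paths$edf_files)) {
    psds <- list()
    for (f in cfg$paths$edf_files) {
      pipeline_log(cfg, "preprocess", recording_id = basename(f),
                   msg = "EDF -> minute PSDs")
      rec <- tryCatch({
        r <- read_edf(f)
        r <- bandpass_eeg(r, cfg$band$f_min %||% 0.5, cfg$band$f_max %||% 45)
        ar <- cfg$artifacts %||% list()
        r <- annotate_artifacts(r, amp_thresh = ar$amp_thresh %||% 200,
                                flat_thresh = ar$flat_thresh %||% 0.05,
                                bad_channel_frac = ar$bad_channel_frac %||% 0.5)
        minute_psds(r, recording_id = basename(f))
      }, error = function(e) {
        stop("stage 'preprocess' failed for recording '", basename(f),
             "': ", conditionMessage(e))
      })
      psds[[basename(f)]] <- rec
    }
    input_hashes <- tools::md5sum(cfg$paths$edf_files)
  } else {
    co <- cfg$cohort %||% list()
    ccfg <- cohort_config(n_minutes = co$n_minutes %||% 60,
                          rot_mean = co$rot_mean %||% 22.4,
                          rot_sd = co$rot_sd %||% 4.8,
                          n_segments = co$n_segments %||% 12)
    pipeline_log(cfg, "simulate",
                 msg = sprintf("%d subject(s) x %d session(s)",
                               co$n_subjects %||% 2,
                               co$sessions_per_subject %||% 1))
    cohort <- simulate_cohort(co$n_subjects %||% 2,
                              co$sessions_per_subject %||% 1,
                              config = ccfg, seed = derive_seed(seed, 10L),
                              params = params,
                              level = co$level %||% "psd", freqs = freqs)
    psds <- lapply(cohort$recordings, `[[`, "psds")
    rot <- vapply(cohort$recordings, `[[`, numeric(1), "rot_minute")
    write.table(cohort$ledger, file.path(out_dir, "ground_truth_ledger.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_psd_table(psds, psd_cache)

  # stage 2: minute-wise spectral fits
  series <- list()
  for (id in names(psds)) {
    pipeline_log(cfg, "fit", recording_id = id,
                 msg = sprintf("%d minutes", ncol(psds[[id]]$power)))
    series[[id]] <- tryCatch(
      ctfit_recording(psds[[id]], params = params, bounds = bounds,
                      control = control,
                      seed = derive_seed(seed, 20L, match(id, names(psds))),
                      rot_minute = if (is.null(rot)) NA_real_ else rot[[id]]),
      error = function(e) {
        stop("stage 'fit' failed for recording '", id, "': ",
             conditionMessage(e))
      })
  }
  write_gain_table(series, file.path(out_dir, "gain_timeseries.tsv"))

  # stage 3: trajectories and regime values
  pars <- cfg$trajectories$parameters %||% c("X", "Y", "Z", "G_ct", "G_tc")
  trajs <- list(); regimes <- list()
  for (id in names(series)) {
    pipeline_log(cfg, "trajectories", recording_id = id, msg = "AIC selection")
    trajs[[id]] <- fit_gain_trajectories(series[[id]], parameters = pars)
    regimes[[id]] <- regime_values(trajs[[id]], series[[id]]$rot_minute)
  }
  traj_rows <- do.call(rbind, lapply(names(trajs), function(id) {
    do.call(rbind, lapply(names(trajs[[id]]), function(p) {
      f <- trajs[[id]][[p]]
      data.frame(recording_id = id, gain = p, family = f$family,
                 coef = paste(sprintf("%s=%.6g", names(coef(f)), coef(f)),
                              collapse = ";"),
                 aic = f$aic, change_0_60 = temporal_change(f))
    }))
  }))
  write.table(traj_rows, file.path(out_dir, "trajectories.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  meta <- data.frame(subject = sub("_.*", "", names(series)),
                     session = seq_along(series))
  if (exists("cohort", inherits = FALSE)) {
    meta <- cohort$ledger[, c("subject", "session", "seizure_duration",
                              "placement", "charge", "etomidate_dose",
                              "benzodiazepine", "session_number",
                              "rot_minute")]
  }
  ctab <- cohort_table(regimes, meta)
  write_cohort_table(ctab, file.path(out_dir, "cohort_table.tsv"))

  # stage 4: report plots
  report_dir <- file.path(out_dir, "report")
  dir.create(report_dir, showWarnings = FALSE)
  for (id in names(series)) {
    grDevices::pdf(file.path(report_dir, paste0(id, ".pdf")), width = 7,
                   height = 5)
    e <- series[[id]]$estimates
    plot(e$minute, e$X, pch = 16, col = "grey50", ylim = range(
      c(e$X, e$Y, e$Z), na.rm = TRUE), xlab = "postictal minute",
      ylab = "gain", main = id)
    points(e$minute, e$Y, pch = 16, col = "steelblue")
    points(e$minute, e$Z, pch = 16, col = "seagreen")
    tt <- seq(0, max(e$minute), length.out = 200)
    for (p in intersect(c("X", "Y", "Z"), names(trajs[[id]]))) {
      lines(tt, predict(trajs[[id]][[p]], tt))
    }
    if (!is.na(series[[id]]$rot_minute)) {
      abline(v = series[[id]]$rot_minute, lty = 2)
    }
    dev.off()
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    input_hashes = as.list(input_hashes),
    package_version = as.character(utils::packageVersion("ctgain")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 10L),
                       fit = derive_seed(seed, 20L)),
    timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))

  list(tables = list(psds = psd_cache,
                     gains = file.path(out_dir, "gain_timeseries.tsv"),
                     trajectories = file.path(out_dir, "trajectories.tsv"),
                     cohort = file.path(out_dir, "cohort_table.tsv")),
       series = series, trajectories = trajs, regimes = regimes,
       cohort_table = ctab, manifest = manifest, out_dir = out_dir)
}
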