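#' Fit trajectories for every gain of a recording
#'
#' Applies [fit_trajectory()] to each requested column of a
#' [ctfit_recording()] result (MAP values by default; missing minutes are
#' dropped before fitting).
#'
#' @param series a `ctfit_series`.
#' @param parameters gain columns to fit.
#' @return named list of selected `ct_traj` fits.
#' @export
fit_gain_trajectories <- function(series,
                                  parameters = c("X", "Y", "Z", "G_ee",
                                                 "G_ei", "G_ct", "G_tc",
                                                 "G_srs")) {
  stopifnot(inherits(series, "ctfit_series"))
  e <- series$estimates
  out <- lapply(parameters, function(p) fit_trajectory(e$minute, e[[p]]))
  names(out) <- parameters
  out
}

#' Gain values at the three clinical time points
#'
#' Evaluates each gain's selected trajectory curve at the first postictal
#' minute (`t = 0` on the fitted curve), at the reorientation (ROT) minute
#' and at 60 minutes. Values are read off the fitted curves, not the raw
#' per-minute estimates.
#'
#' @param fits named list of `ct_traj` fits (one per gain), e.g. from
#'   [fit_gain_trajectories()].
#' @param rot_minute reorientation minute; `NA` marks the ROT column
#'   missing.
#' @param t_end late time point (minutes).
#' @return a `ct_regime` data frame: one row per gain with `at_minute1`,
#'   `at_rot`, `at_minute60`.
#' @export
regime_values <- function(fits, rot_minute, t_end = 60) {
  if (!is.na(rot_minute) && (rot_minute < 0 || rot_minute > t_end)) {
    stop("reorientation minute outside the record span")
  }
  rows <- lapply(names(fits), function(p) {
    f <- fits[[p]]
    data.frame(gain = p,
               at_minute1 = predict(f, 0),
               at_rot = if (is.na(rot_minute)) NA_real_ else
                 predict(f, rot_minute),
               at_minute60 = predict(f, t_end))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ct_regime", "data.frame")
  attr(out, "rot_minute") <- rot_minute
  out
}

#' Long-format cohort analysis table
#'
#' Assembles the per-recording regime values into the tidy table consumed
#' by downstream mixed-effects regression tooling: one row per subject x
#' session x gain x timepoint with the treatment covariates.
#'
#' @param regimes list of `ct_regime` data frames, one per recording.
#' @param metadata data frame with one row per recording: `subject`,
#'   `session` and covariates (e.g. `seizure_duration`, `placement`,
#'   `charge`, `etomidate_dose`, `benzodiazepine`, `session_number`,
#'   `rot_minute`).
#' @return data frame with columns `subject`, `session`, `gain`,
#'   `timepoint` (`minute1`/`rot`/`minute60`), `value`, `missing` and the
#'   covariates.
#' @export
cohort_table <- function(regimes, metadata) {
  stopifnot(length(regimes) >= 1, nrow(metadata) == length(regimes))
  covars <- setdiff(names(metadata), c("subject", "session"))
  rows <- lapply(seq_along(regimes), function(j) {
    r <- regimes[[j]]
    md <- metadata[j, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
      vals <- c(minute1 = r$at_minute1[i], rot = r$at_rot[i],
                minute60 = r$at_minute60[i])
      df <- data.frame(subject = md$subject, session = md$session,
                       gain = r$gain[i], timepoint = names(vals),
                       value = unname(vals), missing = !is.finite(vals),
                       row.names = NULL)
      for (cv in covars) df[[cv]] <- md[[cv]]
      df
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the cohort table
#'
#' Tab-delimited round trip preserving values to full precision.
#'
#' @param x cohort table data frame.
#' @param path file path.
#' @export
write_cohort_table <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  y <- x
  for (j in which(num)) y[[j]] <- sprintf("%.17g", x[[j]])
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", "NaN"))
}
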