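#' Fit every minute of a postictal recording
#'
#' Runs [ctfit()] on each non-missing minute-wise PSD in temporal order,
#' initializing each minute's chain at the previous minute's MAP (the first
#' fitted minute starts from the default init). Composite gains are
#' computed per minute; minutes that are missing, or whose fit errors out,
#' propagate as missing with a logged reason. Per-minute seeds derive
#' deterministically from `seed` via [derive_seed()].
#'
#' @param psds a `ct_minute_psds` object (from [minute_psds()] or a cohort
#'   generator).
#' @param params,bounds,control,seed as in [ctfit()].
#' @param rot_minute optional reorientation minute (metadata, carried
#'   through to trajectory/regime stages).
#' @param keep_samples keep each minute's thinned chain (memory-heavy);
#'   by default only posterior quantiles are retained.
#' @return an object of class `ctfit_series`: `estimates` (data frame with
#'   one row per minute: MAP gains, composites, 95% interval bounds, chi2,
#'   acceptance), `missing` mask, `log`, and metadata. Methods: `print`,
#'   `coef`, `as.data.frame`, `plot`.
#' @export
ctfit_recording <- function(psds, params = ct_default_params(),
                            bounds = ct_bounds(), control = ct_control(),
                            seed = 1, rot_minute = NA_real_,
                            keep_samples = FALSE) {
  stopifnot(inherits(psds, "ct_minute_psds"))
  n_min <- ncol(psds$power)
  par_names <- CT_GAIN_NAMES
  comp_names <- c("X", "Y", "Z", "G_ct", "G_tc")
  cols <- c("minute", par_names, comp_names, "chi2", "accept_rate",
            paste0(par_names, "_lo"), paste0(par_names, "_hi"))
  est <- as.data.frame(matrix(NA_real_, n_min, length(cols),
                              dimnames = list(NULL, cols)))
  est$minute <- seq_len(n_min) - 1L
  logs <- character(0)
  init <- NULL
  chains <- if (keep_samples) vector("list", n_min) else NULL

  for (m in seq_len(n_min)) {
    if (psds$missing[m]) {
      logs <- c(logs, sprintf("minute %d: missing (no clean segments)", m - 1L))
      next
    }
    fit <- tryCatch(
      ctfit(psds$power[, m], psds$freqs, params = params, bounds = bounds,
            control = control, init = init,
            seed = derive_seed(seed, m - 1L), minute_index = m - 1L),
      error = function(e) e)
    if (inherits(fit, "error")) {
      logs <- c(logs, sprintf("minute %d: fit failed (%s)", m - 1L,
                              conditionMessage(fit)))
      next
    }
    est[m, par_names] <- fit$map[par_names]
    est[m, comp_names] <- unlist(fit$gains[comp_names])
    est[m, "chi2"] <- fit$chi2
    est[m, "accept_rate"] <- fit$accept_rate
    if (nrow(fit$samples) > 1) {
      qs <- apply(fit$samples[, par_names, drop = FALSE], 2, quantile,
                  probs = c(0.025, 0.975), names = FALSE)
      est[m, paste0(par_names, "_lo")] <- qs[1, ]
      est[m, paste0(par_names, "_hi")] <- qs[2, ]
    }
    if (keep_samples) chains[[m]] <- fit$samples
    init <- fit$map
  }

  structure(list(estimates = est, missing = is.na(est$chi2),
                 recording_id = psds$recording_id, rot_minute = rot_minute,
                 n_segments = psds$n_segments, log = logs,
                 params = params, bounds = bounds, control = control,
                 seed = seed, chains = chains),
            class = "ctfit_series")
}

#' @export
print.ctfit_series <- function(x, ...) {
  cat(sprintf("Minute-wise gain estimates '%s': %d minute(s), %d missing\n",
              x$recording_id, nrow(x$estimates), sum(x$missing)))
  if (!is.na(x$rot_minute)) {
    cat(sprintf("  reorientation at minute %g\n", x$rot_minute))
  }
  ok <- !x$missing
  if (any(ok)) {
    first <- which(ok)[1]; last <- rev(which(ok))[1]
    for (m in c(first, last)) {
      e <- x$estimates[m, ]
      cat(sprintf("  minute %2d: X = %.3f, Y = %.3f, Z = %.3f (chi2 = %.3f)\n",
                  e$minute + 1L, e$X, e$Y, e$Z, e$chi2))
    }
  }
  invisible(x)
}

#' @export
coef.ctfit_series <- function(object, ...) {
  as.matrix(object$estimates[, c(CT_GAIN_NAMES, "X", "Y", "Z",
                                 "G_ct", "G_tc")])
}

#' @export
as.data.frame.ctfit_series <- function(x, ...) {
  long <- do.call(rbind, lapply(c(CT_GAIN_NAMES, "X", "Y", "Z",
                                  "G_ct", "G_tc"), function(p) {
    data.frame(recording_id = x$recording_id, minute = x$estimates$minute,
               parameter = p, map_value = x$estimates[[p]],
               ci_low = if (p %in% CT_GAIN_NAMES)
                 x$estimates[[paste0(p, "_lo")]] else NA_real_,
               ci_high = if (p %in% CT_GAIN_NAMES)
                 x$estimates[[paste0(p, "_hi")]] else NA_real_,
               chi2 = x$estimates$chi2,
               n_samples = (x$control$n_iter - x$control$burn_in) %/%
                 x$control$thin)
  }))
  rownames(long) <- NULL
  long
}

#' @export
plot.ctfit_series <- function(x, parameters = c("X", "Y", "Z"), ...) {
  e <- x$estimates
  matplot(e$minute, as.matrix(e[, parameters]), type = "b", pch = 16,
          lty = 1, xlab = "postictal minute", ylab = "gain", ...)
  if (!is.na(x$rot_minute)) abline(v = x$rot_minute, lty = 2)
  legend("topright", legend = parameters, col = seq_along(parameters),
         lty = 1, bty = "n")
  invisible(x)
}

#' Write a tidy gain time-series table
#'
#' Long-format delimited table (recording_id, minute, parameter, map_value,
#' ci_low, ci_high, chi2, n_samples).
#'
#' @param x a `ctfit_series` or list of them.
#' @param path file path.
#' @export
write_gain_table <- function(x, path) {
  if (inherits(x, "ctfit_series")) x <- list(x)
  rows <- do.call(rbind, lapply(x, as.data.frame))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
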