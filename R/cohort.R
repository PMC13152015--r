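#' Ground-truth gain trajectory over the postictal hour
#'
#' Builds per-minute loop gains whose composites follow prescribed smooth
#' paths from an early-postictal regime (cortical balance X near 1,
#' corticothalamic loop Y negative, intrathalamic Z near 0) toward a late
#' regime closer to baseline. The composite-to-constituent inversion is
#' under-determined (three targets, five gains), so the cortical inhibitory
#' gain `G_ei` and the partial corticothalamic gain `G_ct` are themselves
#' smooth interpolants between configured anchors; then
#' `G_srs = -Z (alpha+beta)^2 / (alpha beta)`, `G_ee = X (1 - G_ei)`,
#' `G_ese = G_ct (1 - G_srs)(1 - G_ei)` and
#' `G_esre = (Y - G_ct)(1 - G_srs)(1 - G_ei)`. The default anchors make the
#' partial corticothalamic gain decrease and the thalamocortical gain
#' increase over the hour. Every minute is validated against the sampler
#' bounds and for spectral stability.
#'
#' All paths use the saturating form `late + (early - late) exp(-t/tau)`.
#'
#' @param early,late named vectors with `X`, `Y`, `Z` regime anchors.
#' @param minutes 0-based minute grid.
#' @param tau named vector of time constants (minutes) for `X`, `Y`, `Z`.
#' @param g_ei,g_ct `c(early, late)` anchors for the two free constituents.
#' @param params a [ct_params] (rates used in the `Z` inversion and the
#'   stability check).
#' @param bounds a [ct_bounds] to validate against.
#' @return a `ct_true_trajectory`: data frame (minute x gains and
#'   composites) plus the generating settings.
#' @export
make_gain_trajectory <- function(early = c(X = 0.95, Y = -0.30, Z = 0.02),
                                 late = c(X = 0.72, Y = -0.08, Z = 0.12),
                                 minutes = 0:59,
                                 tau = c(X = 20, Y = 20, Z = 25),
                                 g_ei = c(-1.5, -2.0), g_ct = c(0.10, 0.08),
                                 params = ct_default_params(),
                                 bounds = ct_bounds()) {
  sat <- function(e, l, tc) l + (e - l) * exp(-minutes / tc)
  X <- sat(early[["X"]], late[["X"]], tau[["X"]])
  Y <- sat(early[["Y"]], late[["Y"]], tau[["Y"]])
  Z <- sat(early[["Z"]], late[["Z"]], tau[["Z"]])
  Gei <- sat(g_ei[1], g_ei[2], tau[["Y"]])
  Gct <- sat(g_ct[1], g_ct[2], tau[["Y"]])

  ab <- params$alpha * params$beta
  Gsrs <- -Z * (params$alpha + params$beta)^2 / ab
  Gee <- X * (1 - Gei)
  denom <- (1 - Gsrs) * (1 - Gei)
  Gese <- Gct * denom
  Gesre <- (Y - Gct) * denom

  b <- unclass(bounds)
  tab <- data.frame(minute = minutes, G_ee = Gee, G_ei = Gei, G_ese = Gese,
                    G_esre = Gesre, G_srs = Gsrs, X = X, Y = Y, Z = Z,
                    G_ct = Gct, G_tc = Y - Gct)
  for (p in CT_GAIN_NAMES) {
    viol <- tab[[p]] < b[p, "low"] | tab[[p]] > b[p, "high"]
    if (any(viol)) {
      stop("infeasible regime: ", p, " leaves [", b[p, "low"], ", ",
           b[p, "high"], "] at minute ", tab$minute[which(viol)[1]])
    }
  }
  for (m in seq_along(minutes)) {
    g <- gains_from_vector(unlist(tab[m, CT_GAIN_NAMES]),
                           alpha = params$alpha, beta = params$beta)
    sp <- ct_spectrum(g, params, ct_freq_grid(), normalize = FALSE)
    if (!sp$stable) {
      stop("infeasible regime: unstable spectrum at minute ",
           tab$minute[m], " (min loop denominator ",
           format(sp$den_min), ")")
    }
  }
  structure(list(table = tab,
                 settings = list(early = early, late = late, tau = tau,
                                 g_ei = g_ei, g_ct = g_ct)),
            class = "ct_true_trajectory")
}

#' @export
print.ct_true_trajectory <- function(x, ...) {
  tab <- x$table
  n <- nrow(tab)
  cat(sprintf("Ground-truth gain trajectory: %d minutes\n", n))
  cat(sprintf("  X: %.3f -> %.3f, Y: %.3f -> %.3f, Z: %.3f -> %.3f\n",
              tab$X[1], tab$X[n], tab$Y[1], tab$Y[n], tab$Z[1], tab$Z[n]))
  invisible(x)
}

#' Cohort generation settings
#'
#' Defaults encode the study conditions the generator emulates: sixty
#' analyzed postictal minutes, reorientation times drawn from
#' Normal(22.4, 4.8) minutes truncated to [5, 55], twelve 5-s Welch
#' segments per minute, and modest between-subject / between-session
#' Gaussian perturbations of the regime anchors (assumed scales; the study
#' does not report an inter-subject gain noise model).
#'
#' @param n_minutes minutes per recording.
#' @param rot_mean,rot_sd,rot_range reorientation-time distribution
#'   (minutes).
#' @param n_segments Welch segments averaged per minute.
#' @param subject_sd,session_sd Gaussian sd of anchor perturbations at the
#'   subject and session level, named per composite.
#' @param early,late,tau,g_ei,g_ct trajectory settings, see
#'   [make_gain_trajectory()].
#' @return list of class `ct_cohort_config`.
#' @export
cohort_config <- function(n_minutes = 60,
                          rot_mean = 22.4, rot_sd = 4.8,
                          rot_range = c(5, 55), n_segments = 12,
                          subject_sd = c(X = 0.02, Y = 0.03, Z = 0.015),
                          session_sd = c(X = 0.01, Y = 0.015, Z = 0.008),
                          early = c(X = 0.95, Y = -0.30, Z = 0.02),
                          late = c(X = 0.72, Y = -0.08, Z = 0.12),
                          tau = c(X = 20, Y = 20, Z = 25),
                          g_ei = c(-1.5, -2.0), g_ct = c(0.10, 0.08)) {
  structure(list(n_minutes = n_minutes, rot_mean = rot_mean,
                 rot_sd = rot_sd, rot_range = rot_range,
                 n_segments = n_segments, subject_sd = subject_sd,
                 session_sd = session_sd, early = early, late = late,
                 tau = tau, g_ei = g_ei, g_ct = g_ct),
            class = "ct_cohort_config")
}

#' Draw random spectrally stable gain sets
#'
#' Samples loop-gain sets through the composite parameterization
#' (X, Y, Z, G_ei, G_ct) over broad physiological ranges and keeps draws
#' whose linearized spectrum is stable with a moderate damping margin
#' (minimum loop-denominator modulus `den_margin`), so that resonances
#' remain resolvable by finite spectral estimates. Used for validation
#' sweeps against the time-domain oracle.
#'
#' @param n number of gain sets.
#' @param seed integer seed.
#' @param params a [ct_params].
#' @param den_margin stability margin on the loop denominator modulus.
#' @return list of [ct_gains] objects.
#' @export
sample_stable_gains <- function(n, seed = 1, params = ct_default_params(),
                                den_margin = 0.15) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ab2 <- (params$alpha + params$beta)^2 / (params$alpha * params$beta)
  out <- vector("list", n)
  for (j in seq_len(n)) {
    for (k in 1:1000) {
      X <- runif(1, 0.2, 0.9)
      Y <- runif(1, -0.5, min(0.88 - X, 0.5))
      Z <- runif(1, 0.01, 0.3)
      Gei <- runif(1, -6, -0.5)
      Gct <- runif(1, max(0.05, Y), max(0.05, Y) + 0.4)
      Gsrs <- -Z * ab2
      den <- (1 - Gsrs) * (1 - Gei)
      g <- ct_gains(X * (1 - Gei), Gei, Gct * den, (Y - Gct) * den, Gsrs,
                    params$alpha, params$beta)
      sp <- ct_spectrum(g, params, normalize = FALSE)
      if (sp$stable && sp$den_min >= den_margin) break
      g <- NULL
    }
    if (is.null(g)) stop("no stable draw found in 1000 attempts")
    out[[j]] <- g
  }
  out
}

rtruncnorm1 <- function(mean, sd, range) {
  for (k in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  mean
}

#' Generate a synthetic postictal cohort
#'
#' Simulates subjects x sessions postictal recordings with known
#' ground-truth gain trajectories, a reorientation event per recording,
#' and minute-wise channel-median PSDs. At the default `level = "psd"`
#' each minute's observed spectrum is drawn as a Welch average around the
#' analytic model spectrum (Gamma with shape `n_segments`, mirroring the
#' averaging of that many independent 5-s periodograms); `level = "eeg"`
#' synthesizes time-domain EEG per minute and runs the Welch stage
#' instead. Every recording is reproducible from (seed, subject, session)
#' via [derive_seed()], and all generated numbers are kept in a
#' ground-truth ledger.
#'
#' @param n_subjects,sessions_per_subject cohort dimensions.
#' @param config a [cohort_config()].
#' @param seed integer cohort seed.
#' @param params a [ct_params].
#' @param level `"psd"` (default) or `"eeg"`.
#' @param freqs frequency grid for PSD-level generation.
#' @return a `ct_cohort`: list of recordings (each with `id`, `subject`,
#'   `session`, `rot_minute`, `psds`, `truth`, covariates) plus `ledger`
#'   data frame, `config` and `seed`.
#' @export
simulate_cohort <- function(n_subjects, sessions_per_subject = 1,
                            config = cohort_config(), seed = 1,
                            params = ct_default_params(),
                            level = c("psd", "eeg"),
                            freqs = ct_freq_grid()) {
  stopifnot(n_subjects >= 1)
  level <- match.arg(level)
  recs <- list()
  ledger <- NULL
  clamp_anchor <- function(v) {
    v["Z"] <- max(v[["Z"]], 0.005)
    v["Y"] <- min(v[["Y"]], 0.85 - v[["X"]])
    v
  }
  try_truth <- function(early, late) {
    tryCatch(
      make_gain_trajectory(early = clamp_anchor(early),
                           late = clamp_anchor(late),
                           minutes = seq_len(config$n_minutes) - 1L,
                           tau = config$tau, g_ei = config$g_ei,
                           g_ct = config$g_ct, params = params),
      error = function(e) NULL)
  }
  for (subj in seq_len(n_subjects)) {
    set.seed(derive_seed(seed, 1L, subj))
    # subject-level perturbation, truncated to the feasible region
    subj_shift <- NULL
    for (try in 1:50) {
      cand <- rnorm(3, 0, config$subject_sd)
      names(cand) <- c("X", "Y", "Z")
      if (!is.null(try_truth(config$early + cand, config$late + cand))) {
        subj_shift <- cand
        break
      }
    }
    if (is.null(subj_shift)) {
      stop("no feasible subject-level perturbation for subject ", subj,
           " after 50 draws")
    }
    for (sess in seq_len(sessions_per_subject)) {
      rec_seed <- derive_seed(seed, 2L, subj, sess)
      set.seed(rec_seed)
      # anchor perturbations are truncated to the feasible (spectrally
      # stable, admissible) region: redraw on infeasibility, clamp Z to
      # stay positive and Y below the DC stability margin
      truth <- NULL
      for (try in 1:50) {
        sess_shift <- rnorm(3, 0, config$session_sd)
        names(sess_shift) <- c("X", "Y", "Z")
        truth <- try_truth(config$early + subj_shift + sess_shift,
                           config$late + subj_shift + sess_shift)
        if (!is.null(truth)) break
      }
      if (is.null(truth)) {
        # the subject-level anchors are feasible by construction
        sess_shift <- c(X = 0, Y = 0, Z = 0)
        truth <- try_truth(config$early + subj_shift,
                           config$late + subj_shift)
      }
      rot <- rtruncnorm1(config$rot_mean, config$rot_sd, config$rot_range)
      covars <- data.frame(
        seizure_duration = round(rtruncnorm1(35, 10, c(10, 120)), 1),
        placement = sample(c("BL", "RUL"), 1, prob = c(0.73, 0.27)),
        charge = round(rtruncnorm1(400, 150, c(50, 1000))),
        etomidate_dose = round(rtruncnorm1(20.1, 4.0, c(8, 40)), 1),
        benzodiazepine = runif(1) < 0.15,
        session_number = sess)
      id <- sprintf("S%02d_E%02d", subj, sess)
      psds <- if (level == "psd") {
        psd_level_minutes(truth, params, freqs, config$n_segments,
                          derive_seed(rec_seed, 3L), id)
      } else {
        eeg_level_minutes(truth, params, config$n_segments,
                          derive_seed(rec_seed, 3L), id)
      }
      recs[[id]] <- c(list(id = id, subject = subj, session = sess,
                           rot_minute = rot, psds = psds, truth = truth,
                           seed = rec_seed), as.list(covars))
      anc_e <- truth$settings$early
      anc_l <- truth$settings$late
      led <- cbind(data.frame(id = id, subject = subj, session = sess,
                              rot_minute = rot, seed = rec_seed,
                              early_X = anc_e[["X"]], early_Y = anc_e[["Y"]],
                              early_Z = anc_e[["Z"]], late_X = anc_l[["X"]],
                              late_Y = anc_l[["Y"]], late_Z = anc_l[["Z"]]),
                   covars)
      ledger <- rbind(ledger, led)
    }
  }
  structure(list(recordings = recs, ledger = ledger, config = config,
                 seed = seed, level = level, params = params),
            class = "ct_cohort")
}

psd_level_minutes <- function(truth, params, freqs, n_segments, seed, id) {
  set.seed(seed)
  tab <- truth$table
  n_min <- nrow(tab)
  power <- matrix(NA_real_, length(freqs), n_min)
  for (m in seq_len(n_min)) {
    g <- gains_from_vector(unlist(tab[m, CT_GAIN_NAMES]),
                           alpha = params$alpha, beta = params$beta)
    s <- ct_spectrum(g, params, freqs)$power
    # Welch average of n_segments independent periodograms
    power[, m] <- s * rgamma(length(s), shape = n_segments,
                             rate = n_segments)
  }
  structure(list(freqs = freqs, power = power,
                 n_segments = rep(as.integer(n_segments), n_min),
                 missing = rep(FALSE, n_min), recording_id = id),
            class = "ct_minute_psds")
}

eeg_level_minutes <- function(truth, params, n_segments, seed, id) {
  tab <- truth$table
  n_min <- nrow(tab)
  out <- NULL
  for (m in seq_len(n_min)) {
    g <- gains_from_vector(unlist(tab[m, CT_GAIN_NAMES]),
                           alpha = params$alpha, beta = params$beta)
    pm <- params_from_gains(g, params)
    eeg <- simulate_ct_eeg(pm, duration = 5 * n_segments, fs = 256,
                           seed = derive_seed(seed, m), n_channels = 1,
                           sensor_noise_sd = 0)
    mp <- minute_psds(eeg, recording_id = id)
    if (is.null(out)) {
      out <- list(freqs = mp$freqs,
                  power = matrix(NA_real_, length(mp$freqs), n_min),
                  n_segments = integer(n_min),
                  missing = rep(FALSE, n_min), recording_id = id)
    }
    # average all segments of the simulated stretch into this minute
    ok <- which(mp$n_segments > 0)
    w <- mp$n_segments[ok]
    out$power[, m] <- as.vector(mp$power[, ok, drop = FALSE] %*% w) / sum(w)
    out$n_segments[m] <- sum(w)
  }
  structure(out, class = "ct_minute_psds")
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("Synthetic postictal cohort: %d recording(s) (%s level), seed %d\n",
              length(x$recordings), x$level, x$seed))
  cat(sprintf("  reorientation minutes: mean %.1f (range %.1f-%.1f)\n",
              mean(x$ledger$rot_minute), min(x$ledger$rot_minute),
              max(x$ledger$rot_minute)))
  invisible(x)
}
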