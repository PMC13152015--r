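#' Construct a full parameter set realizing target gains
#'
#' Inverts the gain definition `G_ab = S'(V_a) nu_ab` at a chosen operating
#' point: given target loop gains, steady-state firing rates per population
#' and a split of the composite thalamic gains into their constituents, the
#' synaptic strengths are set to `nu_ab = G_ab / S'(V_a*)` and the external
#' column of `nu` is chosen so that the prescribed potentials are an exact
#' fixed point. The linearization of the resulting nonlinear system then
#' has exactly the requested gains, which is what makes the time-domain
#' simulator usable as an oracle for the analytic spectrum.
#'
#' The composites are split as `G_es = split["G_es"]`,
#' `G_se = G_ese / G_es`, `G_sr = split["G_sr"]` (negative),
#' `G_re = G_esre / (G_es G_sr)`, `G_rs = G_srs / G_sr`.
#'
#' @param gains a [ct_gains] object.
#' @param base a [ct_params] object supplying sigmoid, rates and delay.
#' @param firing steady-state firing rates (1/s) per population, named
#'   `e`, `i`, `r`, `s`; `i` must equal `e` (shared afferents).
#' @param split named vector with positive `G_es` and negative `G_sr`.
#' @return a [ct_params] object whose steady state sits at the requested
#'   firing rates and whose linearized gains equal `gains`.
#' @export
params_from_gains <- function(gains, base = ct_default_params(),
                              firing = c(e = 10, i = 10, r = 15, s = 15),
                              split = c(G_es = 2, G_sr = -1)) {
  stopifnot(inherits(gains, "ct_gains"))
  if (abs(firing[["e"]] - firing[["i"]]) > 1e-12) {
    stop("cortical populations must share a firing rate (shared afferents)")
  }
  if (any(firing <= 0) || any(firing >= base$Q_max)) {
    stop("firing rates must lie strictly inside (0, Q_max)")
  }
  if (split[["G_es"]] <= 0 || split[["G_sr"]] >= 0) {
    stop("split must have G_es > 0 and G_sr < 0")
  }
  # operating potentials from the inverse sigmoid
  p <- firing / base$Q_max
  Vstar <- base$theta + base$sigma_prime * log(p / (1 - p))
  names(Vstar) <- CT_POPS
  rho <- base$Q_max / base$sigma_prime * p * (1 - p)
  names(rho) <- CT_POPS

  G_es <- split[["G_es"]]
  G_sr <- split[["G_sr"]]
  G_se <- gains$G_ese / G_es
  G_re <- gains$G_esre / (G_es * G_sr)
  G_rs <- gains$G_srs / G_sr
  if (G_se < 0 || G_re < 0 || G_rs < 0) {
    stop("gain split yields a negative excitatory constituent; ",
         "check signs of G_ese, G_esre, G_srs")
  }

  nu <- matrix(0, 4, 5, dimnames = list(CT_POPS, CT_SOURCES))
  nu["e", "e"] <- gains$G_ee / rho["e"]
  nu["e", "i"] <- gains$G_ei / rho["e"]
  nu["e", "s"] <- G_es / rho["e"]
  nu["i", ] <- nu["e", ]
  nu["r", "e"] <- G_re / rho["r"]
  nu["r", "s"] <- G_rs / rho["r"]
  nu["s", "e"] <- G_se / rho["s"]
  nu["s", "r"] <- G_sr / rho["s"]

  # external column pins the fixed point exactly
  Q <- firing
  drive <- c(
    e = Vstar[["e"]] - (nu["e", "e"] * Q[["e"]] + nu["e", "i"] * Q[["i"]] +
                          nu["e", "s"] * Q[["s"]]),
    r = Vstar[["r"]] - (nu["r", "e"] * Q[["e"]] + nu["r", "s"] * Q[["s"]]),
    s = Vstar[["s"]] - (nu["s", "e"] * Q[["e"]] + nu["s", "r"] * Q[["r"]]))
  nu["e", "n"] <- drive[["e"]] / base$phi_n
  nu["i", "n"] <- nu["e", "n"]
  nu["r", "n"] <- drive[["r"]] / base$phi_n
  nu["s", "n"] <- drive[["s"]] / base$phi_n

  out <- base
  out$nu <- nu
  validate_ct_params(out)
  out
}

#' Simulate time-domain EEG from the corticothalamic model
#'
#' Stochastic Heun integration of the four-population delay-differential
#' system (second-order synaptodendritic dynamics per population, critically
#' damped wave equation on the cortical field, a linearly interpolated
#' `t0/2` delay buffer on thalamus-cortex propagation, white-noise drive on
#' the external input to the relay nucleus). The cortical field deviation
#' is emitted as single- or pseudo-multichannel EEG (channel copies plus
#' independent sensor noise). Deterministic for a fixed seed.
#'
#' @param params a [ct_params] object (e.g. from [params_from_gains()]).
#' @param duration length of the simulation (s).
#' @param fs output sampling rate (Hz), at least 256.
#' @param seed integer seed.
#' @param n_channels number of output channels.
#' @param channel_labels optional 10-20 labels (defaults to a standard set).
#' @param noise_sd standard deviation of the white external-drive
#'   fluctuation (1/s per sqrt(Hz)); keeps the system in its linear regime
#'   at the default.
#' @param sensor_noise_sd sd of independent additive sensor noise (uV).
#' @param eeg_scale scaling from field deviation (1/s) to uV.
#' @param dt_factor integration step is `1 / (dt_factor * fs)`.
#' @param burn_in seconds of initial transient to discard.
#' @return a `ct_eeg` object: channels x time matrix (uV) with `fs`,
#'   `channel_labels`, `reference` and empty `annotations`.
#' @export
simulate_ct_eeg <- function(params, duration = 60, fs = 256, seed = 1,
                            n_channels = 1, channel_labels = NULL,
                            noise_sd = 0.3, sensor_noise_sd = 0.2,
                            eeg_scale = 15, dt_factor = 8, burn_in = 2) {
  validate_ct_params(params)
  if (fs < 256) stop("fs must be at least 256 Hz")
  dt <- 1 / (dt_factor * fs)
  st <- ct_steady_state(params)
  n_total <- (ceiling(duration * fs) + ceiling(burn_in * fs)) * dt_factor
  set.seed(as.integer(seed) %% .Machine$integer.max)
  noise <- rnorm(n_total, sd = noise_sd / sqrt(dt))
  phie <- simulate_ct_kernel(params$Q_max, params$theta, params$sigma_prime,
                             params$alpha, params$beta, params$gamma_e,
                             params$t0, params$nu, params$phi_n, noise, dt,
                             as.integer(dt_factor),
                             st$V, st$Q[["e"]])
  keep <- seq_len(ceiling(duration * fs)) + ceiling(burn_in * fs)
  x <- eeg_scale * (phie[keep] - mean(phie[keep]))
  samples <- matrix(rep(x, each = n_channels), nrow = n_channels)
  if (sensor_noise_sd > 0) {
    samples <- samples + matrix(rnorm(length(samples), sd = sensor_noise_sd),
                                nrow = n_channels)
  }
  if (is.null(channel_labels)) {
    std <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
             "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Pz", "F9", "F10")
    channel_labels <- std[seq_len(n_channels)]
  }
  ct_eeg(samples, fs = fs, channel_labels = channel_labels)
}

#' EEG recording container
#'
#' @param samples channels x time numeric matrix (uV).
#' @param fs sampling rate (Hz).
#' @param channel_labels character vector, one per row of `samples`.
#' @param reference reference electrode label.
#' @param annotations list with `bad_channels` (character) and
#'   `bad_windows` (data.frame `start_s`, `end_s`).
#' @return an object of class `ct_eeg`.
#' @export
ct_eeg <- function(samples, fs, channel_labels, reference = "Cz",
                   annotations = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (fs <= 0) stop("fs must be positive")
  if (length(channel_labels) != nrow(samples)) {
    stop("channel label count (", length(channel_labels),
         ") does not match channel count (", nrow(samples), ")")
  }
  if (is.null(annotations)) {
    annotations <- list(bad_channels = character(0),
                        bad_windows = data.frame(start_s = numeric(0),
                                                 end_s = numeric(0)))
  }
  dur <- ncol(samples) / fs
  if (nrow(annotations$bad_windows) > 0 &&
      (any(annotations$bad_windows$start_s < 0) ||
       any(annotations$bad_windows$end_s > dur + 1e-9))) {
    stop("annotation interval outside record bounds")
  }
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels, reference = reference,
                 annotations = annotations),
            class = "ct_eeg")
}

#' @export
print.ct_eeg <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s), %.1f s at %g Hz, reference %s\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs, x$reference))
  if (length(x$annotations$bad_channels)) {
    cat("  bad channels:", paste(x$annotations$bad_channels, collapse = ", "),
        "\n")
  }
  nw <- nrow(x$annotations$bad_windows)
  if (nw) cat("  rejected windows:", nw, "\n")
  invisible(x)
}
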