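#' Frequency grid for spectral fitting
#'
#' @param f_min,f_max fit band edges (Hz); defaults match the 0.5--45 Hz
#'   acquisition filter band.
#' @param df frequency resolution (Hz); 0.2 Hz is the natural resolution of
#'   5-s Welch segments.
#' @return strictly increasing numeric vector of frequencies (Hz), starting
#'   at the first multiple of `df` at or above `f_min`.
#' @export
ct_freq_grid <- function(f_min = 0.5, f_max = 45, df = 0.2) {
  if (f_min < 0 || f_max <= f_min) stop("invalid band edges")
  f0 <- ceiling(f_min / df - 1e-9) * df
  seq(f0, f_max + 1e-9, by = df)
}

#' Dendritic (synaptodendritic) frequency response
#'
#' Frequency-domain inverse of the second-order synaptic operator:
#' `L(w) = 1 / ((1 - iw/alpha)(1 - iw/beta))`, a double low-pass with unit
#' DC gain.
#'
#' @param omega angular frequency (rad/s); vectorized.
#' @param alpha,beta synaptic decay- and rise-side rates (1/s).
#' @return complex response.
#' @export
dendritic_filter <- function(omega, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  1 / ((1 - 1i * omega / alpha) * (1 - 1i * omega / beta))
}

#' Model EEG power spectrum
#'
#' Closed-form power spectrum of the cortical excitatory field under
#' white-noise drive at the thalamic relay, from the linearization of the
#' four-population model about its steady state. The cortical wave operator
#' contributes `(1 - iw/gamma_e)^2`, every synaptic pathway carries the
#' dendritic filter `L(w)`, thalamocortical propagation carries the one-way
#' delay factor `exp(i w t0 / 2)` (so closed loops pick up `exp(i w t0)`),
#' the intrathalamic loop contributes the denominator `1 - L^2 G_srs` and
#' cortical feedback the loops through `G_ee` and `G_ei`.
#'
#' By default the spatially uniform mode is returned; `n_modes > 0` sums
#' spatial modes of a square cortex of side `L_x` (m).
#'
#' @param gains a [ct_gains] object (or coercible named list).
#' @param params a [ct_params] object supplying `gamma_e`, `t0` (and
#'   `alpha`, `beta` if the gain set carries none).
#' @param freqs frequency grid (Hz), e.g. [ct_freq_grid()].
#' @param normalize normalize to unit band-integrated power (the package
#'   fits relative power; absolute EEG power is not identifiable).
#' @param n_modes if positive, number of spatial modes per axis to sum.
#' @param L_x linear cortex size (m) for the mode sum.
#' @param noise_floor optional flat white floor added before normalization
#'   (fraction of band-mean model power); off (0) by default.
#' @return an object of class `ct_spectrum`: list with `freqs`, `power`,
#'   `stable` (logical), `den_min` (minimum loop-denominator modulus over
#'   the band) and `normalized`.
#' @export
ct_spectrum <- function(gains, params = ct_default_params(),
                        freqs = ct_freq_grid(), normalize = TRUE,
                        n_modes = 0, L_x = 0.5, noise_floor = 0) {
  if (!inherits(gains, "ct_gains")) {
    gains <- ct_gains(gains$G_ee, gains$G_ei, gains$G_ese, gains$G_esre,
                      gains$G_srs, alpha = gains$alpha %||% params$alpha,
                      beta = gains$beta %||% params$beta)
  }
  k <- psd_kernel(freqs, gains$G_ee, gains$G_ei, gains$G_ese, gains$G_esre,
                  gains$G_srs, gains$alpha, gains$beta, params$gamma_e,
                  params$t0, as.integer(n_modes), params$r_e, L_x)
  power <- k$power
  st <- stability_kernel(gains$G_ee, gains$G_ei, gains$G_ese, gains$G_esre,
                         gains$G_srs, gains$alpha, gains$beta,
                         params$gamma_e, params$t0)
  stable <- is.finite(k$den_min) && k$den_min > 1e-4 && k$dc_loop > 1e-6 &&
    st$winding == 0L && all(is.finite(power)) && all(power > 0)
  if (noise_floor > 0) power <- power + noise_floor * mean(power)
  if (normalize && stable) power <- power / trapz(freqs, power)
  structure(list(freqs = freqs, power = power, stable = stable,
                 den_min = k$den_min, dc_loop = k$dc_loop,
                 normalized = normalize),
            class = "ct_spectrum")
}

#' @export
print.ct_spectrum <- function(x, ...) {
  cat(sprintf("Model EEG spectrum: %d frequencies, %.2f-%.2f Hz, %s, %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              if (x$normalized) "unit band power" else "raw",
              if (x$stable) "stable" else "UNSTABLE parameterization"))
  invisible(x)
}

#' @export
plot.ct_spectrum <- function(x, log = "y", xlab = "frequency (Hz)",
                             ylab = "relative power", type = "l", ...) {
  plot(x$freqs, x$power, log = log, xlab = xlab, ylab = ylab, type = type,
       ...)
  invisible(x)
}

#' Normalize a spectrum to unit band-integrated power
#'
#' @param power spectral density values.
#' @param freqs matching frequency grid (Hz).
#' @return rescaled power with trapezoidal band integral 1.
#' @export
normalize_psd <- function(power, freqs) {
  tot <- trapz(freqs, power)
  if (!is.finite(tot) || tot <= 0) stop("cannot normalize: non-positive band power")
  power / tot
}

#' Read / write two-column spectra tables
#'
#' Spectra serialize as delimited tables `frequency_hz`, `power` with a
#' comment header carrying normalization metadata.
#'
#' @param x a `ct_spectrum` (or list with `freqs`, `power`).
#' @param path file path.
#' @return `read_spectrum` returns a list with `freqs`, `power`,
#'   `normalized`.
#' @export
write_spectrum <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: %s",
                     tolower(as.character(isTRUE(x$normalized)))), con)
  writeLines("frequency_hz\tpower", con)
  writeLines(sprintf("%.17g\t%.17g", x$freqs, x$power), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- readLines(path, n = 1L)
  normalized <- grepl("normalized: true", hdr, fixed = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(freqs = df$frequency_hz, power = df$power, normalized = normalized)
}

#' Detect an alpha-band spectral peak
#'
#' A spectrum is said to carry an alpha rhythm when its log-power has a
#' local maximum inside the alpha band whose height above the broadband
#' trend (the log-power chord between the band's flanks) exceeds
#' `min_prominence`. The default prominence of 1 nat (a factor e in power)
#' distinguishes a visible alpha resonance from the shallow comb
#' modulation that the conduction delay imprints on any spectrum.
#'
#' @param spec a `ct_spectrum` (or list with `freqs`, `power`).
#' @param band alpha band (Hz).
#' @param flanks background anchor frequencies (Hz).
#' @param min_prominence required height above the chord (log-power, nats).
#' @return logical; attribute `"prominence"` carries the measured height.
#' @export
alpha_peak <- function(spec, band = c(8, 13), flanks = c(6, 15),
                       min_prominence = 1) {
  f <- spec$freqs
  lp <- log(spec$power)
  idx <- which(f >= band[1] & f <= band[2])
  if (length(idx) < 3) stop("grid too coarse for the alpha band")
  pk <- idx[which.max(lp[idx])]
  has_local <- any(diff(sign(diff(lp[idx]))) == -2)
  la <- approx(f, lp, flanks[1])$y
  lb <- approx(f, lp, flanks[2])$y
  chord <- la + (lb - la) * (f[pk] - flanks[1]) / diff(flanks)
  prom <- lp[pk] - chord
  structure(has_local && prom >= min_prominence, prominence = prom)
}

#' Spectral ripple statistic
#'
#' Root-mean-square deviation of log-power from a smooth (running-median)
#' trend; quantifies the comb-like modulation produced by the
#' thalamocortical conduction delay.
#'
#' @param spec a `ct_spectrum`.
#' @param k running-median width in bins (odd).
#' @return non-negative scalar.
#' @export
spectral_ripple <- function(spec, k = 31L) {
  lp <- log(spec$power)
  sm <- stats::runmed(lp, k = k, endrule = "median")
  sqrt(mean((lp - sm)^2))
}
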