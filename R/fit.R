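#' Sampler bounds for the gain parameters
#'
#' Neurophysiologically plausible ranges (from the model family's source
#' literature) with the sign structure of the loops: cortical excitatory
#' feedback non-negative, cortical inhibitory and intrathalamic feedback
#' non-positive.
#'
#' @param G_ee,G_ei,G_ese,G_esre,G_srs length-2 `c(low, high)` ranges.
#' @param alpha,beta,t0 optional ranges, used only when rates/delay are
#'   fitted (see [ct_control()]).
#' @return an object of class `ct_bounds` (matrix with `low`/`high` rows).
#' @export
ct_bounds <- function(G_ee = c(0, 20), G_ei = c(-40, 0), G_ese = c(0, 40),
                      G_esre = c(-40, 0), G_srs = c(-14, 0),
                      alpha = c(20, 120), beta = c(100, 800),
                      t0 = c(0.06, 0.13)) {
  b <- rbind(G_ee = G_ee, G_ei = G_ei, G_ese = G_ese, G_esre = G_esre,
             G_srs = G_srs, alpha = alpha, beta = beta, t0 = t0)
  colnames(b) <- c("low", "high")
  if (any(b[, "low"] >= b[, "high"])) stop("bounds must satisfy low < high")
  if (b["G_ee", "low"] < 0 || b["G_ese", "low"] < 0 ||
      b["G_ei", "high"] > 0 || b["G_esre", "high"] > 0 ||
      b["G_srs", "high"] > 0) {
    stop("bounds violate the sign constraints of the loop gains")
  }
  structure(b, class = c("ct_bounds", "matrix"))
}

#' MCMC control settings
#'
#' @param n_iter total Metropolis-Hastings iterations.
#' @param burn_in iterations discarded (and, if `adapt`, used for proposal
#'   adaptation; scales are frozen afterwards, preserving detailed
#'   balance post burn-in).
#' @param thin keep every `thin`-th post-burn-in state.
#' @param proposal_frac initial per-parameter Gaussian proposal sd as a
#'   fraction of the bound width.
#' @param adapt adapt proposal scales toward `target_accept` during
#'   burn-in only.
#' @param target_accept acceptance target for the adaptation.
#' @param n_init size of the coarse initialization search: stable candidate
#'   gain sets are drawn across the physiological composite region
#'   (X, Y, Z, G_ei, G_ct) and the lowest-chi-square one seeds the chain
#'   when no explicit `init` is given. Set 0 to start from the fixed
#'   mid-regime default.
#' @param fit_rates also sample `alpha`, `beta`, `t0` (off by default: the
#'   estimation targets the five gains).
#' @param polish run a bounded quasi-Newton refinement from the MAP
#'   afterwards (off by default; the estimate is the MCMC output).
#' @param weights per-frequency chi-square weights (`NULL` = unit weights
#'   on log power).
#' @return a list of class `ct_control`.
#' @export
ct_control <- function(n_iter = 20000L, burn_in = 5000L, thin = 10L,
                       proposal_frac = 0.02, adapt = TRUE,
                       target_accept = 0.3, n_init = 256L,
                       fit_rates = FALSE, polish = FALSE, weights = NULL) {
  if (proposal_frac <= 0) stop("proposal scales must be positive")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), proposal_frac = proposal_frac,
                 adapt = adapt, target_accept = target_accept,
                 n_init = as.integer(n_init), fit_rates = fit_rates,
                 polish = polish, weights = weights),
            class = "ct_control")
}

#' Chi-square spectral misfit
#'
#' `chi2 = sum_f (log P_obs(f) - log P_model(f))^2 / w(f)` with unit
#' weights by default, after both spectra are normalized to unit
#' band-integrated power on the same grid; zero iff the spectra are
#' identical on the grid.
#'
#' @param observed observed power on the grid.
#' @param model model power on the grid.
#' @param freqs common frequency grid (Hz); needed for normalization.
#' @param weights optional per-frequency weights (variance-style: larger
#'   weight down-weights a bin).
#' @param normalize normalize both inputs first (default).
#' @return non-negative scalar.
#' @export
chi2_spectra <- function(observed, model, freqs, weights = NULL,
                         normalize = TRUE) {
  if (length(observed) != length(model) ||
      length(observed) != length(freqs)) {
    stop("frequency grid mismatch between observed and model spectra")
  }
  if (normalize) {
    observed <- normalize_psd(observed, freqs)
    model <- normalize_psd(model, freqs)
  }
  d <- log(observed) - log(model)
  if (is.null(weights)) sum(d^2) else sum(d^2 / weights)
}

# default chain start: a mid-regime stable gain set
default_init <- function(fit_rates = FALSE, params = NULL) {
  th <- c(G_ee = 5.4, G_ei = -7, G_ese = 5.6, G_esre = -2.8, G_srs = -0.6)
  if (fit_rates) {
    th <- c(th, alpha = params$alpha, beta = params$beta, t0 = params$t0)
  }
  th
}

#' Fit the corticothalamic model to one power spectrum
#'
#' The package's core estimator: random-walk Metropolis-Hastings sampling
#' of the five gain parameters (optionally also `alpha`, `beta`, `t0`)
#' against an observed power spectrum, with likelihood
#' `exp(-chi2 / 2)` and flat priors inside the bounds. Proposals are
#' Gaussian and reflected at the bounds (keeping them symmetric);
#' parameterizations whose linearized loop becomes unstable inside the band
#' receive zero likelihood. The reported point estimate (MAP) is the
#' minimum-chi-square state visited by the chain. Deterministic for a
#' fixed seed.
#'
#' @param observed observed power on `freqs` (a `ct_minute_psds` column, a
#'   baseline PSD, or any positive vector).
#' @param freqs frequency grid (Hz). May be omitted when `observed` is a
#'   list carrying `freqs`/`power`.
#' @param params fixed physiological parameters ([ct_params]).
#' @param bounds a [ct_bounds] object.
#' @param control a [ct_control] object.
#' @param init optional named start vector (defaults to a mid-regime
#'   stable set).
#' @param seed integer seed.
#' @param minute_index optional 0-based minute carried into the result.
#' @return an object of class `ctfit` with components `map` (named vector),
#'   `gains` ([ct_gains] at the MAP), `chi2`, `samples` (thinned
#'   post-burn-in matrix), `accept_rate`, `converged`, plus the inputs.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`.
#' @export
ctfit <- function(observed, freqs = NULL, params = ct_default_params(),
                  bounds = ct_bounds(), control = ct_control(),
                  init = NULL, seed = 1, minute_index = NULL) {
  if (is.list(observed) && !is.null(observed$power)) {
    if (is.null(freqs)) freqs <- observed$freqs
    observed <- observed$power
  }
  if (is.null(freqs)) stop("a frequency grid is required")
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("observed spectrum must be positive and finite on the grid")
  }
  obs <- normalize_psd(observed, freqs)
  log_obs <- log(obs)

  par_names <- CT_GAIN_NAMES
  if (control$fit_rates) par_names <- c(par_names, "alpha", "beta", "t0")
  b <- unclass(bounds)[par_names, , drop = FALSE]
  lo <- b[, "low"]; hi <- b[, "high"]
  searched_init <- is.null(init)
  if (is.null(init)) init <- default_init(control$fit_rates, params)
  init <- init[par_names]
  if (any(init < lo) || any(init > hi)) stop("init outside bounds")

  w <- control$weights %||% numeric(0)
  chi2_of <- function(th) {
    chi2_gain_kernel(freqs, log_obs, w, th, params$alpha, params$beta,
                     params$gamma_e, params$t0, control$fit_rates)
  }
  is_stable <- function(th) {
    alpha <- if (control$fit_rates) th[["alpha"]] else params$alpha
    beta <- if (control$fit_rates) th[["beta"]] else params$beta
    t0 <- if (control$fit_rates) th[["t0"]] else params$t0
    stability_kernel(th[[1]], th[[2]], th[[3]], th[[4]], th[[5]],
                     alpha, beta, params$gamma_e, t0)$winding == 0L
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  np <- length(par_names)
  scales <- control$proposal_frac * (hi - lo)
  th <- init
  if (searched_init && control$n_init > 0L) {
    # coarse search across the physiological composite region: draw
    # (X, Y, Z, G_ei, G_ct), invert to loop gains, keep stable in-bounds
    # candidates and seed the chain at the lowest chi-square one
    ab2 <- (params$alpha + params$beta)^2 / (params$alpha * params$beta)
    cand_chi2 <- chi2_of(th)
    for (k in seq_len(control$n_init)) {
      Xc <- runif(1, 0.05, 0.98); Yc <- runif(1, -0.6, 0.92 - Xc)
      Zc <- runif(1, 0, 0.4); Gei <- runif(1, -10, -0.5)
      Gct <- runif(1, 0, 0.6)
      Gsrs <- -Zc * ab2
      den <- (1 - Gsrs) * (1 - Gei)
      cand <- c(Xc * (1 - Gei), Gei, Gct * den, (Yc - Gct) * den, Gsrs)
      names(cand) <- CT_GAIN_NAMES
      if (control$fit_rates) {
        cand <- c(cand, alpha = params$alpha, beta = params$beta,
                  t0 = params$t0)
      }
      if (any(cand < lo) || any(cand > hi)) next
      cc <- chi2_of(cand)
      if (cc < cand_chi2 && is_stable(cand)) { th <- cand; cand_chi2 <- cc }
    }
  }
  if (!is.finite(chi2_of(th)) || !is_stable(th)) {
    stop("initial state has an unstable model spectrum; choose another init")
  }

  mh <- mh_kernel(freqs, log_obs, w, lo, hi, th, scales,
                  params$alpha, params$beta, params$gamma_e, params$t0,
                  control$fit_rates, control$n_iter, control$burn_in,
                  control$thin, control$adapt, control$target_accept)
  map <- setNames(as.numeric(mh$map), par_names)
  chi2_map <- mh$chi2_map
  samples <- mh$samples[seq_len(mh$kept), , drop = FALSE]
  colnames(samples) <- par_names
  accept_rate <- mh$accept_rate

  if (control$polish) {
    op <- tryCatch(
      stats::optim(map, chi2_of, method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && op$value < chi2_map &&
        is_stable(setNames(op$par, par_names))) {
      map <- setNames(op$par, par_names); chi2_map <- op$value
    }
  }

  gains <- gains_from_vector(map[CT_GAIN_NAMES],
                             alpha = if (control$fit_rates) map[["alpha"]] else params$alpha,
                             beta = if (control$fit_rates) map[["beta"]] else params$beta)
  structure(list(map = map, gains = gains, chi2 = chi2_map,
                 samples = samples,
                 accept_rate = accept_rate,
                 converged = accept_rate > 0.01 && accept_rate < 0.95,
                 freqs = freqs, observed = obs, params = params,
                 bounds = bounds, control = control, seed = seed,
                 minute_index = minute_index),
            class = "ctfit")
}

#' @export
print.ctfit <- function(x, ...) {
  cat("Corticothalamic spectral fit")
  if (!is.null(x$minute_index)) cat(" (minute", x$minute_index + 1L, ")")
  cat("\n  MAP gains: ",
      paste(sprintf("%s = %.3f", names(x$map), x$map), collapse = ", "),
      "\n", sep = "")
  g <- x$gains
  cat(sprintf("  composites: X = %.3f, Y = %.3f, Z = %.3f (G_ct = %.3f, G_tc = %.3f)\n",
              g$X, g$Y, g$Z, g$G_ct, g$G_tc))
  cat(sprintf("  chi2 = %.4f, acceptance = %.2f, %d thinned samples\n",
              x$chi2, x$accept_rate, nrow(x$samples)))
  invisible(x)
}

#' @export
coef.ctfit <- function(object, composites = TRUE, ...) {
  out <- object$map
  if (composites) {
    g <- object$gains
    out <- c(out, X = g$X, Y = g$Y, Z = g$Z, G_ct = g$G_ct, G_tc = g$G_tc)
  }
  out
}

#' @export
summary.ctfit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  s <- object$samples
  comp <- t(apply(s[, CT_GAIN_NAMES, drop = FALSE], 1, function(r) {
    compose_gains(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]],
                  object$params$alpha, object$params$beta)
  }))
  all <- cbind(s, comp)
  qs <- t(apply(all, 2, quantile, probs = probs, names = FALSE))
  colnames(qs) <- sprintf("q%g", 100 * probs)
  out <- list(map = coef(object), quantiles = qs, chi2 = object$chi2,
              accept_rate = object$accept_rate,
              n_samples = nrow(s), converged = object$converged)
  class(out) <- "summary.ctfit"
  out
}

#' @export
print.summary.ctfit <- function(x, ...) {
  cat("Corticothalamic spectral fit summary\n")
  cat(sprintf("  chi2 (MAP) = %.4f, acceptance = %.2f, samples = %d\n",
              x$chi2, x$accept_rate, x$n_samples))
  tab <- cbind(MAP = x$map[rownames(x$quantiles)], x$quantiles)
  print(round(tab, 4))
  invisible(x)
}

#' @export
fitted.ctfit <- function(object, ...) {
  ct_spectrum(object$gains, object$params, object$freqs)$power
}

#' @export
residuals.ctfit <- function(object, ...) {
  log(object$observed) - log(fitted(object))
}

#' @export
predict.ctfit <- function(object, freqs = NULL, ...) {
  if (is.null(freqs)) freqs <- object$freqs
  ct_spectrum(object$gains, object$params, freqs)$power
}

#' @export
plot.ctfit <- function(x, ...) {
  plot(x$freqs, x$observed, log = "y", type = "l", col = "grey40",
       xlab = "frequency (Hz)", ylab = "relative power", ...)
  lines(x$freqs, fitted(x), col = "firebrick", lwd = 2)
  legend("topright", legend = c("observed", "model (MAP)"),
         col = c("grey40", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(x)
}
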