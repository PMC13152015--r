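#' Physiological parameter set of the corticothalamic model
#'
#' Bundles the full parameter set of the four-population (cortical
#' excitatory/inhibitory, thalamic reticular/relay) mean-field model:
#' the firing-rate sigmoid (`Q_max`, `theta`, `sigma_prime`), the
#' synaptodendritic rates (`alpha`, `beta`), the cortical wave damping rate
#' (`gamma_e`), the full corticothalamic loop delay `t0` (one-way delay is
#' `t0/2`), the synaptic strength matrix `nu` and the mean external drive
#' `phi_n`.
#'
#' `nu` is a 4 x 5 matrix (rows: target population `e`, `i`, `r`, `s`;
#' columns: source `e`, `i`, `r`, `s`, `n`) in mV s. Only the anatomical
#' connections of the model are used (`e,i <- e,i,s,n`; `r <- e,s,n`;
#' `s <- e,r,n`); other entries must be zero. Inhibitory sources
#' (column `i`; reticular input to the relay, entry `s,r`) must be
#' non-positive and the neural excitatory entries non-negative. The external
#' column `n` is a net non-corticothalamic tone and may take either sign.
#' The two cortical populations share afferents (`nu["i", ] == nu["e", ]`,
#' the random-connectivity symmetry), which the closed-form spectrum relies
#' on.
#'
#' @param Q_max maximum firing rate (1/s).
#' @param theta mean firing threshold potential (mV).
#' @param sigma_prime sigmoid scale (mV); `pi/3` times the threshold-spread
#'   standard deviation in the source convention, see the vignette.
#' @param alpha,beta synaptic decay- and rise-side rates (1/s).
#' @param gamma_e cortical axonal damping rate (1/s).
#' @param t0 full corticothalamic loop delay (s).
#' @param r_e cortical mean axonal range (m), used only by the optional
#'   spatial mode-sum spectrum.
#' @param nu synaptic strength matrix, see Details.
#' @param phi_n mean external drive (1/s).
#' @return an object of class `ct_params`.
#' @seealso [ct_default_params()], [params_from_gains()]
#' @export
ct_params <- function(Q_max = 340, theta = 12.9, sigma_prime = 3.8,
                      alpha = 60, beta = 240, gamma_e = 116, t0 = 0.08,
                      r_e = 0.086, nu = NULL, phi_n = 100) {
  if (is.null(nu)) {
    nu <- matrix(0, 4, 5, dimnames = list(CT_POPS, CT_SOURCES))
  }
  p <- structure(list(Q_max = Q_max, theta = theta, sigma_prime = sigma_prime,
                      alpha = alpha, beta = beta, gamma_e = gamma_e, t0 = t0,
                      r_e = r_e, nu = nu, phi_n = phi_n),
                 class = "ct_params")
  validate_ct_params(p)
  p
}

validate_ct_params <- function(p) {
  stopifnot(inherits(p, "ct_params"))
  num <- c("Q_max", "sigma_prime", "alpha", "beta", "gamma_e", "t0", "r_e")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", f, "' must be a single positive number")
    }
  }
  if (!is.finite(p$theta)) stop("'theta' must be finite")
  nu <- p$nu
  if (!is.matrix(nu) || !identical(dim(nu), c(4L, 5L))) {
    stop("'nu' must be a 4 x 5 matrix (rows e,i,r,s; columns e,i,r,s,n)")
  }
  dimnames(nu) <- list(CT_POPS, CT_SOURCES)
  if (any(!is.finite(nu))) stop("'nu' contains non-finite entries")
  # anatomical zeros
  zero_idx <- rbind(c("e", "r"), c("i", "r"), c("r", "i"), c("r", "r"),
                    c("s", "i"), c("s", "s"))
  if (any(abs(nu[zero_idx]) > 0)) {
    stop("'nu' has a non-zero entry on a connection absent from the model ",
         "(reticular->cortex, i->r, r->r, i->s or s->s)")
  }
  if (any(nu[, "i"] > 0) || nu["s", "r"] > 0) {
    stop("inhibitory synaptic strengths (source i; reticular->relay) must be <= 0")
  }
  if (any(nu[c("e", "i", "r"), "e"] < 0) || any(nu[c("e", "i"), "s"] < 0) ||
      nu["r", "s"] < 0 || nu["s", "e"] < 0) {
    stop("excitatory synaptic strengths must be >= 0")
  }
  if (any(abs(nu["i", 1:4] - nu["e", 1:4]) > 1e-12)) {
    stop("random-connectivity symmetry violated: nu['i', ] must equal nu['e', ]")
  }
  invisible(p)
}

#' Default physiological parameter set
#'
#' Reads the nominal parameter configuration shipped with the package
#' (values in the range of the Robinson-model source literature; the loop
#' delay gives the 40 ms one-way thalamocortical delay). Used for synthesis
#' and sampler initialization only -- every model computation takes its
#' parameters explicitly.
#'
#' @return a [ct_params] object.
#' @export
ct_default_params <- function() {
  path <- system.file("extdata", "default_params.yaml", package = "ctgain")
  if (!nzchar(path)) stop("default parameter config not found")
  read_ct_params(path)
}

#' Read / write a parameter configuration
#'
#' Parameter sets serialize to a flat YAML mapping, one entry per symbol
#' (`nu` flattened to `nu_ab` keys), each with a full-precision `value` and
#' a `unit` string; the round trip is lossless.
#'
#' @param path file path.
#' @param params a [ct_params] object.
#' @return `read_ct_params` returns a [ct_params] object;
#'   `write_ct_params` returns `path` invisibly.
#' @export
read_ct_params <- function(path) {
  raw <- yaml::read_yaml(path)
  val <- function(key) {
    entry <- raw[[key]]
    if (is.null(entry)) stop("parameter config is missing key '", key, "'")
    as.numeric(entry$value)
  }
  nu <- matrix(0, 4, 5, dimnames = list(CT_POPS, CT_SOURCES))
  for (a in CT_POPS) for (b in CT_SOURCES) {
    key <- paste0("nu_", a, b)
    if (!is.null(raw[[key]])) nu[a, b] <- as.numeric(raw[[key]]$value)
  }
  ct_params(Q_max = val("Q_max"), theta = val("theta"),
            sigma_prime = val("sigma_prime"), alpha = val("alpha"),
            beta = val("beta"), gamma_e = val("gamma_e"), t0 = val("t0"),
            r_e = val("r_e"), nu = nu, phi_n = val("phi_n"))
}

#' @rdname read_ct_params
#' @export
write_ct_params <- function(params, path) {
  validate_ct_params(params)
  units <- c(Q_max = "s^-1", theta = "mV", sigma_prime = "mV",
             alpha = "s^-1", beta = "s^-1", gamma_e = "s^-1", t0 = "s",
             r_e = "m", phi_n = "s^-1")
  out <- list()
  # values stored as %.17g strings so the round trip is bit-lossless
  fmt <- function(x) sprintf("%.17g", x)
  for (f in names(units)) {
    out[[f]] <- list(value = fmt(params[[f]]), unit = unname(units[f]))
  }
  for (a in CT_POPS) for (b in CT_SOURCES) {
    out[[paste0("nu_", a, b)]] <-
      list(value = fmt(params$nu[a, b]), unit = "mV s")
  }
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @export
print.ct_params <- function(x, ...) {
  cat("Corticothalamic model parameters\n")
  cat(sprintf("  sigmoid: Q_max = %g /s, theta = %g mV, sigma' = %g mV\n",
              x$Q_max, x$theta, x$sigma_prime))
  cat(sprintf("  rates: alpha = %g /s, beta = %g /s, gamma_e = %g /s\n",
              x$alpha, x$beta, x$gamma_e))
  cat(sprintf("  loop delay t0 = %g ms (one-way %g ms), phi_n = %g /s\n",
              1000 * x$t0, 500 * x$t0, x$phi_n))
  cat("  nu (mV s):\n")
  print(round(x$nu, 4))
  invisible(x)
}
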