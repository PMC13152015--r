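#' Sigmoid firing-rate function and its slope
#'
#' Converts a mean membrane potential into a population firing rate,
#' `Q(V) = Q_max / (1 + exp(-(V - theta)/sigma'))`, and gives the
#' instantaneous sensitivity `dQ/dV`, which is maximal at `V = theta` with
#' value `Q_max / (4 sigma')`.
#'
#' @param V mean membrane potential (mV); vectorized.
#' @param params a [ct_params] object.
#' @return firing rate (1/s) resp. sensitivity (1/s/mV).
#' @examples
#' p <- ct_params(Q_max = 100, theta = 10, sigma_prime = 2)
#' ct_sigmoid(10, p)        # Q_max / 2
#' ct_sigmoid_slope(10, p)  # Q_max / (4 sigma')
#' @export
ct_sigmoid <- function(V, params) {
  if (any(!is.finite(V))) stop("non-finite membrane potential")
  params$Q_max / (1 + exp(-(V - params$theta) / params$sigma_prime))
}

#' @rdname ct_sigmoid
#' @export
ct_sigmoid_slope <- function(V, params) {
  if (any(!is.finite(V))) stop("non-finite membrane potential")
  x <- (V - params$theta) / params$sigma_prime
  e <- exp(-abs(x))                    # stable for large |x|
  params$Q_max / params$sigma_prime * e / (1 + e)^2
}

#' Steady state of the four-population model
#'
#' Solves the fixed point of the model with all time derivatives zero:
#' `V_a = sum_b nu_ab Q(V_b) + nu_an phi_n` simultaneously for the four
#' populations. By the shared-afferent symmetry `V_i = V_e`, the problem
#' reduces to the cortical potential plus an inner reticular/relay fixed
#' point. A damped iteration starting at `theta - 3 sigma'` (selecting the
#' low-firing branch) is used first; if it fails to converge, a bracketing
#' scan of the 1-D reduction on the cortical potential takes the lowest
#' root.
#'
#' @param params a [ct_params] object.
#' @param tol residual tolerance (mV).
#' @param max_iter iteration budget for the damped iteration.
#' @return an object of class `ct_steady_state`: list with named potentials
#'   `V` (mV), firing rates `Q` (1/s) and the final `residual`.
#' @export
ct_steady_state <- function(params, tol = 1e-10, max_iter = 500L) {
  validate_ct_params(params)
  nu <- params$nu
  phi_n <- params$phi_n

  # inner reticular/relay fixed point for a given cortical rate Q_e
  inner <- function(Q_e, V_r, V_s) {
    for (k in seq_len(200L)) {
      V_r_new <- nu["r", "e"] * Q_e + nu["r", "s"] * ct_sigmoid(V_s, params) +
        nu["r", "n"] * phi_n
      V_s_new <- nu["s", "e"] * Q_e + nu["s", "r"] * ct_sigmoid(V_r_new, params) +
        nu["s", "n"] * phi_n
      if (max(abs(V_r_new - V_r), abs(V_s_new - V_s)) < tol / 10) {
        return(c(V_r_new, V_s_new))
      }
      V_r <- 0.5 * V_r + 0.5 * V_r_new
      V_s <- 0.5 * V_s + 0.5 * V_s_new
    }
    c(V_r, V_s)
  }

  cortical_map <- function(V_e, V_r, V_s) {
    Q_e <- ct_sigmoid(V_e, params)
    rs <- inner(Q_e, V_r, V_s)
    F_e <- (nu["e", "e"] + nu["e", "i"]) * Q_e +
      nu["e", "s"] * ct_sigmoid(rs[2], params) + nu["e", "n"] * phi_n
    list(F = F_e, V_r = rs[1], V_s = rs[2])
  }

  V0 <- params$theta - 3 * params$sigma_prime
  V_e <- V0; V_r <- V0; V_s <- V0
  converged <- FALSE
  res <- Inf
  for (k in seq_len(max_iter)) {
    m <- cortical_map(V_e, V_r, V_s)
    res <- abs(m$F - V_e)
    V_r <- m$V_r; V_s <- m$V_s
    if (res < tol) { converged <- TRUE; break }
    V_e <- 0.5 * V_e + 0.5 * m$F
  }

  if (!converged) {
    # bracketing fallback on g(V_e) = V_e - F(V_e); take the lowest root
    g <- function(v) v - cortical_map(v, v, v)$F
    grid <- seq(params$theta - 40 * params$sigma_prime,
                params$theta + 20 * params$sigma_prime, length.out = 241L)
    gv <- vapply(grid, g, numeric(1))
    sgn <- which(gv[-1] * gv[-length(gv)] <= 0)
    if (length(sgn) == 0) {
      stop("steady-state solver did not converge; last residual = ",
           format(res), " mV")
    }
    root <- uniroot(g, lower = grid[sgn[1]], upper = grid[sgn[1] + 1],
                    tol = tol / 10)$root
    m <- cortical_map(root, root, root)
    V_e <- root; V_r <- m$V_r; V_s <- m$V_s
    res <- abs(m$F - root)
    if (res > tol * 10) {
      stop("steady-state solver did not converge; last residual = ",
           format(res), " mV")
    }
  } else {
    V_e <- m$F
  }

  V <- c(e = V_e, i = V_e, r = V_r, s = V_s)
  Q <- ct_sigmoid(V, params)
  names(Q) <- CT_POPS
  structure(list(V = V, Q = Q, residual = res), class = "ct_steady_state")
}

#' @export
print.ct_steady_state <- function(x, ...) {
  cat("Corticothalamic steady state\n")
  df <- data.frame(population = CT_POPS, V_mV = round(x$V, 4),
                   Q_per_s = round(x$Q, 3), row.names = NULL)
  print(df)
  cat("residual:", format(x$residual), "mV\n")
  invisible(x)
}

#' Linearized synaptic gains at a steady state
#'
#' A gain is the product of the sigmoid sensitivity at the operating point
#' and the synaptic coupling strength, `G_ab = S'(V_a) nu_ab`. Returns the
#' five estimated loop gains (`G_ee`, `G_ei`, the composite corticothalamic
#' `G_ese = G_es G_se`, the cortico-reticulo-thalamic `G_esre =
#' G_es G_sr G_re` and the intrathalamic `G_srs = G_sr G_rs`) together with
#' the composite parameters from [compose_gains()].
#'
#' @param params a [ct_params] object.
#' @param state a `ct_steady_state`, e.g. from [ct_steady_state()]; computed
#'   if missing.
#' @return a [ct_gains] object.
#' @export
gains_from_state <- function(params, state = NULL) {
  validate_ct_params(params)
  if (is.null(state)) state <- ct_steady_state(params)
  rho <- ct_sigmoid_slope(state$V, params)
  nu <- params$nu
  G <- function(a, b) unname(rho[a] * nu[a, b])
  ct_gains(G_ee = G("e", "e"),
           G_ei = G("e", "i"),
           G_ese = G("e", "s") * G("s", "e"),
           G_esre = G("e", "s") * G("s", "r") * G("r", "e"),
           G_srs = G("s", "r") * G("r", "s"),
           alpha = params$alpha, beta = params$beta)
}

#' Composite gain parameters
#'
#' Builds the composite parameters from the five loop gains: the cortical
#' excitatory/inhibitory balance `X = G_ee / (1 - G_ei)`, the partial
#' corticothalamic and thalamocortical loop gains
#' `G_ct = G_ese / ((1 - G_srs)(1 - G_ei))`,
#' `G_tc = G_esre / ((1 - G_srs)(1 - G_ei))`, the corticothalamic loop gain
#' `Y = G_ct + G_tc` and the intrathalamic gain
#' `Z = -G_srs alpha beta / (alpha + beta)^2`.
#'
#' @param G_ee,G_ei,G_ese,G_esre,G_srs the five loop gains (dimensionless).
#' @param alpha,beta synaptodendritic rates (1/s).
#' @return named numeric vector with `X`, `Y`, `Z`, `G_ct`, `G_tc`.
#' @examples
#' compose_gains(2, -1, 0.5, -1, -0.5, 100, 100)
#' @export
compose_gains <- function(G_ee, G_ei, G_ese, G_esre, G_srs, alpha, beta) {
  if (abs(1 - G_ei) < 1e-12) stop("composite gains undefined: G_ei = 1")
  if (abs(1 - G_srs) < 1e-12) stop("composite gains undefined: G_srs = 1")
  denom <- (1 - G_srs) * (1 - G_ei)
  G_ct <- G_ese / denom
  G_tc <- G_esre / denom
  c(X = G_ee / (1 - G_ei),
    Y = G_ct + G_tc,
    Z = -G_srs * alpha * beta / (alpha + beta)^2,
    G_ct = G_ct,
    G_tc = G_tc)
}

#' Gain-parameter set
#'
#' Holds the five loop gains together with the synaptodendritic rates and
#' the derived composite parameters (see [compose_gains()]).
#'
#' @param G_ee,G_ei,G_ese,G_esre,G_srs the five loop gains.
#' @param alpha,beta rates used for the intrathalamic composite `Z`.
#' @return an object of class `ct_gains`: a named list with the five gains,
#'   the rates and components `X`, `Y`, `Z`, `G_ct`, `G_tc`.
#' @export
ct_gains <- function(G_ee, G_ei, G_ese, G_esre, G_srs, alpha = 60, beta = 240) {
  g <- c(G_ee = G_ee, G_ei = G_ei, G_ese = G_ese, G_esre = G_esre,
         G_srs = G_srs)
  if (any(!is.finite(g))) stop("non-finite gain")
  comp <- compose_gains(G_ee, G_ei, G_ese, G_esre, G_srs, alpha, beta)
  structure(c(as.list(g), list(alpha = alpha, beta = beta),
              as.list(comp)),
            class = "ct_gains")
}

#' @export
print.ct_gains <- function(x, digits = 4, ...) {
  cat("Corticothalamic gain set\n  loop gains: ")
  cat(paste(sprintf("%s = %.*g", CT_GAIN_NAMES,
                    digits, unlist(x[CT_GAIN_NAMES])), collapse = ", "), "\n")
  cat("  composites: ")
  cat(paste(sprintf("%s = %.*g", c("X", "Y", "Z", "G_ct", "G_tc"), digits,
                    unlist(x[c("X", "Y", "Z", "G_ct", "G_tc")])),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.numeric.ct_gains <- function(x, ...) {
  unlist(x[CT_GAIN_NAMES])
}

gains_from_vector <- function(th, alpha = 60, beta = 240) {
  ct_gains(th[[1]], th[[2]], th[[3]], th[[4]], th[[5]],
           alpha = alpha, beta = beta)
}
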