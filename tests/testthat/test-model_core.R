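test_that("sigmoid firing rate matches its closed form and limits", {
  p <- ct_params(Q_max = 100, theta = 10, sigma_prime = 2)
  expect_equal(ct_sigmoid(10, p), 50)
  expect_equal(ct_sigmoid(12, p), 100 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(ct_sigmoid(12, p), 73.1059, tolerance = 1e-5)
  expect_lt(ct_sigmoid(-1e3, p), 1e-10)
  expect_equal(ct_sigmoid(1e3, p), 100)
  # strictly increasing
  v <- seq(-20, 40, by = 0.5)
  expect_true(all(diff(ct_sigmoid(v, p)) > 0))
  expect_true(all(ct_sigmoid(v, p) > 0 & ct_sigmoid(v, p) < 100))
  expect_error(ct_sigmoid(NaN, p), "non-finite")
})

test_that("sigmoid slope is the analytic derivative with maximum Qmax/(4 sigma')", {
  p <- ct_params(Q_max = 100, theta = 10, sigma_prime = 2)
  expect_equal(ct_sigmoid_slope(10, p), 100 / (4 * 2))
  # value at V = 12 from the analytic derivative
  expect_equal(ct_sigmoid_slope(12, p),
               100 / 2 * exp(-1) / (1 + exp(-1))^2, tolerance = 1e-12)
  expect_equal(ct_sigmoid_slope(12, p), 9.8306, tolerance = 1e-4)
  # centered finite difference oracle
  h <- 1e-6
  for (v in c(3.7, 10, 12, 18.2)) {
    fd <- (ct_sigmoid(v + h, p) - ct_sigmoid(v - h, p)) / (2 * h)
    expect_equal(ct_sigmoid_slope(v, p), fd, tolerance = 1e-7)
  }
  # symmetry about theta
  expect_equal(ct_sigmoid_slope(13.3, p), ct_sigmoid_slope(2 * 10 - 13.3, p))
})

test_that("steady state is self-consistent and handles the decoupled case", {
  # decoupled: all nu zero, phi_n irrelevant
  p0 <- ct_params()
  st0 <- ct_steady_state(p0)
  expect_equal(unname(st0$V), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(st0$Q), rep(ct_sigmoid(0, p0), 4), tolerance = 1e-9)

  # nominal coupled set: fixed-point map reproduces V
  p <- fixture_params()
  st <- ct_steady_state(p)
  expect_lt(st$residual, 1e-9)
  for (a in c("e", "i", "r", "s")) {
    rhs <- sum(p$nu[a, 1:4] * st$Q) + p$nu[a, "n"] * p$phi_n
    expect_equal(unname(st$V[a]), rhs, tolerance = 1e-8)
    expect_equal(unname(st$Q[a]), ct_sigmoid(st$V[[a]], p))
    expect_gt(st$Q[[a]], 0)
    expect_lt(st$Q[[a]], p$Q_max)
  }
})

test_that("steady state matches the long-time mean of the simulator", {
  p <- fixture_params()
  st <- ct_steady_state(p)
  # raw (uncentered) field trace from the integration kernel
  noise <- local({
    set.seed(5)
    rnorm((60 * 256 + 2 * 256) * 8, sd = 0.05 / sqrt(1 / 2048))
  })
  phie <- ctgain:::simulate_ct_kernel(p$Q_max, p$theta, p$sigma_prime,
                                      p$alpha, p$beta, p$gamma_e, p$t0,
                                      p$nu, p$phi_n, noise, 1 / 2048, 8L,
                                      st$V, st$Q[["e"]])
  expect_equal(mean(phie), st$Q[["e"]], tolerance = 0.01)
})

test_that("linearized gains scale with coupling and match finite differences", {
  p <- fixture_params()
  st <- ct_steady_state(p)
  g <- gains_from_state(p, st)
  rho <- ct_sigmoid_slope(st$V, p)
  # zero coupling -> zero gain
  p2 <- p; p2$nu["e", "e"] <- 0; p2$nu["i", "e"] <- 0
  expect_identical(gains_from_state(p2, st)$G_ee, 0)
  # linearity in the coupling strength at fixed steady state
  p3 <- p; p3$nu["e", "e"] <- 2 * p$nu["e", "e"]
  p3$nu["i", "e"] <- p3$nu["e", "e"]
  expect_equal(gains_from_state(p3, st)$G_ee, 2 * g$G_ee, tolerance = 1e-12)
  # finite-difference oracle on the sigmoid response:
  # d(Q_a)/d(phi_b) at fixed other inputs equals S'(V_a) nu_ab
  h <- 1e-6
  V_e <- st$V[["e"]]
  fd <- (ct_sigmoid(V_e + p$nu["e", "s"] * h, p) -
           ct_sigmoid(V_e - p$nu["e", "s"] * h, p)) / (2 * h)
  expect_equal(fd, unname(rho["e"] * p$nu["e", "s"]), tolerance = 1e-6)
})

test_that("compose_gains reproduces the composite identities", {
  out <- compose_gains(2, -1, 0.5, -1.0, -0.5, 100, 100)
  expect_equal(unname(out["X"]), 1.0)
  expect_equal(unname(out["G_ct"]), 0.5 / 3, tolerance = 1e-12)
  expect_equal(unname(out["G_tc"]), -1 / 3, tolerance = 1e-12)
  expect_equal(unname(out["Y"]), -1 / 6, tolerance = 1e-12)
  expect_equal(unname(out["Z"]), 0.125)
  # zero cases
  expect_equal(unname(compose_gains(3, 0, 1, -1, -0.5, 60, 240)["X"]), 3)
  expect_equal(unname(compose_gains(3, -2, 1, -1, 0, 60, 240)["Z"]), 0)
  # guards
  expect_error(compose_gains(1, 1, 1, -1, -0.5, 60, 240), "G_ei")
  expect_error(compose_gains(1, -1, 1, -1, 1, 60, 240), "G_srs")
})

test_that("composite identities hold over random admissible draws", {
  set.seed(42)
  for (k in 1:200) {
    G_ee <- runif(1, 0, 20); G_ei <- runif(1, -40, 0)
    G_ese <- runif(1, 0, 40); G_esre <- runif(1, -40, 0)
    G_srs <- runif(1, -14, 0)
    a <- runif(1, 30, 120); b <- runif(1, 120, 600)
    out <- compose_gains(G_ee, G_ei, G_ese, G_esre, G_srs, a, b)
    expect_identical(unname(out["Y"]), unname(out["G_ct"] + out["G_tc"]))
    expect_identical(sign(out[["Z"]]), -sign(G_srs))
    expect_equal(out[["X"]], G_ee / (1 - G_ei))
    # deterministic pure function
    expect_identical(out, compose_gains(G_ee, G_ei, G_ese, G_esre, G_srs,
                                        a, b))
  }
})

test_that("early-postictal regime (X near 1, Y < 0, Z near 0) is admissible", {
  b <- unclass(ct_bounds())
  g <- make_gain_trajectory(params = fixture_params())$table[1, ]
  expect_gt(g$X, 0.9); expect_lt(g$Y, 0); expect_lt(abs(g$Z), 0.05)
  for (p in c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs")) {
    expect_gte(g[[p]], b[p, "low"])
    expect_lte(g[[p]], b[p, "high"])
  }
})

test_that("parameter sets round-trip through the config format", {
  p <- fixture_params()
  tmp <- tempfile(fileext = ".yaml")
  write_ct_params(p, tmp)
  p2 <- read_ct_params(tmp)
  expect_identical(p$nu, p2$nu)
  for (f in c("Q_max", "theta", "sigma_prime", "alpha", "beta", "gamma_e",
              "t0", "r_e", "phi_n")) {
    expect_identical(p[[f]], p2[[f]])
  }
  # invalid sets are rejected
  bad <- p; bad$nu["e", "i"] <- 1
  expect_error(validate_ct_params(bad), "inhibitory")
  bad2 <- p; bad2$nu["i", "e"] <- bad2$nu["i", "e"] + 1
  expect_error(validate_ct_params(bad2), "symmetry")
})
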