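test_that("zero-noise simulation stays at the fixed point", {
  params <- fixture_params()
  pf <- params_from_gains(fixture_gains(), params)
  st <- ct_steady_state(pf)
  noise <- rep(0, 10 * 2048)
  phie <- ctgain:::simulate_ct_kernel(pf$Q_max, pf$theta, pf$sigma_prime,
                                      pf$alpha, pf$beta, pf$gamma_e, pf$t0,
                                      pf$nu, pf$phi_n, noise, 1 / 2048, 8L,
                                      st$V, st$Q[["e"]])
  expect_lt(max(abs(phie - st$Q[["e"]])), 1e-8)
})

test_that("simulation is bit-identical per seed and diverges across seeds", {
  params <- fixture_params()
  pf <- params_from_gains(fixture_gains(), params)
  a <- simulate_ct_eeg(pf, duration = 5, seed = 42, n_channels = 2)
  b <- simulate_ct_eeg(pf, duration = 5, seed = 42, n_channels = 2)
  c <- simulate_ct_eeg(pf, duration = 5, seed = 43, n_channels = 2)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("params_from_gains realizes the requested operating point and gains", {
  params <- fixture_params()
  for (seed in c(2, 5)) {
    g <- draw_stable_gains(seed)
    pf <- params_from_gains(g, params,
                            firing = c(e = 8, i = 8, r = 18, s = 12))
    st <- ct_steady_state(pf)
    expect_equal(unname(st$Q), c(8, 8, 18, 12), tolerance = 1e-6)
    g2 <- gains_from_state(pf, st)
    for (p in c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs")) {
      expect_equal(g2[[p]], g[[p]], tolerance = 1e-8)
    }
  }
  expect_error(params_from_gains(fixture_gains(), params,
                                 firing = c(e = 8, i = 9, r = 18, s = 12)),
               "share")
})

test_that("trajectory inversion reproduces the prescribed composites", {
  params <- fixture_params()
  tr <- make_gain_trajectory(early = c(X = 0.95, Y = -0.3, Z = 0.02),
                             params = params)
  tab <- tr$table
  for (m in c(1, 30, 60)) {
    comp <- compose_gains(tab$G_ee[m], tab$G_ei[m], tab$G_ese[m],
                          tab$G_esre[m], tab$G_srs[m],
                          params$alpha, params$beta)
    expect_equal(unname(comp["X"]), tab$X[m], tolerance = 1e-10)
    expect_equal(unname(comp["Y"]), tab$Y[m], tolerance = 1e-10)
    expect_equal(unname(comp["Z"]), tab$Z[m], tolerance = 1e-10)
  }
  # directions of change mirror postictal recovery
  expect_lt(tab$X[60] - tab$X[1], 0)
  expect_gt(tab$Y[60] - tab$Y[1], 0)
  expect_gt(tab$Z[60] - tab$Z[1], 0)
  expect_lt(tab$G_ct[60] - tab$G_ct[1], 0)   # corticothalamic partial down
  expect_gt(tab$G_tc[60] - tab$G_tc[1], 0)   # thalamocortical partial up

  # flat request gives constant gains
  flat <- make_gain_trajectory(early = c(X = 0.7, Y = -0.1, Z = 0.08),
                               late = c(X = 0.7, Y = -0.1, Z = 0.08),
                               g_ei = c(-1.5, -1.5), g_ct = c(0.1, 0.1),
                               params = params)
  expect_lt(max(apply(flat$table[, -1], 2, function(v) diff(range(v)))),
            1e-12)
  # infeasible regimes are refused with the violated constraint named
  expect_error(make_gain_trajectory(early = c(X = 0.95, Y = 0.4, Z = 0.02),
                                    params = params), "infeasible")
})

test_that("cohorts have the stated cardinality, ledger and ROT distribution", {
  params <- fixture_params()
  cfg <- cohort_config(n_minutes = 3)
  co <- simulate_cohort(2, 3, config = cfg, seed = 7, params = params)
  expect_identical(length(co$recordings), 6L)
  expect_identical(nrow(co$ledger), 6L)
  expect_true(all(c("seizure_duration", "placement", "charge",
                    "etomidate_dose", "benzodiazepine", "rot_minute",
                    "seed") %in% names(co$ledger)))
  # reproducibility from (seed, subject, session)
  co2 <- simulate_cohort(2, 3, config = cfg, seed = 7, params = params)
  expect_identical(co$ledger, co2$ledger)
  expect_identical(co$recordings[[4]]$psds$power,
                   co2$recordings[[4]]$psds$power)

  # ROT distribution: truncated normal around 22.4
  set.seed(1)
  rots <- replicate(200, ctgain:::rtruncnorm1(cfg$rot_mean, cfg$rot_sd,
                                              cfg$rot_range))
  expect_lt(abs(mean(rots) - 22.4), 1.0)
  expect_true(all(rots >= 5 & rots <= 55))
})

test_that("PSD-level and EEG-level generation agree within Welch error", {
  params <- fixture_params()
  cfg <- cohort_config(n_minutes = 2)
  psd_co <- simulate_cohort(1, 1, config = cfg, seed = 3, params = params,
                            level = "psd")
  eeg_co <- simulate_cohort(1, 1, config = cfg, seed = 3, params = params,
                            level = "eeg")
  p1 <- psd_co$recordings[[1]]$psds
  p2 <- eeg_co$recordings[[1]]$psds
  # compare on the common grid in band-integrated relative power
  common <- intersect(round(p1$freqs, 6), round(p2$freqs, 6))
  i1 <- match(common, round(p1$freqs, 6)); i2 <- match(common, round(p2$freqs, 6))
  for (m in 1:2) {
    a <- band_integrate(common, normalize_psd(p1$power[i1, m], common))
    b <- band_integrate(common, normalize_psd(p2$power[i2, m], common))
    # allow a common offset: unit-integral normalization of a sharply
    # peaked spectrum is itself noisy (the lowest bins dominate the
    # integral), and the two pathways draw that noise independently
    lr <- log(a / b)
    lr <- lr - median(lr)
    # two independent 12-segment Welch estimates: ~4 sd margin per bin
    expect_lt(max(abs(lr)), 0.8)
    expect_lt(mean(abs(lr)), 0.25)
  }
})
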