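test_that("chi-square misfit: zero at identity, scale-invariant, hand value", {
  freqs <- ct_freq_grid()
  p <- ct_spectrum(fixture_gains(), fixture_params(), freqs)$power
  expect_identical(chi2_spectra(p, p, freqs), 0)
  # joint rescaling is absorbed by normalization
  expect_equal(chi2_spectra(5 * p, p, freqs), 0, tolerance = 1e-18)
  q <- p * exp(0.1 * sin(freqs))
  expect_equal(chi2_spectra(p, q, freqs), chi2_spectra(3 * p, 7 * q, freqs),
               tolerance = 1e-10)
  # 3-bin toy with unit weights and log differences (0.1, -0.2, 0.3)
  f3 <- c(1, 2, 3)
  obs <- exp(c(0.1, -0.2, 0.3))
  expect_equal(chi2_spectra(obs, c(1, 1, 1), f3, normalize = FALSE), 0.14,
               tolerance = 1e-12)
  expect_error(chi2_spectra(p[-1], p, freqs), "mismatch")
})

test_that("sampler contracts: determinism, bounds, MAP dominance", {
  params <- fixture_params()
  g <- fixture_gains()
  set.seed(31)
  obs <- ct_spectrum(g, params)$power * rgamma(223, 12, 12)
  freqs <- ct_freq_grid()

  f1 <- ctfit(obs, freqs, params = params, seed = 9, control = fast_control())
  f2 <- ctfit(obs, freqs, params = params, seed = 9, control = fast_control())
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$map, f2$map)
  expect_identical(f1$chi2, f2$chi2)

  b <- unclass(f1$bounds)[colnames(f1$samples), ]
  expect_true(all(t(f1$samples) >= b[, "low"]))
  expect_true(all(t(f1$samples) <= b[, "high"]))
  expect_true(f1$accept_rate > 0 && f1$accept_rate < 1)

  # chain initialized at the generating gains can only improve on them
  gvec <- as.numeric(g)
  names(gvec) <- c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs")
  f3 <- ctfit(obs, freqs, params = params, seed = 9, init = gvec,
              control = fast_control())
  expect_lte(f3$chi2, chi2_spectra(obs, ct_spectrum(g, params)$power, freqs))

  expect_error(ct_control(proposal_frac = 0), "positive")
})

test_that("MAP chi-square is non-increasing in chain length on noiseless input", {
  params <- fixture_params()
  obs <- ct_spectrum(fixture_gains(), params)$power
  freqs <- ct_freq_grid()
  chis <- vapply(c(500L, 2000L, 8000L), function(n) {
    ctfit(obs, freqs, params = params, seed = 5,
          control = ct_control(n_iter = n, burn_in = n %/% 4, thin = 5,
                               n_init = 256))$chi2
  }, numeric(1))
  expect_true(all(diff(chis) <= 1e-12))
  expect_lt(chis[3], 0.05)
})

test_that("fit summary, methods and tidy export are coherent", {
  params <- fixture_params()
  set.seed(17)
  obs <- ct_spectrum(fixture_gains(), params)$power * rgamma(223, 12, 12)
  fit <- ctfit(obs, ct_freq_grid(), params = params, seed = 2,
               control = fast_control())
  co <- coef(fit)
  expect_identical(unname(co["X"]), fit$gains$X)
  expect_identical(unname(co["Y"]), fit$gains$G_ct + fit$gains$G_tc)
  s <- summary(fit)
  expect_identical(rownames(s$quantiles),
                   c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs",
                     "X", "Y", "Z", "G_ct", "G_tc"))
  expect_true(all(s$quantiles[, 1] <= s$quantiles[, 3]))
  expect_identical(length(fitted(fit)), length(fit$freqs))
  expect_equal(residuals(fit), log(fit$observed) - log(fitted(fit)))
  expect_identical(predict(fit, c(5, 10)), ct_spectrum(fit$gains, params,
                                                       c(5, 10))$power)
})

test_that("recording fits run in temporal order with warm starts and missing minutes", {
  params <- fixture_params()
  # constant gains over 8 minutes, with minute 4 missing
  g <- fixture_gains()
  freqs <- ct_freq_grid()
  set.seed(23)
  pw <- sapply(1:8, function(m) ct_spectrum(g, params)$power *
                 rgamma(length(freqs), 12, 12))
  pw[, 4] <- NA
  psds <- structure(list(freqs = freqs, power = pw,
                         n_segments = c(rep(12L, 3), 0L, rep(12L, 4)),
                         missing = seq_len(8) == 4, recording_id = "rec"),
                    class = "ct_minute_psds")
  sr <- ctfit_recording(psds, params = params,
                        control = ct_control(n_iter = 20000, burn_in = 6000,
                                             n_init = 1024),
                        seed = 3)
  expect_identical(sum(sr$missing), 1L)
  expect_true(any(grepl("minute 3: missing", sr$log)))
  est <- sr$estimates
  expect_true(all(is.na(est[4, -1])))
  # stationarity: across-minute MAP scatter below within-chain spread
  # (averaged over the five gains; the two scales are of the same order
  # for any single well-identified parameter)
  ok <- !sr$missing
  ratios <- vapply(c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs"),
                   function(p) {
    map_sd <- sd(est[[p]][ok])
    chain_sd <- mean((est[[paste0(p, "_hi")]][ok] -
                        est[[paste0(p, "_lo")]][ok]) / (2 * 1.96))
    map_sd / chain_sd
  }, numeric(1))
  expect_lt(mean(ratios), 1)
  # tidy export
  long <- as.data.frame(sr)
  expect_identical(nrow(long), 8L * 10L)
  expect_true(all(c("recording_id", "minute", "parameter", "map_value",
                    "ci_low", "ci_high", "chi2", "n_samples") %in%
                    names(long)))
})

test_that("a step change in Y is localized to the correct minute", {
  params <- fixture_params()
  tr <- make_gain_trajectory(params = params)$table
  early <- unlist(tr[1, c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs")])
  late <- unlist(tr[60, c("G_ee", "G_ei", "G_ese", "G_esre", "G_srs")])
  freqs <- ct_freq_grid()
  set.seed(41)
  pw <- sapply(1:10, function(m) {
    gv <- if (m <= 5) early else late
    g <- ct_gains(gv[1], gv[2], gv[3], gv[4], gv[5], params$alpha,
                  params$beta)
    ct_spectrum(g, params)$power * rgamma(length(freqs), 12, 12)
  })
  psds <- structure(list(freqs = freqs, power = pw,
                         n_segments = rep(12L, 10),
                         missing = rep(FALSE, 10), recording_id = "step"),
                    class = "ct_minute_psds")
  sr <- ctfit_recording(psds, params = params, control = fast_control(),
                        seed = 7)
  y <- sr$estimates$Y
  y_early <- tr$Y[1]; y_late <- tr$Y[60]
  crossing <- which(abs(y - y_late) < abs(y - y_early))[1]
  expect_true(crossing >= 5 && crossing <= 7)  # 0-based minute 5 +- 1
})

test_that("an all-missing recording yields an empty series without error", {
  freqs <- ct_freq_grid()
  psds <- structure(list(freqs = freqs,
                         power = matrix(NA_real_, length(freqs), 3),
                         n_segments = integer(3), missing = rep(TRUE, 3),
                         recording_id = "void"),
                    class = "ct_minute_psds")
  sr <- ctfit_recording(psds, params = fixture_params(),
                        control = fast_control(), seed = 1)
  expect_true(all(sr$missing))
  expect_identical(length(sr$log), 3L)
})
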