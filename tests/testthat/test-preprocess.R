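test_that("band-pass filter rejects DC, keeps 10 Hz, attenuates 60 Hz", {
  fs <- 256
  t <- seq(0, 20, by = 1 / fs)[-1]
  make <- function(x) ct_eeg(matrix(x, nrow = 1), fs, "C3")

  dc <- bandpass_eeg(make(rep(5, length(t))))
  expect_lt(max(abs(dc$samples)), 5 * 1e-6)

  mid <- function(x) x[, round(length(t) * 0.25):round(length(t) * 0.75)]
  s10 <- bandpass_eeg(make(sin(2 * pi * 10 * t)))
  amp10 <- (max(mid(s10$samples)) - min(mid(s10$samples))) / 2
  expect_equal(amp10, 1, tolerance = 0.05)

  s60 <- bandpass_eeg(make(sin(2 * pi * 60 * t)))
  amp60 <- (max(mid(s60$samples)) - min(mid(s60$samples))) / 2
  expect_lt(amp60, amp10)

  expect_error(bandpass_eeg(ct_eeg(matrix(0, 1, 100), 80, "C3")), "too low")
})

test_that("artifact annotation flags injected windows and bad channels", {
  eeg <- fixture_noise_eeg(n_channels = 4, duration = 120, sd = 10, seed = 2)
  clean <- annotate_artifacts(eeg)
  expect_identical(nrow(clean$annotations$bad_windows), 0L)
  expect_identical(clean$annotations$bad_channels, character(0))

  # 10x spikes in known windows of channel 2
  spiked <- eeg
  for (w in c(3, 7, 11)) {
    idx <- ((w - 1) * 5 * 256 + 1):(w * 5 * 256)
    spiked$samples[2, idx] <- spiked$samples[2, idx] * 10
  }
  ann <- annotate_artifacts(spiked)
  expect_identical(ann$annotations$bad_windows$start_s, c(10, 30, 50))
  expect_identical(ann$annotations$bad_channels, character(0))

  # 60% corrupted windows -> channel marked bad, windows not globally lost
  bad <- eeg
  n_win <- ncol(eeg$samples) %/% (5 * 256)
  for (w in seq_len(ceiling(0.6 * n_win))) {
    idx <- ((w - 1) * 5 * 256 + 1):(w * 5 * 256)
    bad$samples[1, idx] <- 500
  }
  ann2 <- annotate_artifacts(bad)
  expect_identical(ann2$annotations$bad_channels, "Fp1")
  expect_identical(nrow(ann2$annotations$bad_windows), 0L)

  flat <- eeg; flat$samples[3, ] <- 0.001
  ann3 <- annotate_artifacts(flat)
  expect_identical(ann3$annotations$bad_channels, "F3")

  allbad <- eeg; allbad$samples[] <- 1e3
  expect_error(annotate_artifacts(allbad), "all channels")
})

test_that("minute PSDs: segment accounting, white-noise flatness, peak bin", {
  eeg <- fixture_noise_eeg(n_channels = 3, duration = 60, sd = 1, seed = 3)
  mp <- minute_psds(eeg)
  expect_identical(ncol(mp$power), 1L)
  expect_identical(mp$n_segments, 12L)
  expect_false(any(mp$missing))
  expect_identical(mp$freqs[1], 0.6)
  expect_identical(mp$freqs[length(mp$freqs)], 45)

  # unit-variance white noise is flat across bands
  low <- mean(mp$power[mp$freqs >= 1 & mp$freqs <= 10, 1])
  high <- mean(mp$power[mp$freqs >= 20 & mp$freqs <= 30, 1])
  expect_gt(low / high, 0.8)
  expect_lt(low / high, 1.2)

  # pure sinusoid concentrates in its 0.2-Hz bin
  t <- seq(1 / 256, 60, by = 1 / 256)
  tone <- ct_eeg(matrix(sin(2 * pi * 10 * t), 1), 256, "C3")
  mt <- minute_psds(tone)
  expect_equal(mt$freqs[which.max(mt$power[, 1])], 10)
})

test_that("clean-segment counts are conserved and minutes can go missing", {
  eeg <- fixture_noise_eeg(n_channels = 2, duration = 180, sd = 10, seed = 4)
  # corrupt all of minute 2 (windows 13..24) on one channel
  for (w in 13:24) {
    idx <- ((w - 1) * 5 * 256 + 1):(w * 5 * 256)
    eeg$samples[1, idx] <- 400
  }
  ann <- annotate_artifacts(eeg)
  mp <- minute_psds(ann)
  expect_identical(mp$n_segments, c(12L, 0L, 12L))
  expect_identical(mp$missing, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(mp$power[, 2])))
  # conservation: clean + rejected = total windows
  expect_identical(sum(mp$n_segments) + nrow(ann$annotations$bad_windows),
                   36L)
})

test_that("channel-median is invariant to channel order", {
  eeg <- fixture_noise_eeg(n_channels = 4, duration = 60, sd = 5, seed = 5)
  mp1 <- minute_psds(eeg)
  perm <- c(3, 1, 4, 2)
  eeg2 <- ct_eeg(eeg$samples[perm, ], eeg$fs, eeg$channel_labels[perm])
  mp2 <- minute_psds(eeg2)
  expect_identical(mp1$power, mp2$power)
})

test_that("baseline PSD equals the minute average for stationary input", {
  eeg <- fixture_noise_eeg(n_channels = 2, duration = 300, sd = 5, seed = 6)
  bl <- baseline_psd(eeg)
  expect_identical(bl$n_segments, 60L)
  mp <- minute_psds(eeg)
  avg <- rowMeans(mp$power)
  # same data, different grouping: agreement within sampling error
  expect_lt(median(abs(bl$power / avg - 1)), 0.2)

  # single clean minute: baseline equals that minute's PSD exactly
  one <- fixture_noise_eeg(n_channels = 2, duration = 60, sd = 5, seed = 7)
  expect_identical(baseline_psd(one)$power, minute_psds(one)$power[, 1])

  none <- fixture_noise_eeg(duration = 10, seed = 8)
  none$annotations$bad_windows <- data.frame(start_s = 0, end_s = 10)
  expect_error(baseline_psd(none), "no clean segments")
})

test_that("minute-PSD tables round-trip", {
  eeg <- fixture_noise_eeg(n_channels = 2, duration = 120, sd = 5, seed = 9)
  mp <- minute_psds(eeg, recording_id = "recA")
  tmp <- tempfile(fileext = ".tsv")
  write_psd_table(mp, tmp)
  back <- read_psd_table(tmp)
  expect_identical(names(back), "recA")
  expect_equal(back$recA$power, mp$power, tolerance = 1e-14)
  expect_identical(back$recA$n_segments, mp$n_segments)
})
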