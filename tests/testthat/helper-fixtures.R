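# shared fixtures: built in code, deterministic

fixture_params <- function() ct_default_params()

# the mid-regime baseline gain set used throughout the tests
fixture_gains <- function(params = fixture_params()) {
  ct_gains(5.4, -7, 5.6, -2.8, -0.6, params$alpha, params$beta)
}

# single random spectrally stable gain set (see sample_stable_gains)
draw_stable_gains <- function(seed, params = fixture_params()) {
  sample_stable_gains(1, seed = seed, params = params)[[1]]
}

# white-noise multichannel EEG recording (for preprocess tests)
fixture_noise_eeg <- function(n_channels = 4, duration = 60, fs = 256,
                              sd = 10, seed = 1) {
  set.seed(seed)
  ct_eeg(matrix(rnorm(n_channels * duration * fs, sd = sd),
                nrow = n_channels),
         fs = fs,
         channel_labels = c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3",
                            "P4")[seq_len(n_channels)])
}

# band-integrated power per 1-Hz bin (for oracle comparisons)
band_integrate <- function(freqs, power, edges = seq(0.5, 45, 1)) {
  bins <- cut(freqs, edges, include.lowest = TRUE)
  tapply(power, bins, sum)
}

# quick reduced-chain control for tests that exercise plumbing, not
# convergence
fast_control <- function(...) {
  ct_control(n_iter = 4000L, burn_in = 1200L, thin = 5L, n_init = 1024L, ...)
}
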