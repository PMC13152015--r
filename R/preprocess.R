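#' Band-pass filter an EEG recording
#'
#' First-order Butterworth band-pass per channel. Applied forward-backward
#' (zero-phase, doubling the effective order) by default; a single forward
#' pass is available since the acquisition convention leaves phase handling
#' open. The channel mean (DC) is removed first.
#'
#' @param recording a `ct_eeg`.
#' @param f_lo,f_hi band edges (Hz).
#' @param zero_phase forward-backward filtering if `TRUE` (default).
#' @return the filtered `ct_eeg`.
#' @export
bandpass_eeg <- function(recording, f_lo = 0.5, f_hi = 45,
                         zero_phase = TRUE) {
  stopifnot(inherits(recording, "ct_eeg"))
  fs <- recording$fs
  if (fs <= 2 * f_hi) stop("sampling rate too low for the requested band")
  bf <- signal::butter(1, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- recording$samples
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ] - mean(x[ch, ])
    x[ch, ] <- if (zero_phase) signal::filtfilt(bf, v) else
      signal::filter(bf, v)
  }
  recording$samples <- x
  recording$filter <- list(b = as.numeric(bf$b), a = as.numeric(bf$a),
                           f_lo = f_lo, f_hi = f_hi,
                           passes = if (zero_phase) 2L else 1L)
  recording
}

# squared magnitude of the digital filter at the given frequencies,
# including the number of passes (2 for zero-phase filtering)
filter_power_response <- function(filt, freqs, fs) {
  H <- vapply(freqs, function(f) {
    z <- exp(-2i * pi * f / fs * (seq_along(filt$b) - 1))
    num <- sum(filt$b * z)
    z2 <- exp(-2i * pi * f / fs * (seq_along(filt$a) - 1))
    Mod(num / sum(filt$a * z2))
  }, numeric(1))
  H^(2 * filt$passes)
}

#' Automated artifact annotation
#'
#' Surrogate for visual artifact inspection: marks 5-s windows whose
#' peak amplitude exceeds `amp_thresh` or whose standard deviation falls
#' below `flat_thresh` (flatline / detached electrode) in any usable
#' channel. Channels in which more than `bad_channel_frac` of windows are
#' individually rejected are marked bad and excluded from both the global
#' window rejection and all downstream spectra.
#'
#' @param recording a filtered `ct_eeg`.
#' @param amp_thresh peak absolute amplitude threshold (uV).
#' @param flat_thresh flatline standard-deviation threshold (uV).
#' @param window_s window length (s); 5 s matches the Welch segments.
#' @param bad_channel_frac fraction of rejected windows above which a
#'   channel is marked bad.
#' @return the `ct_eeg` with `annotations$bad_channels` and
#'   `annotations$bad_windows` filled in.
#' @export
annotate_artifacts <- function(recording, amp_thresh = 200,
                               flat_thresh = 0.05, window_s = 5,
                               bad_channel_frac = 0.5) {
  stopifnot(inherits(recording, "ct_eeg"))
  fs <- recording$fs
  wlen <- round(window_s * fs)
  n_win <- ncol(recording$samples) %/% wlen
  if (n_win == 0) stop("recording shorter than one artifact window")
  nch <- nrow(recording$samples)
  flag <- matrix(FALSE, nch, n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    seg <- recording$samples[, idx, drop = FALSE]
    flag[, w] <- apply(seg, 1, function(v) {
      max(abs(v)) > amp_thresh || sd(v) < flat_thresh
    })
  }
  frac_bad <- rowMeans(flag)
  bad_channels <- recording$channel_labels[frac_bad > bad_channel_frac]
  if (length(bad_channels) == nch) stop("all channels marked bad")
  good <- !(recording$channel_labels %in% bad_channels)
  win_bad <- colSums(flag[good, , drop = FALSE]) > 0
  bw <- data.frame(start_s = (which(win_bad) - 1) * window_s,
                   end_s = which(win_bad) * window_s)
  recording$annotations <- list(bad_channels = bad_channels,
                                bad_windows = bw)
  recording
}

# Hann-window periodogram of one segment, one-sided density scaling
segment_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
  xw <- (x - mean(x)) * w
  X <- fft(xw)
  nf <- n %/% 2
  p <- (Mod(X[2:(nf + 1)])^2) * 2 / (fs * sum(w^2))
  freqs <- (1:nf) * fs / n
  list(freqs = freqs, power = p)
}

clean_window_index <- function(recording, window_s = 5) {
  wlen <- round(window_s * recording$fs)
  n_win <- ncol(recording$samples) %/% wlen
  bad <- rep(FALSE, n_win)
  bw <- recording$annotations$bad_windows
  if (!is.null(bw) && nrow(bw) > 0) {
    ws <- (seq_len(n_win) - 1) * window_s
    for (j in seq_len(nrow(bw))) {
      bad <- bad | (ws < bw$end_s[j] - 1e-9 & ws + window_s > bw$start_s[j] + 1e-9)
    }
  }
  list(n_win = n_win, wlen = wlen, clean = which(!bad))
}

#' Per-minute channel-median Welch spectra
#'
#' For every channel, Welch PSDs are computed on non-overlapping
#' artifact-free 5-s segments (the 5-s segment is the Welch block, Hann
#' window), averaged within each postictal minute, and the channel median
#' is taken per frequency. Minutes without clean segments are marked
#' missing. Minute indices are 0-based internally (minute 0 starts at the
#' recording start, taken as seizure termination); reports print 1-based.
#'
#' When the recording was filtered with [bandpass_eeg()], the PSDs are
#' divided by the filter's known squared magnitude response (both passes),
#' so that downstream spectral fits see the underlying signal spectrum
#' rather than the acquisition filter's shoulder.
#'
#' @param recording an annotated, filtered `ct_eeg`.
#' @param window_s Welch segment length (s).
#' @param band keep frequencies within this band (Hz).
#' @param recording_id identifier carried into tables.
#' @return a `ct_minute_psds` object: `freqs`, `power` (frequency x minute
#'   matrix, `NA` columns for missing minutes), `n_segments` per minute,
#'   `missing` mask and `recording_id`.
#' @export
minute_psds <- function(recording, window_s = 5, band = c(0.5, 45),
                        recording_id = "rec") {
  stopifnot(inherits(recording, "ct_eeg"))
  fs <- recording$fs
  ci <- clean_window_index(recording, window_s)
  good_ch <- which(!(recording$channel_labels %in%
                       recording$annotations$bad_channels))
  wins_per_min <- round(60 / window_s)
  n_min <- ceiling(ci$n_win / wins_per_min)
  ref <- segment_psd(recording$samples[good_ch[1], seq_len(ci$wlen)], fs)
  keep <- which(ref$freqs >= band[1] - 1e-9 & ref$freqs <= band[2] + 1e-9)
  freqs <- ref$freqs[keep]
  power <- matrix(NA_real_, length(freqs), n_min)
  n_segments <- integer(n_min)
  for (m in seq_len(n_min) - 1L) {
    wins <- intersect(ci$clean, (m * wins_per_min + 1):((m + 1) * wins_per_min))
    n_segments[m + 1L] <- length(wins)
    if (length(wins) == 0) next
    chans <- matrix(0, length(freqs), length(good_ch))
    for (jc in seq_along(good_ch)) {
      acc <- numeric(length(freqs))
      for (w in wins) {
        idx <- ((w - 1) * ci$wlen + 1):(w * ci$wlen)
        acc <- acc + segment_psd(recording$samples[good_ch[jc], idx], fs)$power[keep]
      }
      chans[, jc] <- acc / length(wins)
    }
    power[, m + 1L] <- apply(chans, 1, median)
  }
  if (!is.null(recording$filter)) {
    power <- power / filter_power_response(recording$filter, freqs, fs)
  }
  structure(list(freqs = freqs, power = power, n_segments = n_segments,
                 missing = n_segments == 0L, recording_id = recording_id),
            class = "ct_minute_psds")
}

#' @export
print.ct_minute_psds <- function(x, ...) {
  cat(sprintf(
    "Minute-wise channel-median PSDs '%s': %d minute(s), %d missing, %d frequencies (%.1f-%.1f Hz)\n",
    x$recording_id, ncol(x$power), sum(x$missing), length(x$freqs),
    min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Averaged baseline spectrum
#'
#' Segment-averaged, channel-median PSD over the whole recording (the
#' eyes-closed baseline convention), using every clean 5-s segment.
#'
#' @inheritParams minute_psds
#' @return list with `freqs`, `power`, `n_segments`.
#' @export
baseline_psd <- function(recording, window_s = 5, band = c(0.5, 45)) {
  stopifnot(inherits(recording, "ct_eeg"))
  fs <- recording$fs
  ci <- clean_window_index(recording, window_s)
  if (length(ci$clean) == 0) stop("no clean segments in baseline recording")
  good_ch <- which(!(recording$channel_labels %in%
                       recording$annotations$bad_channels))
  ref <- segment_psd(recording$samples[good_ch[1], seq_len(ci$wlen)], fs)
  keep <- which(ref$freqs >= band[1] - 1e-9 & ref$freqs <= band[2] + 1e-9)
  freqs <- ref$freqs[keep]
  chans <- matrix(0, length(freqs), length(good_ch))
  for (jc in seq_along(good_ch)) {
    acc <- numeric(length(freqs))
    for (w in ci$clean) {
      idx <- ((w - 1) * ci$wlen + 1):(w * ci$wlen)
      acc <- acc + segment_psd(recording$samples[good_ch[jc], idx], fs)$power[keep]
    }
    chans[, jc] <- acc / length(ci$clean)
  }
  power <- apply(chans, 1, median)
  if (!is.null(recording$filter)) {
    power <- power / filter_power_response(recording$filter, freqs, fs)
  }
  list(freqs = freqs, power = power, n_segments = length(ci$clean))
}

#' Read / write tidy minute-PSD tables
#'
#' Long-format delimited table with columns `recording_id`, `minute`
#' (0-based), `freq_hz`, `power`, `n_segments`; missing minutes appear with
#' `NA` power and `n_segments = 0`.
#'
#' @param x a `ct_minute_psds` object (or list of them).
#' @param path file path.
#' @return `read_psd_table` returns a list of `ct_minute_psds`.
#' @export
write_psd_table <- function(x, path) {
  if (inherits(x, "ct_minute_psds")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(mp) {
    do.call(rbind, lapply(seq_len(ncol(mp$power)), function(m) {
      data.frame(recording_id = mp$recording_id, minute = m - 1L,
                 freq_hz = mp$freqs, power = mp$power[, m],
                 n_segments = mp$n_segments[m])
    }))
  }))
  write.table(format(rows, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd_table
#' @export
read_psd_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  lapply(split(df, df$recording_id), function(d) {
    minutes <- sort(unique(d$minute))
    freqs <- sort(unique(d$freq_hz))
    power <- matrix(NA_real_, length(freqs), length(minutes))
    n_segments <- integer(length(minutes))
    for (j in seq_along(minutes)) {
      dm <- d[d$minute == minutes[j], ]
      dm <- dm[order(dm$freq_hz), ]
      power[, j] <- dm$power
      n_segments[j] <- dm$n_segments[1]
    }
    structure(list(freqs = freqs, power = power, n_segments = n_segments,
                   missing = n_segments == 0L,
                   recording_id = d$recording_id[1]),
              class = "ct_minute_psds")
  })
}
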