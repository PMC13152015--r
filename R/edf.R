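# Minimal EDF (European Data Format) codec: 16-bit integer records with
# per-signal physical scaling, 1-s data records. Covers the subset of the
# format the pipeline needs (continuous multichannel EEG, equal sampling
# rates); EDF+ annotation channels are not written.

pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write an EEG recording to EDF
#'
#' @param recording a `ct_eeg`.
#' @param path output path.
#' @param patient,recording_info free-text EDF header fields.
#' @return `path` invisibly.
#' @export
write_edf <- function(recording, path, patient = "X", recording_info = "X") {
  stopifnot(inherits(recording, "ct_eeg"))
  x <- recording$samples
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  ns <- nrow(x)
  spr <- as.integer(round(fs))            # 1-s records
  n_rec <- ncol(x) %/% spr
  if (n_rec == 0) stop("recording shorter than one EDF record")
  x <- x[, seq_len(n_rec * spr), drop = FALSE]

  # the header stores the physical range as text; use the value as written
  # so the codec's only loss is the 16-bit quantization itself
  phys_max <- as.numeric(sprintf("%.6g", max(1e-6, max(abs(x)))))
  dig <- 32767
  scale <- phys_max / dig

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(patient, 80), pad(recording_info, 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(as.character(256 * (ns + 1)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, n) {
    writeChar(paste0(vapply(vals, pad, "", n = n), collapse = ""), con,
              eos = NULL)
  }
  field(recording$channel_labels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(rep(sprintf("%.6g", -phys_max), ns), 8)
  field(rep(sprintf("%.6g", phys_max), ns), 8)
  field(rep("-32767", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("BP 0.5-45Hz", ns), 80)
  field(rep(as.character(spr), ns), 8)
  field(rep("", ns), 32)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig_vals <- as.integer(pmin(dig, pmax(-dig, round(x[ch, idx] / scale))))
      writeBin(dig_vals, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Maps the header (sampling rate, channel labels) losslessly into a
#' `ct_eeg`; samples are rescaled to physical units. Requesting channels
#' by 10-20 label selects a subset.
#'
#' @param path EDF file.
#' @param channels optional character vector of channel labels to keep.
#' @return a `ct_eeg`.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    v <- readChar(con, n, useBytes = TRUE)
    if (length(v) == 0 || nchar(v, type = "bytes") < n) {
      stop("malformed EDF: truncated header in ", path)
    }
    trimws(v)
  }
  version <- rd(8)
  if (version != "0") stop("malformed EDF: version field is '", version, "'")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1) {
    stop("malformed EDF: ns = ", ns, ", records = ", n_rec)
  }
  if (hdr_bytes != 256 * (ns + 1)) {
    stop("malformed EDF: header bytes field ", hdr_bytes,
         " does not match ns = ", ns)
  }
  fields <- function(n) vapply(seq_len(ns), function(i) rd(n), "")
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)

  want <- seq_len(ns)
  if (!is.null(channels)) {
    want <- match(channels, labels)
    if (any(is.na(want))) {
      stop("channel label(s) not in file: ",
           paste(channels[is.na(want)], collapse = ", "),
           " (available: ", paste(labels, collapse = ", "), ")")
    }
  }
  samples <- matrix(0, length(want), n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[ch]) stop("malformed EDF: truncated data record ", r)
      j <- match(ch, want)
      if (!is.na(j)) {
        idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
        samples[j, idx] <- phys_min[ch] + (raw - dig_min[ch]) * scale[ch]
      }
    }
  }
  ct_eeg(samples, fs = spr[1] / rec_dur, channel_labels = labels[want])
}
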