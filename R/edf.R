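# Minimal European Data Format (EDF) support: fixed-width ASCII header,
# 16-bit little-endian sample records, linear digital-to-physical scaling.
# Covers plain continuous EDF only (no EDF+ annotation streams).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(raw, what) {
  out <- suppressWarnings(as.numeric(trimws(raw)))
  if (any(!is.finite(out))) {
    stop(sprintf("not a valid EDF file: field '%s' is not numeric ('%s')",
                 what, trimws(raw[!is.finite(out)][1L])), call. = FALSE)
  }
  out
}

#' Read one channel of an EDF file
#'
#' Parses the plain-EDF header and extracts the named channel, applying
#' the file's digital-to-physical calibration. The sampling rate is
#' taken from the channel's samples-per-record and the record duration.
#'
#' @param path Path to an EDF file.
#' @param channel Channel label to extract (e.g. \code{"C3-O1"}).
#' @param subject_id Subject id for the returned recording; defaults to
#'   the file's local patient identification field.
#' @return An [eeg_recording()].
#' @export
read_recording_edf <- function(path, channel, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256L) {
    stop(sprintf("%s: not an EDF file (header shorter than 256 bytes)", path),
         call. = FALSE)
  }
  fld <- function(from, len) substr(fixed, from, from + len - 1L)
  version <- trimws(fld(1L, 8L))
  if (version != "0") {
    stop(sprintf("%s: not an EDF file (version field '%s', expected '0')",
                 path, version), call. = FALSE)
  }
  patient <- trimws(fld(9L, 80L))
  n_records <- edf_num(fld(237L, 8L), "number of data records")
  rec_dur <- edf_num(fld(245L, 8L), "data record duration")
  ns <- as.integer(edf_num(fld(253L, 4L), "number of signals"))
  if (ns < 1L) stop(sprintf("%s: EDF file declares no signals", path), call. = FALSE)

  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256L * ns) {
    stop(sprintf("%s: truncated EDF signal header", path), call. = FALSE)
  }
  block <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      substr(sig_hdr, offset * ns + (i - 1L) * width + 1L,
             offset * ns + i * width)
    }, character(1))
  }
  labels <- trimws(block(0L, 16L))
  phys_min <- edf_num(block(16L + 80L + 8L, 8L), "physical minimum")
  phys_max <- edf_num(block(16L + 80L + 8L + 8L, 8L), "physical maximum")
  dig_min <- edf_num(block(16L + 80L + 8L + 16L, 8L), "digital minimum")
  dig_max <- edf_num(block(16L + 80L + 8L + 24L, 8L), "digital maximum")
  spr <- as.integer(edf_num(block(16L + 80L + 8L + 32L + 80L, 8L),
                            "samples per record"))

  idx <- match(channel, labels)
  if (is.na(idx)) {
    stop(sprintf("channel '%s' not found in %s; available: %s",
                 channel, path, paste(labels, collapse = ", ")), call. = FALSE)
  }

  rec_len <- sum(spr)
  raw <- readBin(con, integer(), n = rec_len * n_records, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < rec_len * n_records) {
    stop(sprintf("%s: EDF data section shorter than the header declares", path),
         call. = FALSE)
  }
  offsets <- c(0L, cumsum(spr))
  take <- unlist(lapply(seq_len(n_records) - 1L, function(r) {
    r * rec_len + offsets[idx] + seq_len(spr[idx])
  }), use.names = FALSE)
  dig <- raw[take]
  gain <- (phys_max[idx] - phys_min[idx]) / (dig_max[idx] - dig_min[idx])
  phys <- (dig - dig_min[idx]) * gain + phys_min[idx]
  eeg_recording(
    subject_id = subject_id %||% (if (nzchar(patient)) patient else "unknown"),
    samples = phys, sample_rate = spr[idx] / rec_dur, channel = channel
  )
}

#' Write a recording as a single-channel EDF file
#'
#' Uses 1 s data records (so the sampling rate must be a whole number of
#' samples per second) and the full 16-bit digital range spanning the
#' signal's amplitude extremes. Values round-trip through
#' [read_recording_edf()] to 16-bit quantization accuracy.
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @param physical_dim Physical dimension string (default \code{"uV"}).
#' @return The path, invisibly.
#' @export
write_recording_edf <- function(recording, path, physical_dim = "uV") {
  stopifnot(inherits(recording, "eeg_recording"))
  spr <- recording$sample_rate
  if (abs(spr - round(spr)) > 1e-9) {
    stop("EDF writer requires an integer number of samples per second", call. = FALSE)
  }
  spr <- as.integer(round(spr))
  x <- recording$samples
  n_records <- length(x) %/% spr
  if (n_records < 1L) stop("recording shorter than one 1 s EDF record", call. = FALSE)
  if (n_records * spr < length(x)) {
    warning(sprintf("dropping %d trailing samples (partial EDF record)",
                    length(x) - n_records * spr))
    x <- x[seq_len(n_records * spr)]
  }
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ <= pmin_) { pmin_ <- pmin_ - 1; pmax_ <- pmax_ + 1 }
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(recording$subject_id, 80L),
    edf_pad("drowseeg export", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * 2L, 8L),           # header bytes: fixed + 1 signal block
    edf_pad("", 44L),
    edf_pad(n_records, 8L), edf_pad("1", 8L), edf_pad("1", 4L),
    # signal header block (one signal)
    edf_pad(recording$channel, 16L), edf_pad("synthetic", 80L),
    edf_pad(physical_dim, 8L),
    edf_pad(formatC(pmin_, format = "g", digits = 6), 8L),
    edf_pad(formatC(pmax_, format = "g", digits = 6), 8L),
    edf_pad(dmin, 8L), edf_pad(dmax, 8L),
    edf_pad("BP 0.5-50Hz", 80L), edf_pad(spr, 8L), edf_pad("", 32L)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}
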