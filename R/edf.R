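# Minimal EDF (European Data Format) reader/writer.
#
# Plain EDF only: ASCII header (256 bytes + 256 per signal), data records
# of 16-bit little-endian integers, one shared sampling rate across the
# channels used here.  EDF+ annotation channels are not written; files with
# a different sampling rate per channel are rejected as an unsupported
# dialect.  No R EDF package is available, and the format is simple enough
# that a direct implementation is preferable to an external dependency.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with physical unit µV, one data record per second and a
#' symmetric physical range per channel chosen from the data (so the
#' quantization step is `range/65535`).  The last record is zero-padded
#' when the sample count is not a whole number of records.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / fs)
  phys_max <- pmax(apply(abs(rec$data), 1, max), 1)
  phys_max <- signif(phys_max * 1.0001, 6)   # headroom so data stay in range

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X synthetic mouseEEG", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4),
    paste(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),          # transducer
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),          # prefilter
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  # re-parse the written physical ranges so quantization matches the reader
  pm_written <- as.numeric(vapply(phys_max, edf_num, "", width = 8))
  scale <- (2 * pm_written) / 65535
  padded <- matrix(0, nrow = ns, ncol = n_rec * fs)
  padded[, seq_len(n)] <- rec$data
  dig <- matrix(0L, nrow = ns, ncol = n_rec * fs)
  for (ch in seq_len(ns)) {
    d <- round((padded[ch, ] + pm_written[ch]) / scale[ch]) - 32768
    dig[ch, ] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  out <- integer(ns * n_rec * fs)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      out[pos + seq_len(fs)] <- dig[ch, cols]
      pos <- pos + fs
    }
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the plain-EDF header, checks the file length against the declared
#' record count (a truncated file is a format error and returns no partial
#' object), and rescales the 16-bit samples to physical units using the
#' per-channel physical/digital ranges.
#'
#' @param path EDF file path.
#' @return an [eeg_recording()] (without events; recover them with
#'   [extract_events()]).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sz <- file.size(path)
  if (sz < 256) stop("corrupt EDF header (file too short)", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  grab <- function(s, from, len) substr(s, from, from + len - 1)
  num <- function(x) suppressWarnings(as.numeric(trimws(x)))
  header_bytes <- num(grab(fixed, 185, 8))
  n_rec <- num(grab(fixed, 237, 8))
  rec_dur <- num(grab(fixed, 245, 8))
  ns <- num(grab(fixed, 253, 4))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1 || rec_dur <= 0)
    stop("corrupt EDF header", call. = FALSE)
  if (sz < header_bytes)
    stop("corrupt EDF header (declared size exceeds file)", call. = FALSE)
  sig_hdr <- readChar(con, header_bytes - 256, useBytes = TRUE)
  fld <- function(width, k) {   # k-th field block of given width, per signal
    off <- k
    vapply(seq_len(ns), function(i)
      grab(sig_hdr, off + (i - 1) * width + 1, width), "")
  }
  pos <- 0
  labels <- trimws(fld(16, pos)); pos <- pos + 16 * ns
  pos <- pos + 80 * ns                       # transducer
  pos <- pos + 8 * ns                        # physical dimension
  phys_min <- num(fld(8, pos)); pos <- pos + 8 * ns
  phys_max <- num(fld(8, pos)); pos <- pos + 8 * ns
  dig_min <- num(fld(8, pos)); pos <- pos + 8 * ns
  dig_max <- num(fld(8, pos)); pos <- pos + 8 * ns
  pos <- pos + 80 * ns                       # prefilter
  spr <- num(fld(8, pos))                    # samples per record
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)))
    stop("corrupt EDF header (signal fields)", call. = FALSE)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates across channels: unsupported EDF dialect",
         call. = FALSE)
  spr <- spr[1]
  expected <- header_bytes + n_rec * ns * spr * 2
  if (sz < expected)
    stop("truncated EDF file: expected ", expected, " bytes, found ", sz,
         call. = FALSE)
  raw <- readBin(con, integer(), n = n_rec * ns * spr, size = 2,
                 signed = TRUE, endian = "little")
  # records x (channel-major blocks of spr samples)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr)
  arr <- array(raw, dim = c(spr, ns, n_rec))
  for (ch in seq_len(ns)) {
    gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    data[ch, ] <- (as.vector(arr[, ch, ]) - dig_min[ch]) * gain + phys_min[ch]
  }
  eeg_recording(data, fs = spr / rec_dur, channel_labels = labels,
                meta = list(path = path))
}
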