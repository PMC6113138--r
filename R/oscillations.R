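#' Basal band power
#'
#' Power of a frequency band outside the auditory-evoked response,
#' quantified in a 400 ms bin placed `offset_s` (default 3 s) before each
#' click presentation, averaged over layers, bin samples, trials and
#' channels.  Each bin is transformed with enough surrounding context that
#' every coefficient inside the bin has full wavelet support; events
#' whose bin (plus context) does not fit in the recording are skipped with
#' a message.
#'
#' @param rec an [eeg_recording()].
#' @param events an [event_table()] of the reference clicks (typically the
#'   `click1` events).
#' @param band a [morlet_spec()] ([gamma_band()] or [theta_band()]).
#' @param bin_ms bin length (ms).
#' @param offset_s bin placement before the event onset (s).
#' @return scalar basal power in µV².
#' @export
basal_power <- function(rec, events = rec$events, band = gamma_band(),
                        bin_ms = 400, offset_s = 3) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "event_table"))
  if (!nrow(events)) stop("no events supplied", call. = FALSE)
  fs <- rec$fs
  pad <- attr(morlet_wavelet(band$f_min, fs, band$c), "half")
  bin_samp <- round(bin_ms / 1000 * fs)
  chs <- signal_channels(rec)
  n <- ncol(rec$data)
  s0 <- events$onset_sample - round(offset_s * fs)      # 0-based bin start
  ok <- (s0 - pad) >= 0 & (s0 + bin_samp + pad) <= n
  if (!any(ok))
    stop("basal bin (plus wavelet context) outside the recording for every event",
         call. = FALSE)
  if (any(!ok))
    message(sprintf("basal_power: skipped %d event(s) without context",
                    sum(!ok)))
  total <- 0; count <- 0
  kern <- cwt_kernels(band, fs, bin_samp + 2L * pad)
  bin_cols <- (pad + 1L):(pad + bin_samp)
  for (e in which(ok)) {
    idx <- (s0[e] - pad + 1L):(s0[e] + bin_samp + pad)  # 1-based
    for (ch in chs) {
      W <- cwt_vector(rec$data[ch, idx], band, fs, kernels = kern)
      total <- total + sum(Mod(W[, bin_cols])^2)
      count <- count + length(band$freqs) * bin_samp
    }
  }
  total / count
}

#' Evoked band power anchored to the P1 peak
#'
#' Total band power in a window around the measured P1 latency minus the
#' basal power: gamma uses P1 +/- 25 ms, theta uses 20 ms before to 180 ms
#' after P1.  Anchoring the window to each animal's P1 peak absorbs
#' individual latency variation.  The result can be negative (total below
#' basal), which is retained.
#'
#' @param epochs an `epoch_set` wide enough that the window (plus wavelet
#'   support at `band$f_min`) is valid.
#' @param band a [morlet_spec()].
#' @param basal scalar basal power from [basal_power()] for the same band.
#' @param p1_latency_ms measured P1 latency; when `NA`, falls back to
#'   `default_p1_ms` with a warning.
#' @param window_pre_ms,window_post_ms window half-extents around P1 (ms).
#' @param default_p1_ms fallback P1 latency.
#' @return list with `total`, `basal` and `evoked` (µV²).
#' @export
evoked_band_power <- function(epochs, band, basal,
                              p1_latency_ms,
                              window_pre_ms = 25, window_post_ms = 25,
                              default_p1_ms = 20) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "morlet_spec"))
  if (is.na(p1_latency_ms)) {
    warning("missing P1 latency; using the configured default of ",
            default_p1_ms, " ms")
    p1_latency_ms <- default_p1_ms
  }
  win <- c(p1_latency_ms - window_pre_ms, p1_latency_ms + window_post_ms)
  tfr <- morlet_transform(epochs, band, times_keep_ms = win)
  total <- tfr_band_power(tfr)
  list(total = total, basal = basal, evoked = total - basal)
}

# Mean band power over a whole recording, per the wavelet's analytic
# frequency response: for the unit-energy Morlet, |psi_hat(nu)|^2 =
# 2*sqrt(pi)*sigma_t * exp(-4*pi^2*sigma_t^2*(nu-f)^2).  One FFT per
# channel gives the periodogram, which is then weighted by the layer
# responses; equivalent to the time-domain mean of |coef|^2 up to
# truncation and boundary terms.
whole_recording_band_powers <- function(rec, bands) {
  fs <- rec$fs
  n <- ncol(rec$data)
  nu <- (seq_len(n) - 1) * fs / n
  nu[nu > fs / 2] <- nu[nu > fs / 2] - fs           # signed frequency
  chs <- signal_channels(rec)
  acc <- numeric(length(bands))
  for (ch in chs) {
    P <- Mod(stats::fft(rec$data[ch, ]))^2          # |X_k|^2
    for (b in seq_along(bands)) {
      band <- bands[[b]]
      layer_means <- vapply(band$freqs, function(f) {
        sigma_t <- band$c / (2 * pi * f)
        keep <- abs(nu - f) < 4 / (2 * pi * sigma_t)  # 4 spectral sds
        H2 <- 2 * sqrt(pi) * sigma_t *
          exp(-4 * pi^2 * sigma_t^2 * (nu[keep] - f)^2)
        sum(P[keep] * H2) / n^2                     # = mean_t |coef_t|^2
      }, 0)
      acc[b] <- acc[b] + mean(layer_means)
    }
  }
  acc / length(chs)
}

whole_recording_band_power <- function(rec, band)
  whole_recording_band_powers(rec, list(band))[1]

#' Normalize a power value to the whole-recording band mean
#'
#' Divides `value` by the average power of the same frequency band over
#' the entire recording, yielding a dimensionless quantity comparable
#' across animals and sessions.
#'
#' @param value power in µV².
#' @param rec the [eeg_recording()] (longer than 10 s).
#' @param band the [morlet_spec()] the value was computed in.
#' @return dimensionless normalized power.
#' @export
normalize_to_recording <- function(value, rec, band) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) / rec$fs <= 10)
    stop("recording must be longer than 10 s for a stable normalizer",
         call. = FALSE)
  norm <- whole_recording_band_power(rec, band)
  if (norm == 0) stop("whole-recording band power is zero: normalization undefined",
                      call. = FALSE)
  value / norm
}
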