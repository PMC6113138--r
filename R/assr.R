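#' Zero-phase Butterworth band-pass around the stimulation frequency
#'
#' Second-order Butterworth IIR filter with cutoffs 5 Hz below and above
#' the stimulus frequency (35-45 Hz for a 40 Hz train), applied
#' forward-backward (`filtfilt`) so the net phase shift is zero.  Only
#' signal channels are filtered; the trigger channel passes through.
#'
#' @param rec an [eeg_recording()].
#' @param center_hz stimulation frequency (Hz).
#' @param half_width_hz one-sided pass-band width (Hz).
#' @return the filtered [eeg_recording()].
#' @export
assr_bandpass <- function(rec, center_hz = 40, half_width_hz = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  lo <- center_hz - half_width_hz
  hi <- center_hz + half_width_hz
  if (lo <= 0 || hi >= rec$fs / 2)
    stop("band edges must satisfy 0 < lo < hi < fs/2", call. = FALSE)
  bf <- signal::butter(2, c(lo, hi) / (rec$fs / 2), type = "pass")
  for (ch in signal_channels(rec))
    rec$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  rec
}

#' Segment an ASSR recording into 2.8 s epochs
#'
#' Cuts epochs of `pre_ms` pre-trial, `trial_ms` stimulation and `post_ms`
#' post-trial around each `train_onset` event (defaults 400/2000/400 ms).
#'
#' @param rec an [eeg_recording()].
#' @param events an [event_table()] (defaults to the recording's own);
#'   only `train_onset` rows are used.
#' @param pre_ms,trial_ms,post_ms window parts in ms.
#' @return an `epoch_set` whose `trial_ms` attribute records the
#'   stimulation window.
#' @export
segment_assr <- function(rec, events = rec$events, pre_ms = 400,
                         trial_ms = 2000, post_ms = 400) {
  es <- segment(rec, events, pre_ms = pre_ms, post_ms = trial_ms + post_ms,
                label = "train_onset")
  attr(es, "trial_ms") <- trial_ms
  es
}

#' 40 Hz steady-state power
#'
#' Accumulated power of the stimulation-frequency Morlet layer (c = 5)
#' over the trial window: per trial and channel, `|coef|^2` is summed over
#' the 2 s stimulation phase, then averaged across trials and channels.
#'
#' @param epochs an `epoch_set` from [segment_assr()].
#' @param freq_hz stimulation frequency (Hz).
#' @param trial_ms stimulation window length (ms), taken from the epochs
#'   when available.
#' @param c Morlet cycles parameter.
#' @return accumulated power in µV² (sum over trial-window samples).
#' @export
assr_power <- function(epochs, freq_hz = 40,
                       trial_ms = attr(epochs, "trial_ms") %||% 2000,
                       c = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (sum(epochs$keep) < 1) stop("no trials remain", call. = FALSE)
  spec <- morlet_spec(freq_hz - 0.5, freq_hz + 0.5, step = 1, c = c)
  spec$freqs <- freq_hz
  tfr <- morlet_transform(epochs, spec, times_keep_ms = c(0, trial_ms))
  d <- dim(tfr$coef)
  v <- tfr$valid[1, ]
  acc <- 0
  for (i in seq_len(d[1])) for (ch in seq_len(d[2]))
    acc <- acc + sum(Mod(tfr$coef[i, ch, 1, v])^2)
  acc / (d[1] * d[2])
}

#' Intertrial coherence (phase-locking factor) at the stimulation frequency
#'
#' For every time point, the complex Morlet coefficients of all trials are
#' normalized to unit magnitude and averaged; the modulus of that average
#' is the ITC, ranging from 0 (random phase across trials) to 1 (perfect
#' phase locking).  The scalar summary is the mean (or median) of the ITC
#' curve over the stimulation window, averaged across channels.
#' Zero-magnitude coefficients are excluded from the average and counted.
#'
#' @param epochs an `epoch_set` from [segment_assr()] (>= 2 kept trials).
#' @param freq_hz stimulation frequency (Hz).
#' @param trial_ms stimulation window length (ms).
#' @param c Morlet cycles parameter.
#' @param reduce `"mean"` or `"median"` time reduction for the scalar.
#' @return an `assr_result`: list with `itc_40hz`, `itc_curve`,
#'   `times_ms`, `n_trials`, `n_zero_coef`.
#' @export
assr_itc <- function(epochs, freq_hz = 40,
                     trial_ms = attr(epochs, "trial_ms") %||% 2000,
                     c = 5, reduce = c("mean", "median")) {
  stopifnot(inherits(epochs, "epoch_set"))
  reduce <- match.arg(reduce)
  if (sum(epochs$keep) < 2)
    stop("intertrial coherence requires >= 2 trials", call. = FALSE)
  spec <- morlet_spec(freq_hz - 0.5, freq_hz + 0.5, step = 1, c = c)
  spec$freqs <- freq_hz
  tfr <- morlet_transform(epochs, spec, times_keep_ms = c(0, trial_ms))
  d <- dim(tfr$coef)
  v <- tfr$valid[1, ]
  n_zero <- 0
  itc_ch <- matrix(NA_real_, nrow = d[2], ncol = sum(v))
  for (ch in seq_len(d[2])) {
    z <- matrix(tfr$coef[, ch, 1, v], nrow = d[1])     # trials x times
    mag <- Mod(z)
    zero <- mag == 0
    n_zero <- n_zero + sum(zero)
    u <- z / mag
    u[zero] <- NA_complex_
    m <- colMeans(u, na.rm = TRUE)
    itc_ch[ch, ] <- Mod(m)
  }
  curve <- colMeans(itc_ch)
  scalar <- if (reduce == "mean") mean(curve) else stats::median(curve)
  structure(list(itc_40hz = scalar, itc_curve = curve,
                 times_ms = tfr$times_ms[v], n_trials = d[1],
                 n_zero_coef = n_zero),
            class = "assr_result")
}

#' @export
print.assr_result <- function(x, ...) {
  cat(sprintf("<assr_result> ITC = %.4f over %d trials (%d zero coefficients excluded)\n",
              x$itc_40hz, x$n_trials, x$n_zero_coef))
  invisible(x)
}
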