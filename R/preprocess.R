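#' Recover events from the trigger channel
#'
#' Events are detected as rising crossings of `threshold_uV` on the `TRIG`
#' channel; the onset is the first supra-threshold sample (0-based).
#' Because an EDF trigger channel carries only pulses, labels are
#' reconstructed from the protocol structure when one is supplied: for a
#' paired-click protocol an inter-onset interval matching the intra-pair
#' interval (within `tol_samples`) marks a `click2`; for an ASSR protocol
#' every pulse is a `train_onset`; for an oddball protocol every
#' `deviant_period`-th pulse is the `deviant` and flip-flop blocks/tone
#' frequencies are reassigned by ordinal position.
#'
#' @param rec an [eeg_recording()] with a `TRIG` channel.
#' @param threshold_uV detection threshold (default half the simulator's
#'   500 µV pulse amplitude).
#' @param protocol optional protocol [event_table()] (or its `"protocol"`
#'   attribute list) used to assign labels.
#' @param tol_samples tolerance on expected intervals for classification.
#' @return an [event_table()]; empty (with a warning) when the trigger
#'   channel never crosses the threshold.
#' @export
extract_events <- function(rec, threshold_uV = 250, protocol = NULL,
                           tol_samples = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  trig <- rec$data[trigger_channel(rec), ]
  above <- trig >= threshold_uV
  rising <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rising)) {
    warning("no trigger crossings found; returning empty event table")
    ev <- event_table(integer(0), character(0), fs = rec$fs)
    return(ev)
  }
  onsets <- rising - 1L                      # 0-based
  pattr <- if (inherits(protocol, "event_table")) attr(protocol, "protocol")
           else protocol
  labels <- rep("pulse", length(onsets))
  block <- rep(1L, length(onsets))
  tone <- rep(NA_real_, length(onsets))
  if (!is.null(pattr)) {
    if (pattr$kind == "erp") {
      gaps <- diff(onsets)
      expected <- round(pattr$intra_pair_s * rec$fs)
      labels[] <- "click1"
      labels[1L + which(abs(gaps - expected) <= tol_samples)] <- "click2"
    } else if (pattr$kind == "assr") {
      labels[] <- "train_onset"
    } else if (pattr$kind == "mmn") {
      k <- seq_along(onsets)
      is_dev <- k %% pattr$deviant_period == 0
      labels <- ifelse(is_dev, "deviant", "standard")
      half <- pattr$flip_flop &
        (k > length(onsets) / 2)
      block <- ifelse(half, 2L, 1L)
      std_f <- ifelse(half, pattr$f_dev, pattr$f_std)
      dev_f <- ifelse(half, pattr$f_std, pattr$f_dev)
      tone <- ifelse(is_dev, dev_f, std_f)
    }
  }
  ev <- event_table(onsets, labels, fs = rec$fs, block_id = block,
                    tone_freq_hz = tone)
  attr(ev, "protocol") <- pattr
  ev
}

#' Epoch container
#'
#' Trials x channels x samples array cut around events, with pre/post
#' window metadata, per-trial labels and a keep/drop mask.  Time 0 is the
#' stimulus onset; sample counts follow
#' `round(pre_ms/1000*fs) + round(post_ms/1000*fs)`.
#'
#' @name epoch_set
NULL

new_epoch_set <- function(data, fs, pre_ms, post_ms, labels,
                          keep = rep(TRUE, dim(data)[1]),
                          channel_labels = NULL) {
  pre_samp <- round(pre_ms / 1000 * fs)
  times_ms <- (seq_len(dim(data)[3]) - pre_samp - 1) / fs * 1000
  structure(list(data = data, fs = fs, pre_ms = pre_ms, post_ms = post_ms,
                 labels = labels, keep = keep, times_ms = times_ms,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d ch x %d samples (%g..%g ms), %d kept\n",
              d[1], d[2], d[3], min(x$times_ms), max(x$times_ms),
              sum(x$keep)))
  invisible(x)
}

#' Segment a recording into epochs around events
#'
#' Cuts one epoch per requested event spanning `pre_ms` before to
#' `post_ms` after the onset (the default 200/1000 ms gives the standard
#' 1200 ms ERP bin).  Events without full pre/post context inside the
#' recording are excluded and reported via the `"excluded"` attribute and
#' a message.  The trigger channel is not epoched.
#'
#' @param rec an [eeg_recording()].
#' @param events an [event_table()] (defaults to the recording's own).
#' @param pre_ms,post_ms window bounds in ms.
#' @param label optional label filter (e.g. `"click1"`).
#' @return an `epoch_set`.
#' @export
segment <- function(rec, events = rec$events, pre_ms = 200, post_ms = 1000,
                    label = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "event_table"))
  if (!is.null(label)) events <- events[events$label %in% label, , drop = FALSE]
  if (!nrow(events)) stop("no events to segment", call. = FALSE)
  fs <- rec$fs
  pre_samp <- round(pre_ms / 1000 * fs)
  post_samp <- round(post_ms / 1000 * fs)
  ns_epoch <- pre_samp + post_samp
  n <- ncol(rec$data)
  chs <- signal_channels(rec)
  start <- events$onset_sample - pre_samp + 1L     # 1-based first sample
  end <- events$onset_sample + post_samp
  ok <- start >= 1L & end <= n
  if (!any(ok)) stop("zero events with full pre/post context", call. = FALSE)
  if (any(!ok))
    message(sprintf("segment: excluded %d event(s) lacking full context",
                    sum(!ok)))
  keep_idx <- which(ok)
  data <- array(0, dim = c(length(keep_idx), length(chs), ns_epoch))
  for (i in seq_along(keep_idx)) {
    e <- keep_idx[i]
    data[i, , ] <- rec$data[chs, start[e]:end[e], drop = FALSE]
  }
  es <- new_epoch_set(data, fs, pre_ms, post_ms,
                      labels = events$label[keep_idx],
                      channel_labels = rec$channel_labels[chs])
  attr(es, "excluded") <- which(!ok)
  attr(es, "event_rows") <- keep_idx
  es
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean of the pre-stimulus window
#' (times < 0) so the pre-stimulus mean becomes zero.
#'
#' @param epochs an `epoch_set` with `pre_ms > 0`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$pre_ms <= 0)
    stop("baseline correction requires a pre-stimulus window (pre_ms > 0)",
         call. = FALSE)
  pre_cols <- which(epochs$times_ms < 0)
  d <- dim(epochs$data)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      epochs$data[tr, ch, ] <- epochs$data[tr, ch, ] -
        mean(epochs$data[tr, ch, pre_cols])
  epochs
}

#' Average ERP across kept trials
#'
#' Pointwise mean over trials flagged keep, averaged across channels by
#' default (set `channel` to an index for a single channel).
#'
#' @param epochs an `epoch_set`.
#' @param channel `"mean"` or a channel index.
#' @return a numeric waveform with attributes `times_ms` and `fs`, of
#'   class `erp_waveform`.
#' @export
average_erp <- function(epochs, channel = "mean") {
  stopifnot(inherits(epochs, "epoch_set"))
  kept <- which(epochs$keep)
  if (!length(kept)) stop("no trials remain after rejection", call. = FALSE)
  d <- epochs$data[kept, , , drop = FALSE]
  m <- apply(d, c(2, 3), mean)              # channels x samples
  w <- if (identical(channel, "mean")) colMeans(m) else m[channel, ]
  structure(w, times_ms = epochs$times_ms, fs = epochs$fs,
            n_trials = length(kept), class = "erp_waveform")
}

#' Peak-to-peak artifact rejection
#'
#' Flags any trial whose within-epoch peak-to-peak range exceeds
#' `peak_to_peak_limit_uV` on any signal channel.  The mask is returned,
#' never silently applied; combine with [apply_rejection()].
#'
#' @param epochs an `epoch_set`.
#' @param peak_to_peak_limit_uV rejection limit in µV (> 0); the 800 µV
#'   default is conservative for a signal whose inclusion floor is a
#'   100 µV P1N1.
#' @return a `rejection_mask`: list with logical `keep` and character
#'   `reason` ("" or "amplitude"), one entry per trial.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_limit_uV = 800) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (peak_to_peak_limit_uV <= 0)
    stop("peak_to_peak_limit_uV must be > 0", call. = FALSE)
  d <- dim(epochs$data)
  ptp <- vapply(seq_len(d[1]), function(tr) {
    m <- matrix(epochs$data[tr, , ], nrow = d[2])
    max(apply(m, 1, function(x) diff(range(x))))
  }, 0)
  keep <- ptp <= peak_to_peak_limit_uV
  structure(list(keep = keep,
                 reason = ifelse(keep, "", "amplitude")),
            class = "rejection_mask")
}

#' @rdname reject_artifacts
#' @param mask a `rejection_mask` from [reject_artifacts()].
#' @export
apply_rejection <- function(epochs, mask) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(mask, "rejection_mask"),
            length(mask$keep) == dim(epochs$data)[1])
  epochs$keep <- epochs$keep & mask$keep
  epochs
}
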