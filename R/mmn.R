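#' Pair each deviant with its last preceding standard
#'
#' To compare averages built from equal trial counts, only the last
#' standard tone before each deviant enters the standard average.  Pairs
#' are formed within blocks (flip-flop halves) and pooled; a deviant with
#' no preceding standard in its block is skipped with a message.
#'
#' @param events an [event_table()] with `standard`/`deviant` labels.
#' @return a data.frame with columns `std_row`, `dev_row` (row indices
#'   into `events`), one row per analyzable deviant.
#' @export
match_trials <- function(events) {
  stopifnot(inherits(events, "event_table"))
  dev <- which(events$label == "deviant")
  if (!length(dev)) stop("no deviant events in the table", call. = FALSE)
  std <- events$label == "standard"
  pairs <- lapply(dev, function(d) {
    prior <- which(std & seq_len(nrow(events)) < d &
                     events$block_id == events$block_id[d])
    if (!length(prior)) return(NULL)
    c(std_row = max(prior), dev_row = d)
  })
  skipped <- sum(vapply(pairs, is.null, TRUE))
  if (skipped == length(dev))
    stop("no deviant has a preceding standard", call. = FALSE)
  if (skipped)
    message(sprintf("match_trials: skipped %d deviant(s) without a preceding standard",
                    skipped))
  as.data.frame(do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)]))
}

#' Mismatch-negativity area under the curve
#'
#' The MMN peak is the most negative point of the deviant-minus-standard
#' difference wave inside the post-stimulus search window; the MMN
#' magnitude is the trapezoidal integral of the difference wave over the
#' 50 ms window centered on that peak (+/- 25 ms), in µV·ms (negative for
#' a genuine MMN).  A window clipped by the epoch edge is integrated over
#' the clipped span with a warning.
#'
#' @param diff an `erp_waveform` difference wave (deviant - standard).
#' @param search_window_ms post-stimulus peak search window (ms).
#' @param window_half_ms integration half-window around the peak (ms).
#' @return list with `peak_latency_ms` and `auc` (µV·ms, signed).
#' @export
mmn_auc <- function(diff, search_window_ms = c(20, 100), window_half_ms = 25) {
  stopifnot(inherits(diff, "erp_waveform"))
  times <- attr(diff, "times_ms")
  sw <- which(times >= search_window_ms[1] & times <= search_window_ms[2])
  if (!length(sw)) stop("search window outside the epoch", call. = FALSE)
  peak_i <- sw[which.min(diff[sw])]
  peak_t <- times[peak_i]
  lo <- peak_t - window_half_ms
  hi <- peak_t + window_half_ms
  if (lo < min(times) || hi > max(times)) {
    warning("integration window clipped by the epoch edge")
    lo <- max(lo, min(times)); hi <- min(hi, max(times))
  }
  cols <- which(times >= lo - 1e-9 & times <= hi + 1e-9)
  y <- as.numeric(diff[cols]); t <- times[cols]
  auc <- sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  list(peak_latency_ms = peak_t, auc = auc)
}

#' Robust-MMN inclusion rule
#'
#' Animals qualify for the MMN readout when their baseline
#' standard/deviant ratio reaches `threshold` (default 0.5).  The ratio is
#' taken as `|N1(standard)| / |N1(deviant)|`: a deviant response much
#' larger than the standard one leaves the ratio below the floor only when
#' the standard response is weak, i.e. the session lacks a measurable
#' repetition response to compare against.
#'
#' @param standard_erp,deviant_erp `erp_waveform`s (or `erp_measure`s).
#' @param threshold inclusion floor for the ratio.
#' @param ... passed to [measure_n1()].
#' @return list with `ratio` and logical `robust`.
#' @export
robust_mmn <- function(standard_erp, deviant_erp, threshold = 0.5, ...) {
  m_of <- function(x) if (inherits(x, "erp_measure")) x else measure_n1(x, ...)
  ms <- m_of(standard_erp); md <- m_of(deviant_erp)
  if (abs(md$n1_amplitude_uV) == 0)
    stop("deviant N1 amplitude is zero: ratio undefined", call. = FALSE)
  ratio <- abs(ms$n1_amplitude_uV) / abs(md$n1_amplitude_uV)
  list(ratio = ratio, robust = ratio >= threshold)
}

#' Full MMN analysis of one oddball recording
#'
#' Pairs deviants with their last preceding standards, averages both sets
#' (equal counts by construction), forms the deviant-minus-standard
#' difference wave and measures the peak-centered AUC and the robustness
#' ratio.
#'
#' @param rec an [eeg_recording()] of an oddball session.
#' @param events an [event_table()] (defaults to the recording's own).
#' @param pre_ms,post_ms epoch window (ms); the default 100/400 ms fits
#'   inside the 550 ms inter-onset interval.
#' @param peak_to_peak_limit_uV artifact-rejection limit; rejection is
#'   applied pairwise so equal counts are preserved.
#' @param ... passed to [mmn_auc()].
#' @return an `mmn_result`: list with `standard_erp`, `deviant_erp`,
#'   `difference_wave`, `peak_latency_ms`, `auc`, `std_dev_ratio`,
#'   `robust`, `n_pairs`.
#' @export
analyze_mmn <- function(rec, events = rec$events, pre_ms = 100, post_ms = 400,
                        peak_to_peak_limit_uV = 800, ...) {
  pairs <- match_trials(events)
  pre_samp <- round(pre_ms / 1000 * rec$fs)
  post_samp <- round(post_ms / 1000 * rec$fs)
  fits <- function(rows) events$onset_sample[rows] - pre_samp + 1 >= 1 &
    events$onset_sample[rows] + post_samp <= ncol(rec$data)
  ok <- fits(pairs$std_row) & fits(pairs$dev_row)
  if (!any(ok)) stop("no analyzable standard/deviant pairs", call. = FALSE)
  pairs <- pairs[ok, , drop = FALSE]
  ep_std <- segment(rec, events[pairs$std_row, ], pre_ms, post_ms)
  ep_dev <- segment(rec, events[pairs$dev_row, ], pre_ms, post_ms)
  # pairwise rejection: a pair is dropped when either member is an artifact
  keep <- reject_artifacts(ep_std, peak_to_peak_limit_uV)$keep &
          reject_artifacts(ep_dev, peak_to_peak_limit_uV)$keep
  ep_std$keep <- ep_std$keep & keep
  ep_dev$keep <- ep_dev$keep & keep
  stopifnot(sum(ep_std$keep) == sum(ep_dev$keep))
  std_avg <- average_erp(baseline_correct(ep_std))
  dev_avg <- average_erp(baseline_correct(ep_dev))
  dw <- structure(as.numeric(dev_avg) - as.numeric(std_avg),
                  times_ms = attr(std_avg, "times_ms"),
                  fs = attr(std_avg, "fs"), class = "erp_waveform")
  pk <- mmn_auc(dw, ...)
  rb <- robust_mmn(std_avg, dev_avg)
  structure(list(standard_erp = std_avg, deviant_erp = dev_avg,
                 difference_wave = dw, peak_latency_ms = pk$peak_latency_ms,
                 auc = pk$auc, std_dev_ratio = rb$ratio, robust = rb$robust,
                 n_pairs = sum(ep_std$keep)),
            class = "mmn_result")
}
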