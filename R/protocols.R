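#' Auditory stimulation protocols
#'
#' Deterministic event-table generators for the three session types used in
#' rodent pharmaco-EEG: paired-click ERP sessions, 40 Hz steady-state click
#' trains, and the flip-flop oddball sequence for mismatch negativity.
#' Protocol timing carries no randomness: the same parameters always yield
#' bit-identical onsets.  All onsets are 0-based sample indices; time 0 is
#' the session start.
#'
#' @name protocols
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

protocol_attr <- function(ev, kind, ...) {
  attr(ev, "protocol") <- c(list(kind = kind), list(...))
  ev
}

#' Paired-click ERP protocol
#'
#' The standard sensory-gating session: pairs of identical clicks, with a
#' short intra-pair interval and a long inter-pair interval.  The session
#' default (300 pairs, 0.5 s within a pair, 10 s between pairs) is the
#' configuration whose inter-click gaps also provide the pre-stimulus
#' segments used for basal oscillation power.
#'
#' @param n_pairs number of click pairs (>= 1).
#' @param intra_pair_s interval between click 1 and click 2 within a pair (s).
#' @param inter_pair_s interval between the second click of a pair and the
#'   first click of the next pair (s).
#' @param fs sampling rate in Hz.
#' @return an [event_table()] with alternating `click1`/`click2` labels;
#'   the pair cycle length is `intra_pair_s + inter_pair_s`.
#' @export
make_paired_click_protocol <- function(n_pairs = 300, intra_pair_s = 0.5,
                                       inter_pair_s = 10, fs = 1000) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (intra_pair_s <= 0 || inter_pair_s <= 0)
    stop("intervals must be strictly positive", call. = FALSE)
  cycle <- intra_pair_s + inter_pair_s
  first <- round((seq_len(n_pairs) - 1) * cycle * fs)
  second <- first + round(intra_pair_s * fs)
  onsets <- as.vector(rbind(first, second))
  labels <- rep(c("click1", "click2"), n_pairs)
  ev <- event_table(onsets, labels, fs = fs)
  protocol_attr(ev, "erp", n_pairs = n_pairs, intra_pair_s = intra_pair_s,
                inter_pair_s = inter_pair_s, fs = fs)
}

#' 40 Hz auditory steady-state (ASSR) protocol
#'
#' Periodic trains of single clicks at `rate_hz`, each train lasting
#' `train_s`, separated by `iti_s` of silence.  The default (100 trains of
#' 2 s at 40 Hz with a 30 s inter-train interval) is the canonical ASSR
#' session.  The table holds one `train_onset` event per train plus a
#' `click` child event per click within the train.
#'
#' @param n_trains number of trains (>= 1).
#' @param train_s train duration in seconds.
#' @param rate_hz click repetition rate within a train (Hz).
#' @param iti_s silent interval between trains (s).
#' @param fs sampling rate in Hz.
#' @return an [event_table()]; `rate_hz * train_s` clicks per train (rounded
#'   down with a warning when not a whole number).
#' @export
make_assr_protocol <- function(n_trains = 100, train_s = 2, rate_hz = 40,
                               iti_s = 30, fs = 1000) {
  if (n_trains < 1) stop("n_trains must be >= 1", call. = FALSE)
  if (train_s <= 0 || iti_s <= 0 || rate_hz <= 0)
    stop("intervals and rate must be strictly positive", call. = FALSE)
  if (rate_hz >= fs / 2)
    stop("rate_hz must be below the Nyquist frequency fs/2", call. = FALSE)
  n_clicks_exact <- rate_hz * train_s
  n_clicks <- floor(n_clicks_exact + 1e-9)
  if (abs(n_clicks_exact - n_clicks) > 1e-9)
    warning(sprintf("rate_hz * train_s = %g is not a whole number of clicks; using %d",
                    n_clicks_exact, n_clicks))
  period <- train_s + iti_s
  onsets <- integer(0)
  labels <- character(0)
  for (k in seq_len(n_trains)) {
    t0 <- round((k - 1) * period * fs)
    onsets <- c(onsets, t0, t0 + round(seq_len(n_clicks - 1) / rate_hz * fs))
    labels <- c(labels, "train_onset", rep("click", n_clicks - 1))
  }
  ev <- event_table(onsets, labels, fs = fs)
  protocol_attr(ev, "assr", n_trains = n_trains, train_s = train_s,
                rate_hz = rate_hz, iti_s = iti_s, fs = fs)
}

#' Flip-flop oddball (MMN) protocol
#'
#' Cycles of `deviant_period` tones: `deviant_period - 1` standards followed
#' by one deviant, so the deviant fraction is exactly `1/deviant_period`
#' (the default every-20th placement gives 5%).  Under the flip-flop design
#' the standard and deviant tone frequencies swap exactly at half the
#' cycles, so each frequency serves as standard in one half and as deviant
#' in the other.
#'
#' @param n_cycles number of oddball cycles (even when `flip_flop`).
#' @param deviant_period cycle length in tones (>= 2); the deviant is the
#'   last tone of each cycle.
#' @param tone_s tone duration (s).
#' @param isi_s inter-stimulus interval between tone offset and the next
#'   tone onset (s); the inter-onset interval is `tone_s + isi_s`.
#' @param f_std,f_dev the two tone frequencies in Hz (must differ).
#' @param flip_flop swap standard/deviant frequencies at 50% of cycles.
#' @param fs sampling rate in Hz.
#' @return an [event_table()] with labels `standard`/`deviant`, per-tone
#'   frequencies, and `block_id` 1/2 for the two flip-flop halves.
#' @export
make_oddball_protocol <- function(n_cycles = 600, deviant_period = 20,
                                  tone_s = 0.05, isi_s = 0.5,
                                  f_std = 9000, f_dev = 12000,
                                  flip_flop = TRUE, fs = 1000) {
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (deviant_period < 2) stop("deviant_period must be >= 2", call. = FALSE)
  if (tone_s <= 0 || isi_s <= 0)
    stop("tone_s and isi_s must be strictly positive", call. = FALSE)
  if (f_std == f_dev)
    stop("f_std and f_dev must differ (no pitch deviance otherwise)",
         call. = FALSE)
  if (flip_flop && n_cycles %% 2 != 0)
    stop("n_cycles must be even for a flip-flop design", call. = FALSE)
  ioi <- tone_s + isi_s
  n_tones <- n_cycles * deviant_period
  idx <- seq_len(n_tones) - 1L           # 0-based global tone index
  onsets <- round(idx * ioi * fs)
  pos_in_cycle <- idx %% deviant_period  # deviant at the last position
  is_dev <- pos_in_cycle == deviant_period - 1L
  cycle <- idx %/% deviant_period + 1L
  second_half <- flip_flop & cycle > n_cycles / 2
  block <- ifelse(second_half, 2L, 1L)
  std_f <- ifelse(second_half, f_dev, f_std)
  dev_f <- ifelse(second_half, f_std, f_dev)
  ev <- event_table(onsets,
                    ifelse(is_dev, "deviant", "standard"),
                    fs = fs, block_id = block,
                    tone_freq_hz = ifelse(is_dev, dev_f, std_f))
  protocol_attr(ev, "mmn", n_cycles = n_cycles,
                deviant_period = deviant_period, tone_s = tone_s,
                isi_s = isi_s, f_std = f_std, f_dev = f_dev,
                flip_flop = flip_flop, fs = fs)
}
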