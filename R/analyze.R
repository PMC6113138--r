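#' Analyze one paired-click ERP recording
#'
#' Segments click-1 and click-2 epochs (1200 ms bin: 200 ms pre, 1 s
#' post), rejects artifact trials, baseline-corrects, averages, and
#' measures the N1 amplitude/latency, the P1N1 inclusion amplitude and
#' the S2/S1 gating ratio.
#'
#' @param rec an [eeg_recording()] of a paired-click session.
#' @param events an [event_table()] (defaults to the recording's own).
#' @param pre_ms,post_ms epoch window (ms).
#' @param peak_to_peak_limit_uV artifact-rejection limit (µV).
#' @return list with `n1_amp_uV` (magnitude), `n1_latency_ms`, `p1n1_uV`,
#'   `gating_ratio`, `included` (P1N1 screen), `n_kept_trials`, and the
#'   two `erp_measure`s.
#' @export
analyze_erp <- function(rec, events = rec$events, pre_ms = 200,
                        post_ms = 1000, peak_to_peak_limit_uV = 800) {
  avg_for <- function(lab) {
    ep <- segment(rec, events, pre_ms, post_ms, label = lab)
    ep <- apply_rejection(ep, reject_artifacts(ep, peak_to_peak_limit_uV))
    list(avg = average_erp(baseline_correct(ep)), n = sum(ep$keep))
  }
  a1 <- avg_for("click1")
  a2 <- avg_for("click2")
  m1 <- measure_n1(a1$avg)
  m2 <- measure_n1(a2$avg)
  list(n1_amp_uV = abs(m1$n1_amplitude_uV),
       n1_latency_ms = m1$n1_latency_ms,
       p1n1_uV = m1$p1n1_uV,
       gating_ratio = gating_ratio(m1, m2),
       included = screen_animal(m1),
       n_kept_trials = a1$n + a2$n,
       click1 = m1, click2 = m2)
}

#' Analyze basal and evoked gamma/theta oscillation
#'
#' Morlet-based band power readouts from a paired-click session: basal
#' power from the 400 ms bin 3 s before each click-1, and evoked power
#' from a P1-anchored window (gamma: +/- 25 ms; theta: -20/+180 ms) minus
#' the basal power.  Raw µV² values are reported together with versions
#' normalized to the whole-recording band mean.
#'
#' @param rec an [eeg_recording()] of a paired-click session.
#' @param events an [event_table()] (defaults to the recording's own).
#' @param p1_latency_ms measured P1 latency (from [analyze_erp()]); `NA`
#'   falls back to the default with a warning.
#' @param normalize also compute whole-recording-normalized values.
#' @return list with `basal_gamma`, `evoked_gamma`, `basal_theta`,
#'   `evoked_theta` (µV²) and, when `normalize`, `*_norm` counterparts.
#' @export
analyze_oscillations <- function(rec, events = rec$events,
                                 p1_latency_ms = 20, normalize = TRUE) {
  ev1 <- events[events$label == "click1", , drop = FALSE]
  gam <- gamma_band(); the <- theta_band()
  bg <- basal_power(rec, ev1, gam)
  bt <- basal_power(rec, ev1, the)
  # theta needs ~0.8 s of valid context around the window at 4 Hz
  ep <- segment(rec, ev1, pre_ms = 1000, post_ms = 1200)
  ep <- baseline_correct(ep)
  eg <- evoked_band_power(ep, gam, bg, p1_latency_ms, 25, 25)
  et <- evoked_band_power(ep, the, bt, p1_latency_ms, 20, 180)
  out <- list(basal_gamma = bg, evoked_gamma = eg$evoked,
              basal_theta = bt, evoked_theta = et$evoked)
  if (normalize) {
    wp <- whole_recording_band_powers(rec, list(gam, the))
    ng <- wp[1]; nt <- wp[2]
    out$basal_gamma_norm <- bg / ng
    out$evoked_gamma_norm <- eg$evoked / ng
    out$basal_theta_norm <- bt / nt
    out$evoked_theta_norm <- et$evoked / nt
  }
  out
}

#' Analyze one 40 Hz ASSR recording
#'
#' Band-passes 35-45 Hz (zero-phase Butterworth), segments 2.8 s epochs
#' around train onsets, rejects artifact trials, and computes the
#' accumulated 40 Hz layer power and the intertrial coherence over the
#' 2 s stimulation window.
#'
#' @param rec an [eeg_recording()] of an ASSR session.
#' @param events an [event_table()] (defaults to the recording's own).
#' @param freq_hz stimulation rate (Hz).
#' @param peak_to_peak_limit_uV artifact-rejection limit (µV).
#' @return list with `assr_power`, `assr_itc`, `n_trials`.
#' @export
analyze_assr <- function(rec, events = rec$events, freq_hz = 40,
                         peak_to_peak_limit_uV = 800) {
  recf <- assr_bandpass(rec, center_hz = freq_hz)
  ep <- segment_assr(recf, events)
  ep <- apply_rejection(ep, reject_artifacts(ep, peak_to_peak_limit_uV))
  itc <- assr_itc(ep, freq_hz = freq_hz)
  list(assr_power = assr_power(ep, freq_hz = freq_hz),
       assr_itc = itc$itc_40hz,
       n_trials = sum(ep$keep))
}
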