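#' Measure ERP components on an averaged waveform
#'
#' The mouse N1 (N40) is the maximum negative deflection between 30 and
#' 50 ms after the click; the P1 (P20) is the maximum positive deflection
#' in a configurable window (default 15-30 ms, used for the P1N1 inclusion
#' screen).  Components are measured on the trial average, not per trial.
#' Ties are broken to the earliest sample.
#'
#' @param avg an `erp_waveform` from [average_erp()].
#' @param window_ms N1 search window (ms post-stimulus).
#' @param p1_window_ms P1 search window (ms post-stimulus).
#' @return an `erp_measure`: list with `n1_amplitude_uV` (signed),
#'   `n1_latency_ms`, `p1_amplitude_uV`, `p1_latency_ms` and `p1n1_uV`
#'   (peak-to-trough, positive).
#' @export
measure_n1 <- function(avg, window_ms = c(30, 50), p1_window_ms = c(15, 30)) {
  stopifnot(inherits(avg, "erp_waveform"))
  times <- attr(avg, "times_ms")
  pick <- function(win, fun) {
    cols <- which(times >= win[1] & times <= win[2])
    if (!length(cols))
      stop("measurement window lies outside the epoch", call. = FALSE)
    i <- cols[fun(avg[cols])]                # which.min/max: first on ties
    c(amp = unname(avg[i]), lat = times[i])
  }
  n1 <- pick(window_ms, which.min)
  p1 <- pick(p1_window_ms, which.max)
  structure(list(n1_amplitude_uV = n1[["amp"]], n1_latency_ms = n1[["lat"]],
                 p1_amplitude_uV = p1[["amp"]], p1_latency_ms = p1[["lat"]],
                 p1n1_uV = p1[["amp"]] - n1[["amp"]]),
            class = "erp_measure")
}

#' Sensory-gating ratio (S2/S1)
#'
#' Ratio of the N1 magnitude evoked by the second click to that evoked by
#' the first: intact gating gives values < 1 and disrupted gating drives
#' the ratio toward (or above) 1.  The S2/S1 orientation is chosen so that
#' a gating deficit *increases* the readout.
#'
#' @param m1,m2 `erp_measure`s for click 1 and click 2.
#' @return the dimensionless ratio `|N1(click2)| / |N1(click1)|`.
#' @export
gating_ratio <- function(m1, m2) {
  stopifnot(inherits(m1, "erp_measure"), inherits(m2, "erp_measure"))
  if (abs(m1$n1_amplitude_uV) == 0)
    stop("click-1 N1 amplitude is zero: gating ratio undefined",
         call. = FALSE)
  abs(m2$n1_amplitude_uV) / abs(m1$n1_amplitude_uV)
}

#' Animal inclusion screen on P1N1 amplitude
#'
#' An animal is included when the peak-to-trough P1N1 amplitude of its
#' baseline average ERP reaches `min_p1n1_uV` (default 100 µV).
#'
#' @param avg an `erp_waveform`, or an `erp_measure`.
#' @param min_p1n1_uV inclusion threshold in µV.
#' @param ... passed to [measure_n1()] when `avg` is a waveform.
#' @return logical: include this animal?
#' @export
screen_animal <- function(avg, min_p1n1_uV = 100, ...) {
  m <- if (inherits(avg, "erp_measure")) avg else measure_n1(avg, ...)
  m$p1n1_uV >= min_p1n1_uV
}
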