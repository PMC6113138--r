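#' EEG recording container
#'
#' Holds a channels-by-samples matrix in µV with a sampling rate, channel
#' labels, an attached [event_table()] and free-form metadata.  The trigger
#' channel, when present, is labeled `"TRIG"`.
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param fs sampling rate (Hz).
#' @param channel_labels character vector, one per row of `data`.
#' @param events optional [event_table()] with onsets inside the recording.
#' @param meta named list (animal id, treatment, seed, ...).
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          events = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- sprintf("EEG%d", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data))
  if (anyNA(data)) stop("recording contains NaN/NA samples", call. = FALSE)
  if (!is.null(events)) {
    stopifnot(inherits(events, "event_table"))
    if (nrow(events) && max(events$onset_sample) >= ncol(data))
      stop("events fall outside the recording", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%s)\n", nrow(x$events),
                paste(unique(x$events$label), collapse = ", ")))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

signal_channels <- function(rec) which(rec$channel_labels != "TRIG")
trigger_channel <- function(rec) {
  i <- which(rec$channel_labels == "TRIG")
  if (!length(i)) stop("recording has no trigger channel", call. = FALSE)
  i[1L]
}

# 1/f-shaped Gaussian noise via FFT amplitude shaping, rescaled to sd_uV.
pink_noise <- function(n, sd_uV) {
  if (sd_uV == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))   # DFT bin index
  shape <- c(0, 1 / sqrt(k[-1]))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_uV / stats::sd(x)
}

# Band-limited Gaussian noise (hard FFT mask), rescaled to sd_uV.
band_noise <- function(n, fs, f_lo, f_hi, sd_uV) {
  if (sd_uV == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  X[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_uV / stats::sd(x)
}

#' Generate background EEG (noise floor)
#'
#' Zero-mean background activity: a broadband 1/f ("pink") or white
#' component plus stationary band-limited basal gamma (35-80 Hz) and theta
#' (4-12 Hz) processes whose variances are the targets of the
#' `basal_gamma_scale`/`theta_scale` drug knobs.  Channels are independent
#' realizations.  Deterministic under a fixed seed.
#'
#' @param duration_s duration in seconds (> 0).
#' @param cfg a [sim_config()].
#' @param n_channels number of signal channels.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return an [eeg_recording()] without trigger channel or events.
#' @export
generate_background <- function(duration_s, cfg = sim_config(),
                                n_channels = 2, seed = cfg$seed) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  n <- round(duration_s * cfg$fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  data <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    broad <- if (cfg$noise$spectrum == "pink")
      pink_noise(n, cfg$noise$sd_uV)
    else if (cfg$noise$sd_uV > 0) stats::rnorm(n, 0, cfg$noise$sd_uV)
    else numeric(n)
    data[ch, ] <- broad +
      band_noise(n, cfg$fs, 35, 80, cfg$basal$gamma_sd_uV) +
      band_noise(n, cfg$fs, 4, 12, cfg$basal$theta_sd_uV)
  }
  eeg_recording(data, cfg$fs,
                channel_labels = sprintf("EEG%d", seq_len(n_channels)),
                meta = list(seed = seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# Add a Gaussian-windowed bump at `onset` (0-based) into vector x (in place
# semantics via return).  All times in ms relative to the event onset.
add_bump <- function(x, fs, onset, latency_ms, sigma_ms, amp) {
  half <- ceiling(4 * sigma_ms / 1000 * fs)
  center <- onset + latency_ms / 1000 * fs          # 0-based, fractional
  i0 <- max(0L, floor(center) - half)
  i1 <- min(length(x) - 1L, ceiling(center) + half)
  if (i1 < i0) return(x)
  idx <- i0:i1
  t_ms <- (idx - onset) / fs * 1000
  x[idx + 1L] <- x[idx + 1L] + amp * exp(-(t_ms - latency_ms)^2 / (2 * sigma_ms^2))
  x
}

#' Render a synthetic EEG session
#'
#' Adds stimulus-locked activity on top of the background at each event of
#' the protocol: the ERP component family for click-like events (with
#' per-trial latency/amplitude jitter and a stimulus-locked gamma burst),
#' the N1 gating factor for `click2`, the deviant N1 enhancement for
#' `deviant` events, and a constant-rate sinusoid with per-trial phase
#' offset for `train_onset` events.  A rectangular trigger pulse is written
#' to a dedicated `TRIG` channel at every top-level event (child `click`
#' events inside a train carry no pulse).  The session is padded by
#' `lead_in_s` before the first event so that pre-stimulus windows
#' (including the basal bin 3 s before a click) exist for every trial;
#' event onsets in the returned recording are shifted accordingly.
#'
#' The noise and the trial-jitter random streams are seeded separately, so
#' a noiseless render plus a signal-free render under the same seed sum to
#' the full render sample-for-sample.
#'
#' @param protocol an [event_table()] from one of the `make_*_protocol`
#'   generators.
#' @param cfg a [sim_config()].
#' @param effect optional [drug_effect()] applied to the generative
#'   parameters before rendering.
#' @param amp_scale extra multiplicative amplitude factor (the per-animal
#'   offset used by [simulate_cohort()]).
#' @param lead_in_s silent padding before the first event (s).
#' @param tail_s padding after the last event (s).
#' @param duration_s optional total duration override; an error is raised
#'   naming the first event that does not fit.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param meta metadata list stored on the recording.
#' @return an [eeg_recording()] with channels EEG1, EEG2, TRIG and the
#'   shifted event table attached.
#' @export
render_session <- function(protocol, cfg = sim_config(), effect = NULL,
                           amp_scale = 1, lead_in_s = 5, tail_s = 3,
                           duration_s = NULL, seed = cfg$seed,
                           meta = list()) {
  stopifnot(inherits(protocol, "event_table"), nrow(protocol) >= 1)
  cfg <- apply_drug_effect(cfg, effect)
  fs <- cfg$fs
  pattr <- attr(protocol, "protocol")
  shift <- round(lead_in_s * fs)
  onsets <- protocol$onset_sample + shift
  n <- if (is.null(duration_s)) max(onsets) + round(tail_s * fs) + 1L
       else round(duration_s * fs)
  n <- as.integer(ceiling(n / fs) * fs)   # whole seconds: fast FFT lengths
  bad <- which(onsets >= n)
  if (length(bad))
    stop(sprintf("event %d does not fit in the rendered duration", bad[1L]),
         call. = FALSE)

  bg <- generate_background(n / fs, cfg, n_channels = 2,
                            seed = derive_seed(seed, 101))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 202))

  sig <- numeric(n)
  trig <- numeric(n)
  pulse_len <- max(1L, round(cfg$trigger$pulse_ms / 1000 * fs))
  eg <- cfg$evoked_gamma
  for (i in seq_len(nrow(protocol))) {
    lab <- protocol$label[i]
    on <- onsets[i]
    if (lab %in% c("click1", "click2", "standard", "deviant")) {
      for (nm in names(cfg$erp_components)) {
        cmp <- cfg$erp_components[[nm]]
        amp <- cmp$amplitude_uV * amp_scale
        if (nm == "N1") {
          if (lab == "click2") amp <- amp * cfg$gating_factor
          if (lab == "deviant") amp <- amp * cfg$mmn$deviant_n1_scale
        }
        lat <- cmp$latency_ms +
          if (cmp$jitter_latency_ms_sd > 0)
            stats::rnorm(1, 0, cmp$jitter_latency_ms_sd) else 0
        if (cmp$jitter_amp_frac_sd > 0)
          amp <- amp * (1 + stats::rnorm(1, 0, cmp$jitter_amp_frac_sd))
        sig <- add_bump(sig, fs, on, lat, cmp$width_ms, amp)
      }
      if (lab %in% c("click1", "click2") && eg$amplitude_uV > 0) {
        phi <- stats::runif(1, 0, 2 * pi)
        half <- ceiling(4 * eg$sigma_ms / 1000 * fs)
        ctr <- on + round(eg$center_ms / 1000 * fs)
        idx <- max(0L, ctr - half):min(n - 1L, ctr + half)
        t_s <- (idx - on) / fs
        sig[idx + 1L] <- sig[idx + 1L] + amp_scale * eg$amplitude_uV *
          exp(-(t_s * 1000 - eg$center_ms)^2 / (2 * eg$sigma_ms^2)) *
          cos(2 * pi * eg$freq_hz * t_s + phi)
      }
      trig[(on + 1L):min(n, on + pulse_len)] <- cfg$trigger$amplitude_uV
    } else if (lab == "train_onset") {
      if (is.null(pattr) || pattr$kind != "assr")
        stop("train_onset events require an ASSR protocol attribute",
             call. = FALSE)
      phi <- if (cfg$assr$phase_jitter_rad_sd > 0)
        stats::rnorm(1, 0, cfg$assr$phase_jitter_rad_sd) else 0
      len <- round(pattr$train_s * fs)
      idx <- on:min(n - 1L, on + len - 1L)
      t_s <- (idx - on) / fs
      sig[idx + 1L] <- sig[idx + 1L] + amp_scale * cfg$assr$amplitude_uV *
        sin(2 * pi * pattr$rate_hz * t_s + phi)
      trig[(on + 1L):min(n, on + pulse_len)] <- cfg$trigger$amplitude_uV
    }
    # child "click" events shape no waveform and carry no pulse
  }

  data <- rbind(bg$data[1, ] + sig, bg$data[2, ] + sig, trig)
  ev <- event_table(onsets, protocol$label, fs = fs,
                    block_id = protocol$block_id,
                    tone_freq_hz = protocol$tone_freq_hz)
  attr(ev, "protocol") <- pattr
  eeg_recording(data, fs, channel_labels = c("EEG1", "EEG2", "TRIG"),
                events = ev,
                meta = utils::modifyList(list(seed = seed), meta))
}

#' Simulate a cohort of animals across treatments
#'
#' One recording per animal x treatment under a shared protocol.  Each
#' animal receives a single persistent lognormal amplitude offset
#' (sd `cfg$animal_offsets_sd`) applied across all its treatments - the
#' generative counterpart of the per-animal random intercept in the
#' statistical model.  Recordings get independent, reproducible seed
#' substreams derived from `cfg$seed`.
#'
#' @param n_animals number of animals (>= 2 for the downstream mixed model).
#' @param treatments character vector of treatment labels, in dosing order.
#' @param protocol an [event_table()] protocol shared by all recordings.
#' @param cfg a [sim_config()].
#' @param effects named list of [drug_effect()]s, one entry per treatment
#'   label (use `drug_effect()` for vehicle conditions).
#' @param ... passed to [render_session()] (e.g. `lead_in_s`).
#' @return list of [eeg_recording()]s with `meta$animal_id`,
#'   `meta$treatment` and `meta$animal_offset` set.
#' @export
simulate_cohort <- function(n_animals, treatments, protocol,
                            cfg = sim_config(), effects, ...) {
  if (n_animals < 2) stop("n_animals must be >= 2", call. = FALSE)
  missing_t <- setdiff(treatments, names(effects))
  if (length(missing_t))
    stop("no drug effect given for treatment(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 999))
  offsets <- exp(stats::rnorm(n_animals, 0, cfg$animal_offsets_sd))
  recs <- list()
  for (a in seq_len(n_animals)) {
    for (ti in seq_along(treatments)) {
      trt <- treatments[ti]
      rec <- render_session(protocol, cfg, effect = effects[[trt]],
                            amp_scale = offsets[a],
                            seed = derive_seed(cfg$seed, a, ti),
                            meta = list(animal_id = sprintf("m%02d", a),
                                        treatment = trt,
                                        animal_offset = offsets[a]),
                            ...)
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}
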