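#' ERP component specification
#'
#' One Gaussian-windowed deflection of the mouse auditory ERP family
#' (P20/"P1", N40/"N1", P80, P120).  `width_ms` is the Gaussian standard
#' deviation of the envelope; negative amplitudes are troughs.  Per-trial
#' variability enters through latency jitter (additive, ms) and amplitude
#' jitter (multiplicative fraction).
#'
#' @param latency_ms peak latency relative to stimulus onset (ms).
#' @param width_ms Gaussian sd of the bump (ms, > 0).
#' @param amplitude_uV signed peak amplitude (µV); negative = trough.
#' @param jitter_latency_ms_sd per-trial latency jitter sd (ms, >= 0).
#' @param jitter_amp_frac_sd per-trial fractional amplitude jitter sd (>= 0).
#' @export
erp_component <- function(latency_ms, width_ms, amplitude_uV,
                          jitter_latency_ms_sd = 0, jitter_amp_frac_sd = 0) {
  if (width_ms <= 0) stop("width_ms must be > 0", call. = FALSE)
  if (jitter_latency_ms_sd < 0 || jitter_amp_frac_sd < 0)
    stop("jitter sds must be >= 0", call. = FALSE)
  structure(list(latency_ms = latency_ms, width_ms = width_ms,
                 amplitude_uV = amplitude_uV,
                 jitter_latency_ms_sd = jitter_latency_ms_sd,
                 jitter_amp_frac_sd = jitter_amp_frac_sd),
            class = "erp_component")
}

#' Simulator configuration
#'
#' Generative parameters for synthetic mouse EEG sessions.  The defaults
#' emulate an epidural auditory-cortex recording at 1000 Hz: 1/f ("pink")
#' background in µV, stationary band-limited basal gamma and theta
#' activity, a P1/N1/P80/P120 deflection family per click (N1 trough at
#' 40 ms), paired-click gating that scales the click-2 N1, a 40 Hz
#' steady-state entrainment with per-trial Gaussian phase jitter, and a
#' deviant N1 enhancement producing mismatch negativity.  Absolute
#' amplitudes are conventions chosen so that a healthy animal clears the
#' 100 µV P1N1 inclusion floor with margin.
#'
#' @param fs sampling rate (Hz).
#' @param noise list `spectrum` ("pink" or "white") and `sd_uV` for the
#'   broadband background.
#' @param basal list `gamma_sd_uV`, `theta_sd_uV`: sd of the stationary
#'   band-limited (35-80 Hz / 4-12 Hz) basal processes.
#' @param erp_components named list of [erp_component()]s added at every
#'   click-like event (`click1`, `click2`, `standard`, `deviant`).  The
#'   component named `N1` is the one targeted by gating, deviance and the
#'   `n1_scale` drug knob.
#' @param evoked_gamma list `freq_hz`, `amplitude_uV`, `center_ms`,
#'   `sigma_ms`: a brief stimulus-locked gamma burst near the P1 latency,
#'   with random per-trial phase.
#' @param gating_factor multiplier in \[0, 1\] applied to the click-2 N1
#'   amplitude (the generative S2/S1 ratio).
#' @param assr list `amplitude_uV`, `phase_jitter_rad_sd`: 40 Hz train
#'   entrainment amplitude and per-trial phase jitter.
#' @param mmn list `deviant_n1_scale` (>= 1): multiplier on the deviant N1.
#' @param animal_offsets_sd sd of the per-animal lognormal amplitude
#'   offset (0.2 gives ~20% between-animal amplitude spread).
#' @param trigger list `pulse_ms`, `amplitude_uV` for the rectangular
#'   trigger pulse written at each top-level event.
#' @param seed master integer seed; per-animal/treatment substreams are
#'   derived from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(fs = 1000,
                       noise = list(spectrum = "pink", sd_uV = 15),
                       basal = list(gamma_sd_uV = 8, theta_sd_uV = 10),
                       erp_components = list(
                         P1   = erp_component(20, 5, 60, 1, 0.1),
                         N1   = erp_component(40, 8, -120, 2, 0.1),
                         P80  = erp_component(80, 15, 40, 3, 0.1),
                         P120 = erp_component(120, 20, 25, 4, 0.1)),
                       evoked_gamma = list(freq_hz = 50, amplitude_uV = 15,
                                           center_ms = 20, sigma_ms = 10),
                       gating_factor = 0.5,
                       assr = list(amplitude_uV = 25, phase_jitter_rad_sd = 0.5),
                       mmn = list(deviant_n1_scale = 1.5),
                       animal_offsets_sd = 0.2,
                       trigger = list(pulse_ms = 10, amplitude_uV = 500),
                       seed = 1L) {
  stopifnot(fs > 0, noise$sd_uV >= 0,
            gating_factor >= 0, gating_factor <= 1,
            assr$phase_jitter_rad_sd >= 0,
            mmn$deviant_n1_scale >= 1,
            animal_offsets_sd >= 0)
  if (!noise$spectrum %in% c("pink", "white"))
    stop("noise$spectrum must be 'pink' or 'white'", call. = FALSE)
  for (cmp in erp_components)
    if (!inherits(cmp, "erp_component"))
      stop("erp_components must be built with erp_component()", call. = FALSE)
  structure(list(fs = fs, noise = noise, basal = basal,
                 erp_components = erp_components,
                 evoked_gamma = evoked_gamma, gating_factor = gating_factor,
                 assr = assr, mmn = mmn,
                 animal_offsets_sd = animal_offsets_sd,
                 trigger = trigger, seed = as.integer(seed)),
            class = "sim_config")
}

#' Drug effect: multiplicative changes to generative parameters
#'
#' Captures the direction structure of an NMDA-receptor antagonist as
#' multipliers on the generative knobs: reduced N1 (`n1_scale < 1`),
#' increased basal gamma power (`basal_gamma_scale > 1` multiplies the
#' basal gamma *variance*), reduced evoked gamma (`evoked_gamma_scale`
#' multiplies burst power), reduced steady-state amplitude
#' (`assr_amp_scale`), extra per-trial phase jitter (`assr_jitter_add_rad`
#' adds to the jitter sd, lowering intertrial coherence), and attenuated
#' deviance processing (`mmn_scale` shrinks the deviant N1 enhancement
#' toward 1).
#'
#' @param n1_scale,basal_gamma_scale,evoked_gamma_scale,theta_scale,assr_amp_scale,mmn_scale
#'   positive multipliers (1 = no effect).  Power-domain knobs
#'   (`basal_gamma_scale`, `evoked_gamma_scale`, `theta_scale`) multiply
#'   variance/power; amplitude-domain knobs (`n1_scale`,
#'   `assr_amp_scale`, `mmn_scale`) multiply amplitude.
#' @param assr_jitter_add_rad additional phase-jitter sd in radians (>= 0).
#' @return a list of class `drug_effect`.
#' @export
drug_effect <- function(n1_scale = 1, basal_gamma_scale = 1,
                        evoked_gamma_scale = 1, theta_scale = 1,
                        assr_amp_scale = 1, assr_jitter_add_rad = 0,
                        mmn_scale = 1) {
  mult <- c(n1_scale, basal_gamma_scale, evoked_gamma_scale, theta_scale,
            assr_amp_scale, mmn_scale)
  if (any(mult <= 0)) stop("drug-effect multipliers must be > 0", call. = FALSE)
  if (assr_jitter_add_rad < 0)
    stop("assr_jitter_add_rad must be >= 0", call. = FALSE)
  structure(list(n1_scale = n1_scale, basal_gamma_scale = basal_gamma_scale,
                 evoked_gamma_scale = evoked_gamma_scale,
                 theta_scale = theta_scale, assr_amp_scale = assr_amp_scale,
                 assr_jitter_add_rad = assr_jitter_add_rad,
                 mmn_scale = mmn_scale),
            class = "drug_effect")
}

# Fold a drug effect into a sim_config before rendering.
apply_drug_effect <- function(cfg, effect) {
  if (is.null(effect)) return(cfg)
  stopifnot(inherits(effect, "drug_effect"))
  cfg$erp_components$N1$amplitude_uV <-
    cfg$erp_components$N1$amplitude_uV * effect$n1_scale
  cfg$basal$gamma_sd_uV <- cfg$basal$gamma_sd_uV * sqrt(effect$basal_gamma_scale)
  cfg$basal$theta_sd_uV <- cfg$basal$theta_sd_uV * sqrt(effect$theta_scale)
  cfg$evoked_gamma$amplitude_uV <-
    cfg$evoked_gamma$amplitude_uV * sqrt(effect$evoked_gamma_scale)
  cfg$assr$amplitude_uV <- cfg$assr$amplitude_uV * effect$assr_amp_scale
  cfg$assr$phase_jitter_rad_sd <-
    cfg$assr$phase_jitter_rad_sd + effect$assr_jitter_add_rad
  cfg$mmn$deviant_n1_scale <-
    1 + (cfg$mmn$deviant_n1_scale - 1) * effect$mmn_scale
  cfg
}

# Deterministic substream seed derivation (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483587
  for (tag in c(...)) s <- (s * 7919 + as.double(tag) + 1) %% 2147483587
  as.integer(s) + 1L
}
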