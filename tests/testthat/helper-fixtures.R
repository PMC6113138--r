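# Shared fixture builders: small, fast, noise-free unless a test needs noise.

quiet_cfg <- function(..., seed = 1L) {
  args <- list(noise = list(spectrum = "white", sd_uV = 0),
               basal = list(gamma_sd_uV = 0, theta_sd_uV = 0),
               evoked_gamma = list(freq_hz = 50, amplitude_uV = 0,
                                   center_ms = 20, sigma_ms = 10))
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, c(args, list(seed = seed)))
}

# A single-component, jitter-free ERP configuration.
n1_only_cfg <- function(amp = -150, seed = 1L, ...) {
  quiet_cfg(erp_components = list(N1 = erp_component(40, 8, amp)),
            seed = seed, ...)
}

# Waveform helper: wrap a numeric vector as an erp_waveform.
as_waveform <- function(x, fs = 1000, pre_ms = 100) {
  pre_samp <- round(pre_ms / 1000 * fs)
  structure(as.numeric(x),
            times_ms = (seq_along(x) - pre_samp - 1) / fs * 1000,
            fs = fs, class = "erp_waveform")
}

# Epochs built directly from a trials x samples matrix (one channel).
epochs_from_matrix <- function(m, fs = 1000, pre_ms = 100) {
  d <- array(0, dim = c(nrow(m), 1, ncol(m)))
  d[, 1, ] <- m
  mouseEEG:::new_epoch_set(d, fs, pre_ms,
                           ncol(m) / fs * 1000 - pre_ms,
                           labels = rep("click1", nrow(m)))
}
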