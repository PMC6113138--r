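# Independent oracle: direct time-domain convolution sum, one output point
# at a time.  Deliberately naive; shares no code with the FFT path.
oracle_cwt <- function(x, f, fs, c = 5) {
  psi <- morlet_wavelet(f, fs, c)
  half <- attr(psi, "half")
  ts <- (half + 1):(length(x) - half)
  vapply(ts, function(t) sum(x[(t - half):(t + half)] * Conj(psi)) / fs,
         complex(1))
}

test_that("Morlet transform matches the direct-convolution oracle to 1e-6", {
  fs <- 1000
  tt <- seq(0, 1, 1 / fs)
  set.seed(3)
  x <- sin(2 * pi * (30 * tt + 25 * tt^2)) + rnorm(length(tt), 0, 0.3)  # chirp
  spec <- morlet_spec(35, 80, 5)
  W <- mouseEEG:::cwt_vector(x, spec, fs)
  for (k in seq_along(spec$freqs)) {
    orc <- oracle_cwt(x, spec$freqs[k], fs)
    half <- attr(morlet_wavelet(spec$freqs[k], fs), "half")
    got <- W[k, (half + 1):(length(x) - half)]
    expect_lt(max(Mod(got - orc)) / max(Mod(orc)), 1e-6)
  }
})

test_that("the narrow-window direct path agrees with the FFT path", {
  fs <- 1000
  set.seed(4)
  m <- matrix(rnorm(3 * 2200, 0, 10), nrow = 3)
  ep <- epochs_from_matrix(m, pre_ms = 1000)
  full <- morlet_transform(ep, gamma_band())
  win <- morlet_transform(ep, gamma_band(), times_keep_ms = c(-5, 45))
  cols <- which(full$times_ms >= -5 & full$times_ms <= 45)
  expect_equal(win$coef[, , , ], full$coef[, , , cols], tolerance = 1e-9)
})

test_that("layer power peaks at the stimulus frequency and scales quadratically", {
  fs <- 1000
  tt <- seq(0, 2, 1 / fs)
  x1 <- sin(2 * pi * 50 * tt)
  ep <- epochs_from_matrix(rbind(x1), pre_ms = 0)
  tfr <- morlet_transform(ep, gamma_band())
  pw <- vapply(seq_along(tfr$freqs), function(k)
    mean(Mod(tfr$coef[1, 1, k, tfr$valid[k, ]])^2), 0)
  # unit-energy normalization shifts the response maximum ~f/(2c^2), i.e.
  # about 1 Hz below the stimulus frequency at c = 5
  expect_lte(abs(tfr$freqs[which.max(pw)] - 50), 1)
  expect_gt(min(pw[tfr$freqs %in% 49:51]), max(pw[abs(tfr$freqs - 50) > 10]))

  ep2 <- epochs_from_matrix(rbind(2 * x1), pre_ms = 0)
  tfr2 <- morlet_transform(ep2, gamma_band())
  k50 <- which(tfr$freqs == 50)
  p1 <- mean(Mod(tfr$coef[1, 1, k50, tfr$valid[k50, ]])^2)
  p2 <- mean(Mod(tfr2$coef[1, 1, k50, tfr2$valid[k50, ]])^2)
  expect_equal(p2 / p1, 4, tolerance = 1e-9)
})

test_that("epochs shorter than the wavelet support raise a listing error", {
  ep <- epochs_from_matrix(matrix(rnorm(100), nrow = 1), pre_ms = 0)
  expect_error(morlet_transform(ep, theta_band()), "usable")
})

test_that("power of uncorrelated components is additive", {
  set.seed(6)
  fs <- 1000
  n <- 2000
  tt <- seq_len(n) / fs
  burst <- 10 * sin(2 * pi * 45 * tt)
  pw <- function(x) {
    ep <- epochs_from_matrix(rbind(x), pre_ms = 0)
    tfr <- morlet_transform(ep, gamma_band())
    mean(vapply(seq_along(tfr$freqs), function(k)
      mean(Mod(tfr$coef[1, 1, k, tfr$valid[k, ]])^2), 0))
  }
  reps <- replicate(8, {
    noise <- as.vector(mouseEEG:::band_noise(n, fs, 35, 80, 8))
    c(sum = pw(burst + noise), parts = pw(burst) + pw(noise))
  })
  expect_equal(mean(reps["sum", ]) / mean(reps["parts", ]), 1,
               tolerance = 0.05)
})

test_that("basal power recovers variance scaling and stationarity", {
  cfg <- quiet_cfg()
  cfg$basal$gamma_sd_uV <- 8
  ev <- event_table(seq(5000, 200000, 2000), "click1", fs = 1000)

  bg1 <- generate_background(205, cfg, seed = 51)
  b1 <- basal_power(bg1, ev, gamma_band())

  # noiseless recording: basal power ~ 0
  b0 <- basal_power(generate_background(205, quiet_cfg(), seed = 1), ev,
                    gamma_band())
  expect_lt(b0, 1e-20)

  # variance doubled -> basal power ratio ~ 2 (100 trials)
  cfg2 <- cfg
  cfg2$basal$gamma_sd_uV <- 8 * sqrt(2)
  b2 <- basal_power(generate_background(205, cfg2, seed = 52), ev,
                    gamma_band())
  expect_equal(b2 / b1, 2, tolerance = 0.1)

  # stationarity: basal bin equals whole-recording mean of the same process
  w <- mouseEEG:::whole_recording_band_power(bg1, gamma_band())
  expect_equal(b1 / w, 1, tolerance = 0.05)

  expect_error(basal_power(bg1, event_table(100, "click1", fs = 1000),
                           gamma_band()), "outside")
})

test_that("evoked power isolates the stimulus-locked burst from basal power", {
  p <- make_paired_click_protocol(30, 0.5, 3, 1000)
  osc_of <- function(burst_uV, basal_sd) {
    cfg <- quiet_cfg(evoked_gamma = list(freq_hz = 50, amplitude_uV = burst_uV,
                                         center_ms = 20, sigma_ms = 10),
                     seed = 77)
    cfg$basal$gamma_sd_uV <- basal_sd
    cfg$erp_components <- list()   # no deflections: isolate burst vs basal
    rec <- render_session(p, cfg)
    ev1 <- rec$events[rec$events$label == "click1", ]
    bp <- basal_power(rec, ev1, gamma_band())
    ep <- baseline_correct(segment(rec, ev1, pre_ms = 1000, post_ms = 1200))
    evoked_band_power(ep, gamma_band(), bp, p1_latency_ms = 20)$evoked
  }
  # stationary noise only: evoked ~ 0 relative to the burst condition
  e_none <- osc_of(0, 8)
  e_small <- osc_of(25, 8)
  e_big <- osc_of(50, 8)
  expect_lt(abs(e_none), 0.15 * e_small)
  expect_gt(e_small, 0)
  expect_gt(e_big, 2 * e_small)          # monotone (quadratic-ish) in amplitude

  # basal-only scaling leaves evoked power unchanged within sampling error
  e_basal2 <- osc_of(25, 8 * sqrt(2))
  expect_equal(e_basal2 / e_small, 1, tolerance = 0.2)
})

test_that("whole-recording normalization is scale-invariant with trivial anchors", {
  cfg <- quiet_cfg()
  cfg$basal$gamma_sd_uV <- 8
  rec <- generate_background(60, cfg, seed = 12)
  w <- mouseEEG:::whole_recording_band_power(rec, gamma_band())
  expect_equal(normalize_to_recording(w, rec, gamma_band()), 1)
  expect_equal(normalize_to_recording(0, rec, gamma_band()), 0)

  rec2 <- rec
  rec2$data <- rec$data * 2
  expect_equal(normalize_to_recording(4 * w, rec2, gamma_band()),
               normalize_to_recording(w, rec, gamma_band()), tolerance = 1e-9)

  short <- generate_background(5, cfg, seed = 1)
  expect_error(normalize_to_recording(w, short, gamma_band()), "10 s")
  silent <- generate_background(60, quiet_cfg(), seed = 1)
  expect_error(normalize_to_recording(1, silent, gamma_band()), "undefined")
})
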