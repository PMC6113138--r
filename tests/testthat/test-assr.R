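make_assr_epochs <- function(n_trials, phases, amp = 1, fs = 1000,
                             noise_sd = 0, trial_ms = 2000) {
  tt <- seq(0, (trial_ms + 800) / 1000 - 1 / fs, 1 / fs)
  m <- t(vapply(seq_len(n_trials), function(i)
    amp[(i - 1) %% length(amp) + 1] *
      sin(2 * pi * 40 * (tt - 0.4) + phases[(i - 1) %% length(phases) + 1]) +
      rnorm(length(tt), 0, noise_sd), numeric(length(tt))))
  ep <- epochs_from_matrix(m, fs = fs, pre_ms = 400)
  attr(ep, "trial_ms") <- trial_ms
  ep
}

test_that("band-pass is zero-phase, passes 40 Hz and rejects DC/20/80 Hz", {
  fs <- 1000
  tt <- seq(0, 10, 1 / fs)
  mk_rec <- function(x) eeg_recording(rbind(x, x), fs,
                                      channel_labels = c("EEG1", "EEG2"))
  resp <- function(f) {
    rec <- assr_bandpass(mk_rec(sin(2 * pi * f * tt)))
    mid <- 3000:8000
    max(abs(rec$data[1, mid]))
  }
  expect_gt(resp(40), 0.95)
  expect_lt(resp(20), 0.5)
  expect_lt(resp(80), 0.5)

  # DC killed
  recdc <- assr_bandpass(mk_rec(rep(1, length(tt))))
  expect_lt(max(abs(recdc$data[1, 3000:8000])), 1e-6)

  # zero phase: 40 Hz peak position unshifted by more than 1 sample
  x <- sin(2 * pi * 40 * tt)
  recf <- assr_bandpass(mk_rec(x))
  win <- 5000:5100
  expect_lte(abs(which.max(recf$data[1, win]) - which.max(x[win])), 1)

  # forward-backward filtering of an impulse is symmetric
  imp <- rep(0, 2001); imp[1001] <- 1
  reci <- assr_bandpass(mk_rec(imp))
  h <- reci$data[1, ]
  expect_equal(h[1001 + 1:300], h[1001 - 1:300], tolerance = 1e-9)

  expect_error(assr_bandpass(mk_rec(x), center_hz = 600), "fs/2")
})

test_that("ASSR epoching yields 2.8 s epochs around train onsets", {
  pa <- make_assr_protocol(100, 2, 40, 3, 1000)
  cfg <- quiet_cfg(assr = list(amplitude_uV = 25, phase_jitter_rad_sd = 0))
  rec <- render_session(pa, cfg, lead_in_s = 1, tail_s = 1)
  ep <- segment_assr(rec)
  expect_equal(dim(ep$data)[1], 100)
  expect_equal(dim(ep$data)[3], 2800)
})

test_that("ASSR power is quadratic in amplitude and phase-blind", {
  ep1 <- make_assr_epochs(10, phases = 0, amp = 1)
  ep2 <- make_assr_epochs(10, phases = 0, amp = 2)
  expect_equal(assr_power(ep2) / assr_power(ep1), 4, tolerance = 1e-6)

  # zero entrainment, zero noise
  ep0 <- make_assr_epochs(4, phases = 0, amp = 0)
  expect_equal(assr_power(ep0), 0)

  # fixed amplitude, phases scrambled: power unchanged
  set.seed(9)
  epj <- make_assr_epochs(50, phases = rnorm(50, 0, 1), amp = 1)
  expect_equal(assr_power(epj) / assr_power(make_assr_epochs(50, 0, 1)), 1,
               tolerance = 0.02)
})

test_that("ITC spans its closed-form anchors", {
  # identical trials: exactly phase-locked
  ep <- make_assr_epochs(10, phases = 0)
  expect_equal(assr_itc(ep)$itc_40hz, 1, tolerance = 1e-9)

  # two trials in antiphase cancel
  ep2 <- make_assr_epochs(2, phases = c(0, pi))
  expect_lt(assr_itc(ep2)$itc_40hz, 1e-6)

  # Gaussian jitter sigma: E|mean e^{i phi}| = exp(-sigma^2/2)
  set.seed(11)
  sg <- 0.5
  ep3 <- make_assr_epochs(500, phases = rnorm(500, 0, sg))
  mc_sd <- sqrt((1 - exp(-sg^2)) / (2 * 500))
  expect_lt(abs(assr_itc(ep3)$itc_40hz - exp(-sg^2 / 2)), 3 * mc_sd + 0.01)

  # uniform phases, 100 trials: Rayleigh resultant expectation ~ sqrt(pi/4n)
  set.seed(12)
  vals <- replicate(12, {
    epu <- make_assr_epochs(100, phases = runif(100, 0, 2 * pi))
    assr_itc(epu)$itc_40hz
  })
  expect_equal(mean(vals), sqrt(pi / 400), tolerance = 0.25)

  expect_error(assr_itc(make_assr_epochs(1, 0)), ">= 2")
})

test_that("ITC is invariant to common rotation and amplitude scaling", {
  set.seed(13)
  ph <- rnorm(40, 0, 0.7)
  base <- assr_itc(make_assr_epochs(40, phases = ph))$itc_40hz
  rot <- assr_itc(make_assr_epochs(40, phases = ph + 1.1))$itc_40hz
  expect_equal(rot, base, tolerance = 1e-6)
  scl <- assr_itc(make_assr_epochs(40, phases = ph,
                                   amp = runif(40, 0.5, 3)))$itc_40hz
  expect_equal(scl, base, tolerance = 1e-6)
  expect_true(base >= 0 && base <= 1)
})

test_that("ITC decreases monotonically with phase-jitter spread", {
  set.seed(14)
  itcs <- vapply(c(0, 0.25, 0.5, 1.0, 2.0), function(sg) {
    ep <- make_assr_epochs(500, phases = if (sg == 0) 0 else rnorm(500, 0, sg))
    assr_itc(ep)$itc_40hz
  }, 0)
  expect_true(all(diff(itcs) < 0))
})

test_that("power and ITC are functionally independent axes", {
  set.seed(15)
  ph <- rnorm(60, 0, 0.5)
  p_a1 <- assr_power(make_assr_epochs(60, ph, amp = 1))
  p_a2 <- assr_power(make_assr_epochs(60, ph, amp = 2))
  i_a1 <- assr_itc(make_assr_epochs(60, ph, amp = 1))$itc_40hz
  i_a2 <- assr_itc(make_assr_epochs(60, ph, amp = 2))$itc_40hz
  expect_equal(p_a2 / p_a1, 4, tolerance = 0.01)   # amplitude moves power...
  expect_equal(i_a2, i_a1, tolerance = 1e-9)       # ...but not ITC
  ph2 <- rnorm(60, 0, 1.5)
  p_j <- assr_power(make_assr_epochs(60, ph2, amp = 1))
  i_j <- assr_itc(make_assr_epochs(60, ph2, amp = 1))$itc_40hz
  expect_equal(p_j / p_a1, 1, tolerance = 0.05)    # jitter leaves power...
  expect_lt(i_j, i_a1 - 0.2)                       # ...but lowers ITC
})
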