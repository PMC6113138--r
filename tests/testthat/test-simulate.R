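test_that("background noise has the requested scale, spectrum and determinism", {
  cfg0 <- quiet_cfg()
  expect_equal(max(abs(generate_background(10, cfg0)$data)), 0)

  cfgw <- sim_config(noise = list(spectrum = "white", sd_uV = 20),
                     basal = list(gamma_sd_uV = 0, theta_sd_uV = 0))
  bg <- generate_background(60, cfgw, seed = 11)
  expect_lt(abs(sd(bg$data[1, ]) - 20) / 20, 0.05)

  # determinism under a fixed seed
  a <- generate_background(5, cfgw, seed = 3)
  b <- generate_background(5, cfgw, seed = 3)
  expect_identical(a$data, b$data)

  expect_error(generate_background(0, cfg0), "duration")
})

test_that("pink background follows a 1/f power spectrum over 1-100 Hz", {
  cfgp <- sim_config(noise = list(spectrum = "pink", sd_uV = 20),
                     basal = list(gamma_sd_uV = 0, theta_sd_uV = 0))
  bg <- generate_background(120, cfgp, seed = 5)
  x <- bg$data[1, ]
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * 1000 / n
  keep <- f >= 1 & f <= 100
  fit <- lm(log(P[keep]) ~ log(f[keep]))
  expect_lt(abs(coef(fit)[2] + 1), 0.15)   # PSD slope ~ -1
})

test_that("noiseless render reproduces the configured N1 and drug scaling", {
  p <- make_paired_click_protocol(5, 0.5, 2, 1000)
  rec <- render_session(p, n1_only_cfg(-150))
  ep <- baseline_correct(segment(rec, label = "click1"))
  m <- measure_n1(average_erp(ep))
  expect_equal(m$n1_amplitude_uV, -150, tolerance = 1e-6)
  expect_equal(m$n1_latency_ms, 40)

  # n1_scale 0.6 -> trough 0.6x baseline
  rec2 <- render_session(p, n1_only_cfg(-150),
                         effect = drug_effect(n1_scale = 0.6))
  m2 <- measure_n1(average_erp(baseline_correct(segment(rec2, label = "click1"))))
  expect_equal(m2$n1_amplitude_uV / m$n1_amplitude_uV, 0.6, tolerance = 1e-6)
})

test_that("identity drug effect reproduces the baseline render bit-exactly", {
  p <- make_paired_click_protocol(3, 0.5, 2, 1000)
  cfg <- sim_config(seed = 9)
  base <- render_session(p, cfg)
  ident <- render_session(p, cfg, effect = drug_effect())
  expect_identical(base$data, ident$data)
})

test_that("noise and signal streams are additive under a shared seed", {
  p <- make_paired_click_protocol(3, 0.5, 2, 1000)
  cfg_full <- sim_config(noise = list(spectrum = "pink", sd_uV = 15),
                         basal = list(gamma_sd_uV = 5, theta_sd_uV = 5),
                         seed = 21)
  cfg_sig <- quiet_cfg(seed = 21)
  cfg_sig$erp_components <- cfg_full$erp_components
  cfg_sig$evoked_gamma <- cfg_full$evoked_gamma
  full <- render_session(p, cfg_full)
  signal_only <- render_session(p, cfg_sig)
  noise_only <- generate_background(ncol(full$data) / 1000, cfg_full,
                                    seed = mouseEEG:::derive_seed(21, 101))
  recon <- signal_only$data[1:2, ] + noise_only$data
  expect_equal(recon, full$data[1:2, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ASSR render with zero jitter and noise phase-locks perfectly", {
  pa <- make_assr_protocol(10, 2, 40, 2, 1000)
  cfg <- quiet_cfg(assr = list(amplitude_uV = 25, phase_jitter_rad_sd = 0))
  rec <- render_session(pa, cfg, lead_in_s = 1, tail_s = 1)
  res <- assr_itc(segment_assr(rec))
  expect_equal(res$itc_40hz, 1, tolerance = 1e-9)
})

test_that("cohort simulation books one recording per animal x treatment", {
  p <- make_paired_click_protocol(1, 0.5, 2, 1000)
  effects <- list(veh = drug_effect(), dose1 = drug_effect(n1_scale = 0.5))
  cfg <- n1_only_cfg(-150)
  recs <- simulate_cohort(12, c("veh", "dose1"), p, cfg, effects)
  expect_length(recs, 24)
  expect_equal(sum(vapply(recs, function(r) r$meta$treatment == "veh", TRUE)), 12)

  expect_error(simulate_cohort(12, c("veh", "unknown"), p, cfg, effects),
               "unknown")
  expect_error(simulate_cohort(1, "veh", p, cfg, effects), "n_animals")

  # zero offset sd: all animals identical under noiseless settings
  cfg0 <- n1_only_cfg(-150)
  cfg0$animal_offsets_sd <- 0
  recs0 <- simulate_cohort(3, "veh", p, cfg0, effects)
  n1s <- vapply(recs0, function(r)
    measure_n1(average_erp(baseline_correct(segment(r))))$n1_amplitude_uV, 0)
  expect_equal(n1s, rep(n1s[1], 3))
})

test_that("animal offsets of sd 0.2 spread N1 by about 20% of the mean", {
  # Monte Carlo over 200 animals, noiseless single-click sessions
  p <- make_paired_click_protocol(1, 0.5, 2, 1000)
  cfg <- n1_only_cfg(-150, seed = 33)
  recs <- simulate_cohort(200, "veh", p, cfg, list(veh = drug_effect()),
                          lead_in_s = 1, tail_s = 1)
  n1s <- vapply(recs, function(r)
    measure_n1(average_erp(baseline_correct(segment(r))))$n1_amplitude_uV, 0)
  cv <- sd(n1s) / abs(mean(n1s))
  expect_gt(cv, 0.15)
  expect_lt(cv, 0.27)
})

test_that("events beyond a forced duration raise a generation error", {
  p <- make_paired_click_protocol(3, 0.5, 2, 1000)
  expect_error(render_session(p, n1_only_cfg(), duration_s = 4),
               "does not fit")
})
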