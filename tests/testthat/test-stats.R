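sim_null_table <- function(n_animals = 12, treatments = c("vehicle_baseline",
                                                          "d1", "d2", "d3"),
                           tau = 1, sigma = 1, delta = setNames(
                             numeric(length(treatments)), treatments)) {
  a <- rep(seq_len(n_animals), each = length(treatments))
  trt <- rep(treatments, n_animals)
  intercept <- rnorm(n_animals, 10, tau)[a]
  biomarker_table(data.frame(
    animal_id = sprintf("m%02d", a), treatment = trt, protocol = "erp",
    parameter = "n1_amp",
    value = intercept + delta[trt] + rnorm(length(a), 0, sigma),
    stringsAsFactors = FALSE))
}

test_that("Bonferroni family levels match the dose x parameter arithmetic", {
  expect_equal(bonferroni_alpha(1, 6), 0.05 / 6)
  expect_equal(bonferroni_alpha(1, 2), 0.025)
  expect_equal(bonferroni_alpha(3, 6), 0.05 / 18)
  expect_equal(bonferroni_alpha(3, 2), 0.05 / 6)
  expect_equal(bonferroni_alpha(1, 1), 0.05)
  expect_equal(bonferroni_alpha(3, 1), 0.05 / 3)
  expect_error(bonferroni_alpha(0, 6), ">= 1")
})

test_that("contrast summaries flag dose and washout tests at their own levels", {
  df <- data.frame(parameter = "n1_amp",
                   contrast = c("d1 - vehicle_baseline",
                                "vehicle_washout - vehicle_baseline"),
                   treatment = c("d1", "vehicle_washout"),
                   estimate = c(1, 1), conf_low = c(0, 0),
                   conf_high = c(2, 2), df = c(11, 11),
                   p_value = c(0.004, 0.03),
                   is_washout = c(FALSE, TRUE), method = "lmm_satterthwaite")
  class(df) <- c("contrast_result", "data.frame")

  s1 <- summarize_contrasts(df, alpha_star = 0.008333)
  expect_true(s1$significant[1])    # 0.004 < 0.05/6
  expect_true(s1$significant[2])    # washout judged at 0.05 regardless

  s2 <- summarize_contrasts(df, alpha_star = 0.002777)
  expect_false(s2$significant[1])   # 0.004 not below 0.05/18
  expect_true(s2$significant[2])
})

test_that("identical values per animal give a zero estimate with p near 1", {
  set.seed(2)
  v <- rnorm(8, 100, 10)
  bt <- biomarker_table(data.frame(
    animal_id = rep(sprintf("m%d", 1:8), 2),
    treatment = rep(c("vehicle_baseline", "d1"), each = 8),
    protocol = "erp", parameter = "n1_amp", value = rep(v, 2)))
  res <- suppressWarnings(fit_contrasts(bt, "n1_amp"))
  expect_equal(res$estimate, 0, tolerance = 1e-8)
  expect_gt(res$p_value, 0.99)
  expect_true(res$conf_low <= res$estimate & res$estimate <= res$conf_high)
})

test_that("estimates absorb animal relabeling and per-animal constant shifts", {
  set.seed(3)
  bt <- sim_null_table(delta = c(vehicle_baseline = 0, d1 = 2, d2 = 0, d3 = 0))
  r0 <- fit_contrasts(bt, "n1_amp")

  # relabel animals
  bt2 <- bt
  bt2$animal_id <- factor(bt2$animal_id,
                          labels = sample(sprintf("x%02d", 1:12)))
  r1 <- fit_contrasts(bt2, "n1_amp")
  expect_equal(r1$estimate, r0$estimate, tolerance = 1e-8)
  expect_equal(r1$p_value, r0$p_value, tolerance = 1e-6)

  # add a constant to one animal's values: absorbed by its intercept
  bt3 <- bt
  sel <- bt3$animal_id == "m01"
  bt3$value[sel] <- bt3$value[sel] + 50
  r2 <- fit_contrasts(bt3, "n1_amp")
  expect_equal(r2$estimate, r0$estimate, tolerance = 1e-6)
})

test_that("an injected shift is recovered with near-nominal CI coverage", {
  set.seed(4)
  shift <- -0.5
  hits <- 0; n_rep <- 120
  for (i in seq_len(n_rep)) {
    bt <- sim_null_table(treatments = c("vehicle_baseline", "d1"),
                         delta = c(vehicle_baseline = 0, d1 = shift))
    r <- suppressWarnings(fit_contrasts(bt, "n1_amp"))
    hits <- hits + (r$conf_low <= shift && shift <= r$conf_high)
  }
  expect_gte(hits / n_rep, 0.90)   # nominal 0.95, binomial noise at 120 reps
})

test_that("the model falls back to a paired fixed-effects fit when singular", {
  set.seed(3)
  bt <- sim_null_table(tau = 0)       # no between-animal variance
  expect_warning(r <- fit_contrasts(bt, "n1_amp"), "fixed-effects")
  expect_equal(r$method, rep("fixed_effects_block", 3))
  expect_equal(nrow(r), 3)
})

test_that("input validation catches degenerate designs", {
  bt <- sim_null_table()
  expect_error(fit_contrasts(bt, "nope"), "no rows")
  one_trt <- biomarker_table(bt[bt$treatment == "vehicle_baseline", ])
  expect_error(fit_contrasts(one_trt, "n1_amp"), "2 treatments")
  expect_error(biomarker_table(data.frame(animal_id = 1)), "columns")
  dup <- rbind(as.data.frame(bt), as.data.frame(bt)[1, ])
  expect_error(biomarker_table(dup), "more than one value")
})
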