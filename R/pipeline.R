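#' Default demonstration configuration
#'
#' A desk-scale cohort that reproduces the qualitative dose-response
#' pattern of a high-dose NMDA-receptor antagonist: 12 animals, vehicle
#' baseline plus one active treatment, and session sizes reduced from the
#' full protocols (40 click pairs with a 5 s inter-pair interval instead
#' of 300 pairs at 10 s; 30 ASSR trains with a 4 s inter-train interval
#' instead of 100 at 30 s; 30 oddball cycles instead of 600) so a full
#' run completes in minutes.  The full-session parameters remain the
#' defaults of the `make_*_protocol` generators.
#'
#' @param seed master seed for the run.
#' @return a nested configuration list for [run_experiment()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(),                       # extra sim_config() arguments
    cohort = list(
      n_animals = 12,
      treatments = c("vehicle_baseline", "drug_high"),
      effects = list(
        vehicle_baseline = drug_effect(),
        drug_high = drug_effect(n1_scale = 0.5, basal_gamma_scale = 2,
                                evoked_gamma_scale = 0.4, theta_scale = 1,
                                assr_amp_scale = 0.5,
                                assr_jitter_add_rad = 1.0, mmn_scale = 0.3))
    ),
    protocols = list(
      erp  = list(n_pairs = 40, intra_pair_s = 0.5, inter_pair_s = 5),
      assr = list(n_trains = 30, train_s = 2, rate_hz = 40, iti_s = 4),
      mmn  = list(n_cycles = 30, deviant_period = 20, tone_s = 0.05,
                  isi_s = 0.5, f_std = 9000, f_dev = 12000,
                  flip_flop = TRUE)
    ),
    screens = list(min_p1n1_uV = 100, mmn_ratio_threshold = 0.5),
    stats = list(baseline = "vehicle_baseline",
                 washout = "vehicle_washout",
                 family_alpha = 0.05,
                 n_parameters = c(erp = 6, assr = 2, mmn = 1))
  )
}

validate_config <- function(config) {
  for (f in c("seed", "cohort", "protocols", "stats"))
    if (is.null(config[[f]]))
      stop("config is missing the '", f, "' field", call. = FALSE)
  for (p in c("erp", "assr", "mmn"))
    if (is.null(config$protocols[[p]]))
      stop("config is missing the 'protocols$", p, "' block", call. = FALSE)
  for (f in c("n_animals", "treatments", "effects"))
    if (is.null(config$cohort[[f]]))
      stop("config is missing the 'cohort$", f, "' field", call. = FALSE)
  invisible(config)
}

#' Run the full simulate-analyze-model experiment
#'
#' Simulates one cohort per protocol (the same animals, i.e. the same
#' per-animal offsets, across protocols), runs the four analysis stages,
#' applies the baseline inclusion screens (100 µV P1N1 for the ERP
#' readouts; standard/deviant ratio >= 0.5 for the MMN readout), fits the
#' mixed-model treatment contrasts per parameter, and flags significance
#' at the protocol family's Bonferroni-corrected level.  Deterministic
#' under a fixed seed.  When `out_dir` is given, writes
#' `biomarkers.csv`, `contrasts.csv` and `manifest.json` (plus per-animal
#' event tables and EDFs when `write_recordings`).
#'
#' @param config a configuration list, see [default_config()].
#' @param out_dir optional output directory (created if needed).
#' @param write_recordings also write each recording as EDF + event TSV.
#' @return list with `biomarkers` (a [biomarker_table()]), `contrasts`
#'   (with significance flags), `excluded` (animals dropped by screens),
#'   and `alpha_star` per protocol.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           write_recordings = FALSE) {
  validate_config(config)
  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  coh <- config$cohort
  baseline <- config$stats$baseline
  washout <- config$stats$washout
  doses <- setdiff(coh$treatments, c(baseline, washout))
  if (!length(doses)) stop("no dose treatment in the cohort", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  protos <- list(
    erp  = do.call(make_paired_click_protocol,
                   c(config$protocols$erp, list(fs = cfg$fs))),
    assr = do.call(make_assr_protocol,
                   c(config$protocols$assr, list(fs = cfg$fs))),
    mmn  = do.call(make_oddball_protocol,
                   c(config$protocols$mmn, list(fs = cfg$fs)))
  )

  rows <- list()
  extras <- list()
  excluded <- list(erp = character(0), mmn = character(0))
  add_row <- function(animal, trt, proto, param, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      animal_id = animal, treatment = trt, protocol = proto,
      parameter = param, value = value, stringsAsFactors = FALSE)

  for (proto in names(protos)) {
    recs <- simulate_cohort(coh$n_animals, coh$treatments, protos[[proto]],
                            cfg, coh$effects)
    for (rec in recs) {
      a <- rec$meta$animal_id; trt <- rec$meta$treatment
      if (write_recordings && !is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("%s_%s_%s", proto, a, trt))
        write_edf(rec, paste0(stem, ".edf"))
        write_event_table(rec$events, paste0(stem, "_events.tsv"))
      }
      if (proto == "erp") {
        erp <- analyze_erp(rec)
        osc <- analyze_oscillations(rec, p1_latency_ms = erp$click1$p1_latency_ms)
        if (trt == baseline && !erp$included)
          excluded$erp <- c(excluded$erp, a)
        add_row(a, trt, proto, "n1_amp", erp$n1_amp_uV)
        add_row(a, trt, proto, "gating_ratio", erp$gating_ratio)
        add_row(a, trt, proto, "basal_gamma", osc$basal_gamma)
        add_row(a, trt, proto, "evoked_gamma", osc$evoked_gamma)
        add_row(a, trt, proto, "basal_theta", osc$basal_theta)
        add_row(a, trt, proto, "evoked_theta", osc$evoked_theta)
        extras[[length(extras) + 1L]] <- data.frame(
          animal_id = a, treatment = trt,
          basal_gamma_norm = osc$basal_gamma_norm,
          evoked_gamma_norm = osc$evoked_gamma_norm,
          basal_theta_norm = osc$basal_theta_norm,
          evoked_theta_norm = osc$evoked_theta_norm,
          n_kept_trials = erp$n_kept_trials, stringsAsFactors = FALSE)
      } else if (proto == "assr") {
        res <- analyze_assr(rec)
        add_row(a, trt, proto, "assr_power", res$assr_power)
        add_row(a, trt, proto, "assr_itc", res$assr_itc)
      } else {
        res <- analyze_mmn(rec)
        if (trt == baseline && !res$robust)
          excluded$mmn <- c(excluded$mmn, a)
        add_row(a, trt, proto, "mmn_auc_abs", abs(res$auc))
      }
    }
  }

  bm <- do.call(rbind, rows)
  # apply baseline screens across all treatments of the flagged animals
  bm <- bm[!(bm$protocol == "erp" & bm$animal_id %in% excluded$erp), ]
  bm <- bm[!(bm$protocol == "mmn" & bm$animal_id %in% excluded$mmn), ]
  bm <- biomarker_table(bm)

  n_par <- config$stats$n_parameters
  alpha_star <- vapply(names(protos), function(p)
    bonferroni_alpha(length(doses), n_par[[p]], config$stats$family_alpha), 0)

  contr <- list()
  for (p in unique(bm$parameter)) {
    proto <- bm$protocol[bm$parameter == p][1]
    cc <- fit_contrasts(bm, p, baseline = baseline, washout = washout)
    cc <- summarize_contrasts(cc, alpha_star[[proto]])
    cc$protocol <- proto
    contr[[p]] <- cc
  }
  contrasts <- do.call(rbind, contr)
  rownames(contrasts) <- NULL
  class(contrasts) <- c("contrast_result", "data.frame")

  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(bm),
                     file.path(out_dir, "biomarkers.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(contrasts),
                     file.path(out_dir, "contrasts.csv"), row.names = FALSE)
    manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("mouseEEG")),
      n_animals = coh$n_animals, treatments = coh$treatments,
      protocols = config$protocols,
      excluded = excluded,
      alpha_star = as.list(alpha_star))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(biomarkers = bm, contrasts = contrasts, excluded = excluded,
       alpha_star = alpha_star)
}
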