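#' Biomarker table
#'
#' Tidy per-animal, per-treatment readouts feeding the mixed-model layer:
#' one row per animal x treatment x parameter with columns `animal_id`,
#' `treatment`, `protocol`, `parameter`, `value`.
#'
#' @param df a data.frame with those columns.
#' @return the validated data.frame with class `biomarker_table`.
#' @export
biomarker_table <- function(df) {
  need <- c("animal_id", "treatment", "protocol", "parameter", "value")
  if (!all(need %in% names(df)))
    stop("biomarker table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dup <- duplicated(df[c("animal_id", "treatment", "parameter")])
  if (any(dup))
    stop("more than one value per animal x treatment x parameter",
         call. = FALSE)
  class(df) <- unique(c("biomarker_table", class(df)))
  df
}

#' Mixed-model treatment contrasts for one parameter
#'
#' Fits a linear mixed model with a random intercept per animal and
#' treatment as a fixed factor, then estimates each treatment level
#' against the vehicle-at-baseline reference: every dose vs. baseline and
#' washout vs. baseline.  P-values and degrees of freedom use the
#' Satterthwaite small-sample approximation; two-sided confidence
#' intervals at level `conf_level`.  When the between-animal variance is
#' estimated as zero (singular fit) the function falls back, with a
#' warning, to the equivalent fixed-effects analysis with animal as a
#' blocking factor.
#'
#' @param table a [biomarker_table()].
#' @param parameter which parameter to analyze.
#' @param baseline reference treatment label.
#' @param washout label of the washout check contrast (exempt from the
#'   Bonferroni family).
#' @param conf_level confidence level for the two-sided intervals.
#' @return a data.frame of class `contrast_result` with one row per
#'   non-reference treatment: `parameter`, `contrast`, `estimate`,
#'   `conf_low`, `conf_high`, `df`, `p_value`, `is_washout`, `method`.
#' @export
fit_contrasts <- function(table, parameter,
                          baseline = "vehicle_baseline",
                          washout = "vehicle_washout",
                          conf_level = 0.95) {
  stopifnot(inherits(table, "biomarker_table"))
  d <- table[table$parameter == parameter, , drop = FALSE]
  if (!nrow(d)) stop("no rows for parameter ", parameter, call. = FALSE)
  if (length(unique(d$animal_id)) < 2)
    stop("need >= 2 animals", call. = FALSE)
  if (length(unique(d$treatment)) < 2)
    stop("need >= 2 treatments", call. = FALSE)
  if (!baseline %in% d$treatment)
    stop("baseline treatment '", baseline, "' absent from the data",
         call. = FALSE)
  d$treatment <- stats::relevel(factor(d$treatment), ref = baseline)
  d$animal_id <- factor(d$animal_id)

  fit <- suppressMessages(
    lmerTest::lmer(value ~ treatment + (1 | animal_id), data = d))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (!singular) {
    ct <- stats::coef(summary(fit))
    method <- "lmm_satterthwaite"
  } else {
    warning("zero between-animal variance: falling back to the fixed-effects",
            " paired analysis")
    lmfit <- stats::lm(value ~ animal_id + treatment, data = d)
    s <- stats::coef(summary(lmfit))
    rows <- grepl("^treatment", rownames(s))
    ct <- cbind(s[, 1:3, drop = FALSE],
                df = stats::df.residual(lmfit),
                s[, 4, drop = FALSE])[rows, , drop = FALSE]
    colnames(ct) <- c("Estimate", "Std. Error", "t value", "df", "Pr(>|t|)")
    rownames(ct) <- rownames(s)[rows]
    method <- "fixed_effects_block"
  }
  rows <- grepl("^treatment", rownames(ct))
  ct <- ct[rows, , drop = FALSE]
  lev <- sub("^treatment", "", rownames(ct))
  alpha <- 1 - conf_level
  tq <- stats::qt(1 - alpha / 2, df = ct[, "df"])
  res <- data.frame(
    parameter = parameter,
    contrast = sprintf("%s - %s", lev, baseline),
    treatment = lev,
    estimate = ct[, "Estimate"],
    conf_low = ct[, "Estimate"] - tq * ct[, "Std. Error"],
    conf_high = ct[, "Estimate"] + tq * ct[, "Std. Error"],
    df = ct[, "df"],
    p_value = ct[, "Pr(>|t|)"],
    is_washout = lev == washout,
    method = method,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Bonferroni-corrected significance level for a dose x parameter family
#'
#' The family is the set of dose contrasts across the parameters of one
#' protocol: `alpha* = family_alpha / (n_doses * n_parameters)`.  Washout
#' vs. baseline contrasts are a return-to-baseline check and are exempt
#' from the correction.
#'
#' @param n_doses number of tested dosages (>= 1).
#' @param n_parameters number of parameters in the protocol family (>= 1).
#' @param family_alpha family-wise level.
#' @return the corrected per-test level `alpha*`.
#' @export
bonferroni_alpha <- function(n_doses, n_parameters, family_alpha = 0.05) {
  if (n_doses < 1 || n_parameters < 1)
    stop("n_doses and n_parameters must be >= 1", call. = FALSE)
  family_alpha / (n_doses * n_parameters)
}

#' Flag contrast significance at the family-corrected level
#'
#' Dose contrasts are tested at `alpha_star`; washout contrasts at
#' `washout_alpha` (0.05), since the washout check is not part of the
#' Bonferroni family.
#'
#' @param contrasts a `contrast_result` (rows may cover several
#'   parameters).
#' @param alpha_star Bonferroni-corrected level for dose contrasts.
#' @param washout_alpha uncorrected level for the washout check.
#' @return the input with `adjusted_alpha` and `significant` columns.
#' @export
summarize_contrasts <- function(contrasts, alpha_star, washout_alpha = 0.05) {
  stopifnot(inherits(contrasts, "contrast_result"), nrow(contrasts) >= 1)
  contrasts$adjusted_alpha <- ifelse(contrasts$is_washout, washout_alpha,
                                     alpha_star)
  contrasts$significant <- contrasts$p_value < contrasts$adjusted_alpha
  contrasts
}

#' @export
print.contrast_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s | %s: Estimated difference: %.4g; confidence limits: %.4g to %.4g; P = %.4g",
                x$parameter[i], x$contrast[i], x$estimate[i],
                x$conf_low[i], x$conf_high[i], x$p_value[i]))
    if (!is.null(x$significant))
      cat(if (x$significant[i]) "  *" else "")
    cat("\n")
  }
  invisible(x)
}
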