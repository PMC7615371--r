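# Dose-response statistics for the volunteer arm and the mixed-effects
# heart-rate model for the clinical arm.

#' Spearman rank correlation between a segment metric and concentration
#'
#' Mid-rank ties, two-sided p-value (asymptotic).
#'
#' @param metric segment metric values.
#' @param ce paired segment-mean concentrations.
#' @return List with `rho` and `p_value` (`NA` for constant input).
#' @export
spearman_dose_response <- function(metric, ce) {
  ok <- is.finite(metric) & is.finite(ce)
  if (sum(ok) < 5) stop("spearman_dose_response requires >= 5 segments")
  if (sd(metric[ok]) == 0 || sd(ce[ok]) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(cor.test(metric[ok], ce[ok], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Ordinary least squares dose-response with 95% confidence intervals
#'
#' @param hr_segments segment-mean heart rates (or any response), bpm.
#' @param ce_segments paired segment-mean concentrations, ug/ml.
#' @return List with `intercept`, `slope`, `ci` (2x2 matrix), and the
#'   fitted `model`.
#' @export
linear_dose_response <- function(hr_segments, ce_segments) {
  ok <- is.finite(hr_segments) & is.finite(ce_segments)
  if (sum(ok) < 10) stop("linear_dose_response requires >= 10 points")
  if (sd(ce_segments[ok]) == 0) stop("degenerate design: constant predictor")
  fit <- lm(y ~ x, data = data.frame(y = hr_segments[ok],
                                     x = ce_segments[ok]))
  ci <- confint(fit, level = 0.95)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       ci = ci, model = fit)
}

#' Cohen's d effect size
#'
#' `(mean(group_b) - mean(group_a)) / pooled SD` with the usual
#' (n-1)-weighted pooled standard deviation.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return Cohen's d, or `NA` when the pooled SD is zero.
#' @export
effect_size_d <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("effect_size_d requires >= 2 values per group")
  pooled <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
  if (pooled == 0) return(NA_real_)
  (mean(b) - mean(a)) / pooled
}

#' Preprocess clinical heart-rate records
#'
#' Heart rates outside \[10, 250\] bpm are set to missing first; then each
#' patient's series is smoothed with a centered 2-minute moving median
#' that ignores missing values (25 samples at the 5 s sampling interval;
#' an odd width keeps the filter exact on locally monotone data).
#' Patients whose series is entirely missing are dropped with a warning.
#' The result carries `attr(, "smooth_window")` used by
#' [fit_clinical_glm()] for decorrelating thinning.
#'
#' @param table long-format clinical table from [simulate_clinical()] (or
#'   with the same columns).
#' @param window_s smoothing window length, s (default 120).
#' @return The table with smoothed `hr_bpm`.
#' @export
preprocess_clinical_hr <- function(table, window_s = 120) {
  stopifnot(all(c("patient_id", "t_s", "hr_bpm") %in% names(table)))
  si <- attr(table, "sample_interval")
  if (is.null(si)) si <- median(diff(sort(unique(table$t_s))))
  w <- round(window_s / si)
  if (w %% 2 == 0) w <- w + 1L
  hr <- table$hr_bpm
  hr[hr < 10 | hr > 250] <- NA_real_
  out <- table
  out$hr_bpm <- hr
  drop_ids <- character(0)
  for (id in unique(out$patient_id)) {
    sel <- out$patient_id == id
    x <- out$hr_bpm[sel]
    if (all(is.na(x))) { drop_ids <- c(drop_ids, id); next }
    sm <- zoo::rollapply(x, w, function(v)
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE),
      fill = NA, partial = TRUE, align = "center")
    out$hr_bpm[sel] <- sm
  }
  if (length(drop_ids)) {
    warning("dropping patient(s) with no valid heart rate: ",
            paste(drop_ids, collapse = ", "))
    out <- out[!out$patient_id %in% drop_ids, ]
  }
  attr(out, "smooth_window") <- w
  attr(out, "sample_interval") <- si
  attr(out, "truth_coeffs") <- attr(table, "truth_coeffs")
  out
}

#' Mixed-effects heart-rate model for the clinical arm
#'
#' Fits, by restricted maximum likelihood, the linear mixed model
#' `HR = b0 + b1*age + b2*BMI + b3*ASA + b4*(sex = F) + b5*prop +
#' b6*fent + b7*des + b8*prop*fent + b9*prop*des + b10*fent*des +
#' (1 | patient)` with ASA numeric (2/3) and a female indicator.
#' Confidence intervals are large-sample Wald intervals; degrees of
#' freedom and p-values come from the Satterthwaite method.
#'
#' Because the moving-median preprocessing makes neighbouring residuals
#' strongly dependent, the table is thinned to one observation per
#' smoothing window by default before fitting, so that per-observation
#' Wald intervals are approximately calibrated. Set `thin = 1` to use
#' every sample (the literal published procedure; its intervals are
#' anticonservative on smoothed data).
#'
#' @param table a (preferably preprocessed) clinical table.
#' @param thin keep every `thin`-th sample per patient; `NULL` (default)
#'   uses the preprocessing smooth window when present, else 1.
#' @return List of class `clinical_model_fit`: `coefficients`
#'   (data.frame with estimate, lower, upper, se, t, p per term),
#'   `ranef_sd`, `residual_sd`, `n_patients`, `n_obs`, `singular`, and
#'   the underlying `model`.
#' @export
fit_clinical_glm <- function(table, thin = NULL) {
  stopifnot(all(c("patient_id", "hr_bpm", "prop_ugml", "fent_ngml",
                  "des_pct", "age", "bmi", "asa", "sex") %in% names(table)))
  if (length(unique(table$patient_id)) < 2)
    stop("fit_clinical_glm requires >= 2 patients")
  if (is.null(thin)) thin <- attr(table, "smooth_window") %||% 1L
  df <- as.data.frame(table)
  if (thin > 1L) {
    # skip the half-window edges of each patient's series, where the
    # centered median runs on a partial window and is biased exactly
    # where the drug trajectories change fastest
    half <- ceiling(thin / 2)
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$patient_id),
                          function(i) {
                            i <- i[seq_along(i) > half &
                                     seq_along(i) <= length(i) - half]
                            i[seq(1L, length(i), by = thin)]
                          }),
                   use.names = FALSE)
    df <- df[sort(keep), ]
  }
  df <- df[is.finite(df$hr_bpm), ]
  df$sex_f <- as.numeric(df$sex == "F")
  fit <- lmerTest::lmer(
    hr_bpm ~ age + bmi + asa + sex_f + prop_ugml + fent_ngml + des_pct +
      prop_ugml:fent_ngml + prop_ugml:des_pct + fent_ngml:des_pct +
      (1 | patient_id),
    data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular mixed-model fit; random-intercept variance is on ",
            "the boundary")
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  coefs <- data.frame(
    term = c("intercept", "age", "bmi", "asa", "sex_f", "prop", "fent",
             "des", "prop_fent", "prop_des", "fent_des"),
    estimate = unname(est),
    lower = unname(est - 1.96 * se), upper = unname(est + 1.96 * se),
    se = unname(se), t = unname(sm[, "t value"]),
    p = unname(sm[, "Pr(>|t|)"]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 ranef_sd = vc$sdcor[vc$grp == "patient_id"],
                 residual_sd = vc$sdcor[vc$grp == "Residual"],
                 n_patients = length(unique(df$patient_id)),
                 n_obs = nrow(df), singular = singular, model = fit),
            class = "clinical_model_fit")
}

#' @export
print.clinical_model_fit <- function(x, ...) {
  cat(sprintf(
    "<clinical_model_fit: %d patients, %d obs, random intercept SD %.2f bpm>\n",
    x$n_patients, x$n_obs, x$ranef_sd))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Correlation between subject mean heart rate and slow-wave frequency
#'
#' @param hr_means per-subject mean heart rates, bpm.
#' @param sw_freq_means per-subject mean slow-wave frequencies, Hz.
#' @return List with `r` (Pearson) and `p_value`; `NA` for zero-variance
#'   input.
#' @export
hr_vs_sw_frequency <- function(hr_means, sw_freq_means) {
  ok <- is.finite(hr_means) & is.finite(sw_freq_means)
  if (sum(ok) < 4) stop("hr_vs_sw_frequency requires >= 4 subjects")
  if (sd(hr_means[ok]) == 0 || sd(sw_freq_means[ok]) == 0)
    return(list(r = NA_real_, p_value = NA_real_))
  ct <- cor.test(hr_means[ok], sw_freq_means[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
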