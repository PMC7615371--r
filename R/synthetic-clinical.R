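#' Configuration for the synthetic clinical cohort generator
#'
#' Study conditions for [simulate_clinical()]: a cohort of older surgical
#' patients whose heart rate, sampled every 5 seconds, follows a linear
#' model in demographics and effect-site drug concentrations (propofol,
#' fentanyl, desflurane, and their pairwise interactions) with a
#' per-patient random intercept, plus occasional monitor spike artifacts.
#' The eleven fixed-effect defaults are the fitted clinical coefficients.
#'
#' Drug trajectories are smooth on the 2-minute artifact-smoothing scale:
#' propofol decays exponentially from an induction level, desflurane rises
#' to a patient-specific maintenance level, and fentanyl follows repeated
#' boluses with a slow rise and decay.
#'
#' @param n_patients cohort size (>= 2).
#' @param coeffs named vector of the eleven fixed effects: intercept, age,
#'   bmi, asa, sex_f, prop, fent, des, prop_fent, prop_des, fent_des.
#' @param random_intercept_sd between-patient intercept SD, bpm.
#' @param residual_sd within-patient white measurement noise, bpm.
#' @param sample_interval sampling interval, s.
#' @param duration record length per patient, s.
#' @param artifact_rate expected spike artifacts (HR outside \[10, 250\])
#'   per hour per patient.
#' @param age_range,bmi_mean,bmi_sd,asa_levels,p_female demographics.
#' @param prop_init_range,prop_tau propofol: induction concentration range
#'   (ug/ml) and exponential decay constant (s).
#' @param des_level_range,des_tau desflurane: maintenance level range (%)
#'   and rise constant (s).
#' @param fent_bolus_interval,fent_bolus_amp,fent_rise_tau,fent_decay_tau
#'   fentanyl bolus schedule: interval (s), per-bolus amplitude range
#'   (ng/ml), rise and decay constants (s).
#' @param seed integer RNG seed.
#' @return A validated list of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(
    n_patients = 96,
    coeffs = c(intercept = 45.444, age = 0.213, bmi = 0.122, asa = 1.976,
               sex_f = 0.367, prop = 1.319, fent = -2.604, des = -1.838,
               prop_fent = 0.988, prop_des = -0.711, fent_des = 0.463),
    random_intercept_sd = 7, residual_sd = 2,
    sample_interval = 5, duration = 3600, artifact_rate = 6,
    age_range = c(61, 86), bmi_mean = 27, bmi_sd = 4,
    asa_levels = c(2, 3), p_female = 30 / 96,
    prop_init_range = c(2.5, 5), prop_tau = 1200,
    des_level_range = c(2, 7), des_tau = 300,
    fent_bolus_interval = 1500, fent_bolus_amp = c(0.8, 1.8),
    fent_rise_tau = 300, fent_decay_tau = 1800,
    seed = 1) {
  needed <- c("intercept", "age", "bmi", "asa", "sex_f", "prop", "fent",
              "des", "prop_fent", "prop_des", "fent_des")
  if (!all(needed %in% names(coeffs)))
    stop("coeffs must contain: ", paste(needed, collapse = ", "))
  cfg <- list(n_patients = n_patients, coeffs = coeffs[needed],
              random_intercept_sd = random_intercept_sd,
              residual_sd = residual_sd,
              sample_interval = sample_interval, duration = duration,
              artifact_rate = artifact_rate, age_range = age_range,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              asa_levels = asa_levels, p_female = p_female,
              prop_init_range = prop_init_range, prop_tau = prop_tau,
              des_level_range = des_level_range, des_tau = des_tau,
              fent_bolus_interval = fent_bolus_interval,
              fent_bolus_amp = fent_bolus_amp,
              fent_rise_tau = fent_rise_tau,
              fent_decay_tau = fent_decay_tau, seed = seed)
  if (cfg$n_patients < 2) stop("n_patients must be >= 2")
  if (cfg$residual_sd < 0) stop("residual_sd must be >= 0")
  if (cfg$sample_interval <= 0) stop("sample_interval must be > 0")
  structure(cfg, class = "clinical_sim_config")
}

clinical_linpred <- function(coeffs, df) {
  coeffs[["intercept"]] + coeffs[["age"]] * df$age +
    coeffs[["bmi"]] * df$bmi + coeffs[["asa"]] * df$asa +
    coeffs[["sex_f"]] * as.numeric(df$sex == "F") +
    coeffs[["prop"]] * df$prop_ugml + coeffs[["fent"]] * df$fent_ngml +
    coeffs[["des"]] * df$des_pct +
    coeffs[["prop_fent"]] * df$prop_ugml * df$fent_ngml +
    coeffs[["prop_des"]] * df$prop_ugml * df$des_pct +
    coeffs[["fent_des"]] * df$fent_ngml * df$des_pct
}

#' Simulate a long-format clinical heart-rate table
#'
#' Per patient: demographics and drug trajectories are drawn, the heart
#' rate is computed from the configured linear model plus a patient random
#' intercept and white residual noise, and spike artifacts (values outside
#' 10-250 bpm) are injected at the configured rate. Deterministic given
#' the config seed.
#'
#' @param config a [clinical_sim_config()].
#' @return data.frame with columns `patient_id`, `t_s`, `hr_bpm`,
#'   `prop_ugml`, `fent_ngml`, `des_pct`, `age`, `bmi`, `asa`, `sex`, plus
#'   attributes `truth_coeffs` and `truth_intercepts` for validation.
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "clinical_sim_config"))
  with_local_seed(config$seed, {
    tgrid <- seq(0, config$duration - config$sample_interval,
                 by = config$sample_interval)
    b_i <- rnorm(config$n_patients, 0, config$random_intercept_sd)
    rows <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      age <- round(runif(1, config$age_range[1], config$age_range[2]))
      bmi <- round(max(18, min(42, rnorm(1, config$bmi_mean, config$bmi_sd))),
                   1)
      asa <- sample(config$asa_levels, 1)
      sex <- if (runif(1) < config$p_female) "F" else "M"
      # per-patient trajectory timing is randomized so that drug
      # regressors are not collinear functions of elapsed time across
      # the cohort
      p0 <- runif(1, config$prop_init_range[1], config$prop_init_range[2])
      ptau <- config$prop_tau * runif(1, 0.75, 1.5)
      prop <- p0 * exp(-tgrid / ptau)
      dlevel <- runif(1, config$des_level_range[1], config$des_level_range[2])
      d0 <- runif(1, 0, 600)
      des <- ifelse(tgrid > d0,
                    dlevel * (1 - exp(-(tgrid - d0) / config$des_tau)), 0)
      bolus_t <- runif(1, 0, 300)
      while (tail(bolus_t, 1) < config$duration)
        bolus_t <- c(bolus_t, tail(bolus_t, 1) +
                       config$fent_bolus_interval * runif(1, 0.7, 1.3))
      fent <- numeric(length(tgrid))
      for (tb in bolus_t) {
        amp <- runif(1, config$fent_bolus_amp[1], config$fent_bolus_amp[2])
        dt <- tgrid - tb
        on <- dt >= 0
        fent[on] <- fent[on] + amp * (1 - exp(-dt[on] / config$fent_rise_tau)) *
          exp(-dt[on] / config$fent_decay_tau)
      }
      df <- data.frame(patient_id = sprintf("P%03d", i), t_s = tgrid,
                       prop_ugml = prop, fent_ngml = fent, des_pct = des,
                       age = age, bmi = bmi, asa = asa, sex = sex)
      df$hr_bpm <- clinical_linpred(config$coeffs, df) + b_i[i] +
        rnorm(length(tgrid), 0, config$residual_sd)
      n_art <- rpois(1, config$artifact_rate * config$duration / 3600)
      if (n_art > 0) {
        at <- sample(length(tgrid), min(n_art, length(tgrid)))
        hi <- runif(length(at)) < 0.5
        df$hr_bpm[at] <- ifelse(hi, runif(length(at), 251, 320),
                                runif(length(at), 0, 9))
      }
      rows[[i]] <- df
    }
    out <- do.call(rbind, rows)
    out <- out[, c("patient_id", "t_s", "hr_bpm", "prop_ugml", "fent_ngml",
                   "des_pct", "age", "bmi", "asa", "sex")]
    rownames(out) <- NULL
    attr(out, "truth_coeffs") <- config$coeffs
    attr(out, "truth_intercepts") <- b_i
    attr(out, "sample_interval") <- config$sample_interval
    out
  })
}
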