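test_that("rank and moment correlations match brute-force oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_dose_response(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_dose_response(x, -x)$rho, -1)
  expect_true(is.na(spearman_dose_response(rep(1, 5), x)$rho))
  set.seed(51)
  for (i in 1:15) {
    n <- sample(5:8, 1)
    a <- rnorm(n); b <- rnorm(n)
    # rank/moment oracle: Pearson formula applied to mid-ranks / values
    pearson <- function(u, v)
      sum((u - mean(u)) * (v - mean(v))) /
        sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
    expect_equal(spearman_dose_response(a, b)$rho,
                 pearson(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(hr_vs_sw_frequency(a, b)$r, pearson(a, b),
                 tolerance = 1e-12)
  }
})

test_that("linear dose-response interpolates noise-free data exactly", {
  x <- seq(0, 4, length.out = 12)
  y <- 56.1 + 4.23 * x
  fit <- suppressWarnings(linear_dose_response(y, x)) # perfect-fit warning
  expect_equal(fit$intercept, 56.1, tolerance = 1e-9)
  expect_equal(fit$slope, 4.23, tolerance = 1e-9)
  expect_error(linear_dose_response(y, rep(1, 12)), "degenerate")
})

test_that("Cohen's d matches hand computations", {
  expect_equal(effect_size_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(effect_size_d(c(0, 2), c(2, 4)), sqrt(2))
  expect_true(is.na(effect_size_d(c(1, 1), c(1, 1))))
  set.seed(52)
  a <- rnorm(50); b <- rnorm(50) + 1
  sp <- sqrt((49 * var(a) + 49 * var(b)) / 98)
  expect_equal(effect_size_d(a, b), (mean(b) - mean(a)) / sp)
})

test_that("clinical preprocessing suppresses artifacts and keeps smooth data", {
  tab <- data.frame(patient_id = "P001", t_s = seq(0, 1795, by = 5),
                    hr_bpm = 70)
  tab$hr_bpm[100] <- 300 # one spike
  out <- preprocess_clinical_hr(tab)
  expect_equal(out$hr_bpm, rep(70, nrow(tab)))
  # constant input is unchanged
  tab2 <- data.frame(patient_id = "P001", t_s = seq(0, 1795, by = 5),
                     hr_bpm = 70)
  expect_equal(preprocess_clinical_hr(tab2)$hr_bpm, rep(70, 360))
  # simulated artifacts never survive
  sim <- simulate_clinical(clinical_sim_config(n_patients = 4,
                                               duration = 1200,
                                               artifact_rate = 60,
                                               seed = 5))
  pre <- preprocess_clinical_hr(sim)
  expect_true(all(pre$hr_bpm >= 10 & pre$hr_bpm <= 250, na.rm = TRUE))
  # idempotent away from trajectory extrema: reapplying changes almost
  # nothing (the odd centered window is exact on locally monotone data)
  twice <- preprocess_clinical_hr(pre)
  expect_lt(mean(abs(twice$hr_bpm - pre$hr_bpm), na.rm = TRUE), 0.2)
  expect_lt(max(abs(twice$hr_bpm - pre$hr_bpm), na.rm = TRUE), 2)
  # an all-artifact patient is dropped with a warning
  bad <- rbind(tab2, data.frame(patient_id = "P002",
                                t_s = seq(0, 1795, by = 5), hr_bpm = 300))
  expect_warning(out3 <- preprocess_clinical_hr(bad), "P002")
  expect_false("P002" %in% out3$patient_id)
})

test_that("the mixed model solves the noise-free system exactly", {
  cfg <- clinical_sim_config(n_patients = 8, duration = 900,
                             residual_sd = 0, random_intercept_sd = 0,
                             artifact_rate = 0, seed = 6)
  tab <- simulate_clinical(cfg)
  fit <- suppressWarnings(fit_clinical_glm(preprocess_clinical_hr(tab)))
  expect_equal(fit$coefficients$estimate, unname(cfg$coeffs),
               tolerance = 0.01)
  expect_error(fit_clinical_glm(tab[tab$patient_id == "P001", ]),
               ">= 2 patients")
})

test_that("default clinical simulation recovers the drug coefficients", {
  cfg <- clinical_sim_config(seed = 2)
  tab <- simulate_clinical(cfg)
  fit <- fit_clinical_glm(preprocess_clinical_hr(tab))
  co <- fit$coefficients
  expect_equal(nrow(co), 11L)
  expect_true(all(co$lower <= co$estimate & co$estimate <= co$upper))
  prop <- co[co$term == "prop", ]
  expect_gt(prop$estimate, 0)
  expect_true(prop$lower <= cfg$coeffs[["prop"]] &&
                cfg$coeffs[["prop"]] <= prop$upper)
  expect_lt(co[co$term == "fent", "estimate"], 0)
})

test_that("fixed effects are recovered within their CIs across replicates", {
  # 50 seeded replicates of a reduced cohort; the pass mark per
  # coefficient (42/50) is the one-sided 95% binomial bound for a true
  # coverage of 0.90
  n_rep <- 50
  covered <- matrix(NA, n_rep, 11)
  for (s in seq_len(n_rep)) {
    cfg <- clinical_sim_config(n_patients = 40, duration = 2400, seed = s)
    tab <- simulate_clinical(cfg)
    fit <- fit_clinical_glm(suppressWarnings(preprocess_clinical_hr(tab)))
    truth <- as.numeric(attr(tab, "truth_coeffs"))
    covered[s, ] <- fit$coefficients$lower <= truth &
      truth <= fit$coefficients$upper
  }
  expect_true(all(colSums(covered) >= 42))
  expect_gte(mean(covered), 0.9)
})

test_that("linked simulations show the heart-rate / wave-frequency correlation", {
  set.seed(53)
  hrs <- rnorm(16, 56.1, 2)
  freqs <- numeric(16)
  for (i in 1:16) {
    cfg <- volunteer_sim_config(phase_scale = 0.25, hr_intercept = hrs[i],
                                sw_freq_hr_link = 0.02, seed = 600 + i)
    r <- simulate_volunteer(cfg, events_only = TRUE)
    freqs[i] <- mean(r$truth_sw$frequency)
  }
  res <- hr_vs_sw_frequency(hrs, freqs)
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)
})
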