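# Score derivation: Cox fits vs. brute-force oracles, selection filter,
# weight assignment, end-to-end table derivation.

test_that("symmetric carrier groups give a hazard ratio of 1", {
  time <- c(3, 6, 9, 12, 15, 3, 6, 9, 12, 15)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  carrier <- rep(c(1, 0), each = 5)
  fit <- fit_univariate_cox(carrier, time, event)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
})

test_that("Newton beta matches a grid-search maximizer on a 12-patient toy cohort", {
  set.seed(7)
  time <- c(2.1, 4.3, 5.7, 7.2, 8.9, 10.4, 12.8, 14.1, 16.5, 18.2, 20.7, 23.3)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1)
  carrier <- c(1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0, 0)
  fit <- fit_univariate_cox(carrier, time, event)
  beta_grid <- oracle_cox_grid(carrier, time, event)
  expect_equal(fit$beta, beta_grid, tolerance = 1e-4)
})

test_that("tied event times reproduce the literal Efron oracle", {
  time <- c(3, 3, 3, 5, 5, 8, 8, 10, 12, 12, 15, 20)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 0)
  carrier <- c(1, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1)
  fit <- fit_univariate_cox(carrier, time, event, ties = "efron")
  beta_grid <- oracle_cox_grid(carrier, time, event, ties = "efron")
  expect_equal(fit$beta, beta_grid, tolerance = 1e-4)
  # Breslow likewise against its own oracle
  fit_b <- fit_univariate_cox(carrier, time, event, ties = "breslow")
  expect_equal(fit_b$beta,
               oracle_cox_grid(carrier, time, event, ties = "breslow"),
               tolerance = 1e-4)
})

test_that("Efron and Breslow coincide without ties and match the exact partial likelihood", {
  set.seed(11)
  for (i in 1:20) {
    d <- random_survdata(25)
    fe <- fit_univariate_cox(d$x, d$time, d$event, ties = "efron")
    fb <- fit_univariate_cox(d$x, d$time, d$event, ties = "breslow")
    expect_lt(abs(fe$beta - fb$beta), 1e-10)
    # oracle likelihoods agree too when there are no ties
    for (b in c(-0.5, 0, 0.7))
      expect_equal(oracle_cox_loglik(b, d$x, d$time, d$event, "efron"),
                   oracle_cox_loglik(b, d$x, d$time, d$event, "breslow"),
                   tolerance = 1e-10)
    expect_equal(fe$beta, optimize(oracle_cox_loglik, c(-5, 5), x = d$x,
                                   time = d$time, event = d$event,
                                   maximum = TRUE, tol = 1e-10)$maximum,
                 tolerance = 1e-5)
  }
})

test_that("degenerate fits are handled as specified", {
  expect_error(fit_univariate_cox(c(1, 0, 1), c(1, 2, 3), c(0, 0, 0)),
               "zero events")
  expect_error(fit_univariate_cox(c(1, 1, 1), c(1, 2, 3), c(1, 0, 1)),
               "constant")
  # complete separation: all events among carriers -> capped, flagged
  time <- c(1, 2, 3, 10, 11, 12, 13, 14)
  event <- c(1, 1, 1, 0, 0, 0, 0, 0)
  carrier <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_warning(fit <- fit_univariate_cox(carrier, time, event), "capped")
  expect_true(fit$flagged)
  expect_lte(abs(fit$beta), 10)
})

test_that("the selection filter applies the printed strictness at its boundaries", {
  mk <- function(hr, n_carriers) structure(
    list(hr = hr, n_carriers = n_carriers), class = "cox_fit")
  fits <- list(freq_ok_adverse = mk(2.0, 26),       # f = 0.10
               too_rare = mk(3.0, 2),               # f = 0.0077
               neutral = mk(1.2, 52),               # f = 0.20
               protective_boundary = mk(0.66, 13),  # f = 0.05, HR = 0.66
               hr_boundary = mk(1.5, 52),           # HR exactly 1.5
               freq_boundary = mk(2.0, 3),          # f = 3/260 < 1.5%
               freq_just_above = mk(2.0, 4))        # f = 4/260 > 1.5%
  sel <- select_prognostic_lesions(fits, cohort_n = 260)
  expect_true("freq_ok_adverse" %in% sel)
  expect_false("too_rare" %in% sel)
  expect_false("neutral" %in% sel)
  expect_true("protective_boundary" %in% sel)   # <= 0.66 is inclusive
  expect_false("hr_boundary" %in% sel)          # > 1.5 is strict
  expect_false("freq_boundary" %in% sel)
  expect_true("freq_just_above" %in% sel)
})

test_that("log-HR banding yields the documented signed weights", {
  expect_identical(assign_lesion_score(0.66), 1L)
  expect_identical(assign_lesion_score(2.25), -2L)
  expect_identical(assign_lesion_score(20), -4L)   # clamped
  expect_identical(assign_lesion_score(1 / 2.25), 2L)
  expect_identical(assign_lesion_score(0.05), 4L)  # clamped protective
  expect_error(assign_lesion_score(1.2), "neutral band")
  expect_error(assign_lesion_score(1.5), "neutral band")
})

test_that("derive_score_table signs lesions by their event load", {
  set.seed(13)
  n <- 120
  lethal <- rbinom(n, 1, 0.4)
  benign <- rbinom(n, 1, 0.4)
  # events concentrated in lethal carriers, absent in benign carriers
  t_event <- rexp(n, 0.02 * exp(2 * lethal - 1.5 * benign))
  cens <- rexp(n, 0.02)
  time <- pmin(t_event, cens, 60)
  event <- as.integer(t_event <= pmin(cens, 60))
  profiles <- lapply(seq_len(n), function(i) {
    lesions <- c(if (lethal[i]) "LETHAL:loss", if (benign[i]) "BENIGN:loss")
    structure(list(patient_id = paste0("P", i),
                   lesions = sort(as.character(lesions))),
              class = "lesion_profile")
  })
  records <- data.frame(patient_id = paste0("P", seq_len(n)),
                        efs_months = time, event = event)
  tab <- derive_score_table(profiles, records)
  expect_true("LETHAL:loss" %in% tab$entries$lesion)
  expect_true("BENIGN:loss" %in% tab$entries$lesion)
  expect_lt(tab$entries$score[tab$entries$lesion == "LETHAL:loss"], 0)
  expect_gt(tab$entries$score[tab$entries$lesion == "BENIGN:loss"], 0)
})

test_that("derivation handles the vacuous and zero-event cases", {
  profiles <- lapply(1:30, function(i)
    structure(list(patient_id = paste0("P", i), lesions = character(0)),
              class = "lesion_profile"))
  records <- data.frame(patient_id = paste0("P", 1:30),
                        efs_months = rexp(30, 0.05), event = rep(1L, 30))
  tab <- derive_score_table(profiles, records)
  expect_identical(nrow(tab$entries), 0L)
  expect_identical(cumulative_score(character(0), tab), 0L)
  expect_identical(as.character(classify_personall(0)), "good")

  records$event <- 0L
  expect_error(derive_score_table(profiles, records), "zero events")
})

test_that("EFS is truncated at the 60-month horizon for derivation", {
  # identical cohorts except for events far beyond 60 months: same table
  n <- 80
  set.seed(17)
  carrier <- rep(c(1, 0), n / 2)
  time <- c(rexp(n / 2, 0.05), rexp(n / 2, 0.01)) + 1
  event <- rbinom(n, 1, 0.8)
  profiles <- lapply(seq_len(n), function(i)
    structure(list(patient_id = paste0("P", i),
                   lesions = if (carrier[i]) "X:loss" else character(0)),
              class = "lesion_profile"))
  rec1 <- data.frame(patient_id = paste0("P", seq_len(n)),
                     efs_months = pmin(time, 61), event = event)
  rec2 <- rec1
  rec2$efs_months[rec2$efs_months >= 61] <- 200  # beyond horizon either way
  t1 <- derive_score_table(profiles, rec1)
  t2 <- derive_score_table(profiles, rec2)
  expect_identical(t1$entries, t2$entries)
})

test_that("planted log hazard ratios are recovered with small bias at n = 1000", {
  lp <- matrix(0.5, 1, 1, dimnames = list("ETV6:loss", "B-other"))
  beta_true <- log(2)
  cfg <- sim_config(n_patients = 1000, subtype_freq = c("B-other" = 1),
                    lesion_prob = lp, subclonal_rate = 0,
                    survival_mode = "lesion_hr", baseline_hazard = 0.0085,
                    lesion_hrs = c("ETV6:loss" = exp(beta_true)),
                    censoring_rate = 0.002)
  betas <- vapply(1:50, function(s) {
    co <- generate_cohort(cfg, seed = 1200 + s)
    m <- lesion_matrix(co$profiles, "ETV6:loss")
    fit_univariate_cox(m[1, ], co$records$efs_months, co$records$event)$beta
  }, 0)
  expect_lt(abs(mean(betas) - beta_true), 0.1)
})
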