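test_that("genotypes follow Hardy-Weinberg carrier prevalence", {
  panel <- snp_panel(c("rsA", "rsB", "rsC"), c("GA", "GB", "GC"),
                     rep("minor_allele_risk", 3), c(0.1, 0.35, 0.8))
  ch <- simulate_cohort(cohort_config(n_individuals = 50000, panel = panel,
                                      seed = 17))
  for (i in 1:3) {
    q <- panel$risk_allele_freq[i]
    expected <- 1 - (1 - q)^2
    emp <- carrier_prevalence(ch[[panel$snp_id[i]]])$prevalence
    se <- sqrt(expected * (1 - expected) / 50000)
    expect_lt(abs(emp - expected), 3 * se)
  }
})

test_that("degenerate allele frequencies give degenerate genotypes", {
  panel <- snp_panel(c("rs0", "rs1"), c("G0", "G1"),
                     rep("minor_allele_risk", 2), c(0, 1))
  ch <- simulate_cohort(cohort_config(n_individuals = 2000, panel = panel,
                                      seed = 1))
  expect_true(all(ch$rs0 == 0))
  expect_true(all(ch$rs1 == 2))
})

test_that("simulation is deterministic and substreams are independent", {
  panel <- one_snp_panel()
  cfg <- cohort_config(n_individuals = 3000, panel = panel, seed = 99)
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch1, ch2)

  # adding a SNP to the panel must not perturb unrelated draws
  panel2 <- snp_panel(c("rs1", "rs2"), c("G1", "G2"),
                      rep("minor_allele_risk", 2), c(panel$risk_allele_freq, 0.4),
                      c(log(2), 0), c(log(2), 0))
  ch3 <- simulate_cohort(cohort_config(n_individuals = 3000, panel = panel2,
                                       seed = 99))
  expect_identical(ch1$rs1, ch3$rs1)
  expect_identical(ch1$entry_age, ch3$entry_age)
  expect_identical(ch1$sex, ch3$sex)
  expect_identical(ch1$bmi, ch3$bmi)
})

test_that("case-cohort sampling retains all cases and is reproducible", {
  panel <- one_snp_panel()
  ch <- simulate_cohort(cohort_config(n_individuals = 8000, panel = panel,
                                      seed = 12))
  cc <- sample_case_cohort(ch, 1000, seed = 4)
  expect_s3_class(cc, "case_cohort")
  expect_equal(sum(cc$in_subcohort), 1000)
  expect_true(all(ch$id[ch$event] %in% cc$id))      # every case retained
  expect_true(any(cc$is_case & cc$in_subcohort) ||
                sum(ch$event) * 1000 / 8000 < 5)    # overlap permitted
  expect_identical(cc, sample_case_cohort(ch, 1000, seed = 4))

  full <- sample_case_cohort(ch, nrow(ch), seed = 4)
  expect_equal(nrow(full), nrow(ch))
  expect_true(all(full$in_subcohort))

  expect_error(sample_case_cohort(ch, 0), "subcohort_size")
  expect_error(sample_case_cohort(ch, nrow(ch) + 1), "subcohort_size")
})

test_that("case/subcohort overlap matches its sampling expectation", {
  panel <- one_snp_panel()
  ch <- simulate_cohort(cohort_config(n_individuals = 10000, panel = panel,
                                      seed = 31))
  n_cases <- sum(ch$event)
  m <- 1500
  expected <- n_cases * m / nrow(ch)
  overlaps <- vapply(1:60, function(s) {
    cc <- sample_case_cohort(ch, m, seed = s)
    sum(cc$is_case & cc$in_subcohort)
  }, numeric(1))
  # per-draw variance is hypergeometric-like; binomial bound is conservative
  se <- sqrt(expected * (1 - m / nrow(ch)) / 60)
  expect_lt(abs(mean(overlaps) - expected), 3 * se + 1e-9)
})

test_that("raising a SNP's log hazard ratio raises carrier events", {
  lo <- hi <- numeric(100)
  for (r in 1:100) {
    ch0 <- simulate_cohort(cohort_config(
      n_individuals = 1200, panel = one_snp_panel(b_f = 0),
      bmi_log_hr = 0, seed = 5000 + r))
    ch1 <- simulate_cohort(cohort_config(
      n_individuals = 1200, panel = one_snp_panel(b_f = log(3)),
      bmi_log_hr = 0, seed = 5000 + r))
    lo[r] <- sum(ch0$event & ch0$rs1 >= 1)
    hi[r] <- sum(ch1$event & ch1$rs1 >= 1)
  }
  expect_gt(mean(hi - lo), 0)
  expect_gt(mean(hi > lo), 0.5)
})

test_that("null-covariate event ages match the closed-form Gompertz law", {
  lambda <- 2e-5; gamma <- 0.09; entry <- 30
  cdf <- function(t) {
    H <- function(a) lambda / gamma * (exp(gamma * a) - 1)
    1 - exp(-(H(t) - H(entry)))
  }
  pass <- logical(100)
  for (r in 1:100) {
    ch <- simulate_cohort(cohort_config(
      n_individuals = 400, panel = one_snp_panel(b_f = 0, b_m = 0),
      bmi_log_hr = 0, lambda = lambda, gamma = gamma,
      entry_age_mean = entry, entry_age_sd = 1e-9,
      entry_age_min = entry - 1e-6, entry_age_max = entry + 1e-6,
      max_followup = 500, admin_censor_age = 1e6, seed = 7000 + r))
    stopifnot(all(ch$event))
    D <- suppressWarnings(stats::ks.test(ch$exit_age, cdf))$statistic
    pass[r] <- D < 1.358 / sqrt(400)   # asymptotic 5% critical value
  }
  expect_gte(mean(pass), 0.90)
})

test_that("gamma = 0 falls back to the exponential hazard, not an error", {
  rate <- 0.01
  ch <- simulate_cohort(cohort_config(
    n_individuals = 4000, panel = one_snp_panel(b_f = 0, b_m = 0),
    bmi_log_hr = 0, lambda = rate, gamma = 0,
    entry_age_mean = 30, entry_age_sd = 1e-9,
    entry_age_min = 30 - 1e-6, entry_age_max = 30 + 1e-6,
    max_followup = 1e6, admin_censor_age = 1e7, seed = 3))
  expect_true(all(ch$event))
  # memoryless: event age minus entry is Exp(rate)
  expect_equal(mean(ch$exit_age - ch$entry_age), 1 / rate, tolerance = 0.08)
})

test_that("full-cohort hazard ratio recovery against the survival package", {
  skip_if_not_installed("survival")
  ch <- simulate_cohort(cohort_config(n_individuals = 20000,
                                      panel = one_snp_panel(),
                                      bmi_log_hr = 0, seed = 8))
  ch$carrier <- as.integer(ch$rs1 >= 1)
  fit <- survival::coxph(survival::Surv(entry_age, exit_age, event) ~ carrier,
                         data = ch, ties = "breslow")
  se <- sqrt(diag(fit$var))
  expect_lt(abs(unname(coef(fit)) - log(2)), 3 * se)
})
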