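test_that("the fitter matches a brute-force grid maximizer on tiny data", {
  d <- tiny_surv_data()
  beta_grid <- grid_mle(d$entry_age, d$exit_age, d$event, d$x)
  fit <- coxcc(~ x, d, weighting = "unweighted")
  expect_lt(abs(unname(coef(fit)) - beta_grid), 1e-4)
  expect_equal(fit$loglik,
               plik_breslow(unname(coef(fit)), d$entry_age, d$exit_age,
                            d$event, d$x),
               tolerance = 1e-10)
})

test_that("subcohort = full cohort reduces to a standard delayed-entry fit", {
  skip_if_not_installed("survival")
  ch <- simulate_cohort(cohort_config(n_individuals = 3000,
                                      panel = one_snp_panel(), seed = 2))
  ch$carrier <- as.integer(ch$rs1 >= 1)
  full <- sample_case_cohort(ch, nrow(ch), seed = 2)  # Prentice degenerates
  f1 <- coxcc(~ carrier + bmi, full, weighting = "prentice")
  f2 <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ carrier + bmi,
    data = ch, ties = "breslow",
    control = survival::coxph.control(eps = 1e-12, iter.max = 50, toler.chol = 1e-13))
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-6)
  expect_equal(f1$loglik, unname(f2$loglik[2]), tolerance = 1e-8)
})

test_that("Efron tie handling matches the survival package on tied ages", {
  skip_if_not_installed("survival")
  ch <- simulate_cohort(cohort_config(n_individuals = 2000,
                                      panel = one_snp_panel(), seed = 14))
  ch$carrier <- as.integer(ch$rs1 >= 1)
  ch$exit_age <- ceiling(ch$exit_age)                 # force heavy ties
  ch$entry_age <- pmin(ch$entry_age, ch$exit_age - 0.5)
  for (t in c("breslow", "efron")) {
    f1 <- coxcc(~ carrier + bmi, ch, ties = t, robust = FALSE)
    f2 <- survival::coxph(
      survival::Surv(entry_age, exit_age, event) ~ carrier + bmi,
      data = ch, ties = t,
      control = survival::coxph.control(eps = 1e-12, iter.max = 50, toler.chol = 1e-13))
    expect_lt(max(abs(coef(f1) - coef(f2))), 1e-6)
    expect_equal(f1$se, unname(sqrt(diag(f2$var))), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("sandwich standard errors match the survival package's robust fit", {
  skip_if_not_installed("survival")
  ch <- simulate_cohort(cohort_config(n_individuals = 4000,
                                      panel = one_snp_panel(), seed = 6))
  ch$carrier <- as.integer(ch$rs1 >= 1)
  ch$rowid <- seq_len(nrow(ch))
  f1 <- coxcc(~ carrier + bmi, ch)
  f2 <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ carrier + bmi,
    data = ch, ties = "breslow", robust = TRUE, cluster = rowid,
    control = survival::coxph.control(eps = 1e-12, iter.max = 50, toler.chol = 1e-13))
  expect_equal(f1$robust_se, sqrt(diag(vcov(f2))), tolerance = 1e-6,
               ignore_attr = TRUE)
  # hazard-ratio confidence bounds are exp(coef +- z * robust se)
  z <- qnorm(0.975)
  expect_equal(f1$ci_low, exp(coef(f1) - z * f1$robust_se), tolerance = 1e-12)
  expect_equal(f1$ci_high, exp(coef(f1) + z * f1$robust_se), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or flagged, not papered over", {
  d <- tiny_surv_data()
  d$x0 <- 1
  expect_error(coxcc(~ x0, d, weighting = "unweighted"), "constant")
  d0 <- d; d0$event <- FALSE
  expect_error(coxcc(~ x, d0, weighting = "unweighted"), "no events")

  # perfect separation: every carrier fails before any noncarrier
  sep <- data.frame(entry_age = rep(0, 8),
                    exit_age = c(1, 2, 3, 4, 11, 12, 13, 14),
                    event = c(rep(TRUE, 4), rep(FALSE, 4)),
                    x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_warning(fit <- coxcc(~ x, sep, weighting = "unweighted"),
                 "monotone likelihood")
  expect_false(fit$converged)
})

test_that("the fit is invariant to row order and id relabeling", {
  ch <- simulate_cohort(cohort_config(n_individuals = 2500,
                                      panel = one_snp_panel(), seed = 20))
  cc <- sample_case_cohort(ch, 600, seed = 20)
  cc$carrier <- as.integer(cc$rs1 >= 1)
  f1 <- coxcc(~ carrier + bmi, cc)
  set.seed(1)
  perm <- sample(nrow(cc))
  cc2 <- cc[perm, , drop = FALSE]
  cc2$id <- seq_len(nrow(cc2)) + 10000   # relabel ids
  f2 <- coxcc(~ carrier + bmi, cc2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-8)
})

test_that("the weighted log partial likelihood is concave along directions", {
  ch <- simulate_cohort(cohort_config(n_individuals = 1500,
                                      panel = one_snp_panel(), seed = 9))
  cc <- sample_case_cohort(ch, 400, seed = 9)
  cc$carrier <- as.integer(cc$rs1 >= 1)
  fit <- coxcc(~ carrier + bmi, cc, robust = FALSE)
  eng <- fit$engine
  ll <- function(b) pafcc:::cox_eval_cpp(eng$entry, eng$exit, eng$status,
                                         eng$X, b, FALSE, FALSE)$loglik
  set.seed(3)
  for (i in 1:5) {
    b0 <- rnorm(2); b1 <- rnorm(2)
    mid <- ll((b0 + b1) / 2)
    expect_gte(mid, (ll(b0) + ll(b1)) / 2 - 1e-9)
  }
})

test_that("proportional hazards test is calibrated under the null", {
  set.seed(42)
  pvals <- vapply(1:200, function(r) {
    d <- sim_exp_surv(300, b1 = log(2))
    fit <- coxcc(~ x, d, weighting = "unweighted", robust = FALSE)
    check_proportional_hazards(fit)$p
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.11)
})

test_that("proportional hazards test detects a reversing effect", {
  set.seed(43)
  pvals <- vapply(1:60, function(r) {
    d <- sim_exp_surv(400, b1 = 1, b2 = -1, t_change = qexp(0.5, 0.1))
    fit <- coxcc(~ x, d, weighting = "unweighted", robust = FALSE)
    check_proportional_hazards(fit)$p
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.5)
})

test_that("a perfectly balanced exposure yields a zero test statistic", {
  # two tied events at each time, one exposed and one not: contributions to
  # the age trend cancel exactly
  d <- data.frame(entry_age = rep(0, 8),
                  exit_age = rep(c(2, 4, 6, 8), each = 2),
                  event = TRUE,
                  x = rep(c(0, 1), 4))
  fit <- suppressWarnings(coxcc(~ x, d, weighting = "unweighted",
                                robust = FALSE))
  res <- check_proportional_hazards(fit)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_error(suppressWarnings(check_proportional_hazards(
    coxcc(~ x, tiny_surv_data()[c(1, 4), ], weighting = "unweighted"))),
    "at least 2 events")
})
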