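test_that("Levin's formula reproduces printed values and closed forms", {
  expect_equal(round(100 * levin_paf(444 / 6909, 2.48), 1), 8.7)
  expect_equal(levin_paf(0.5, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(levin_paf(c(0, 0.3, 0.9), 1), c(0, 0, 0))
  expect_lt(levin_paf(0.4, 0.5), 0)            # protective exposure
  expect_equal(levin_paf(1, 2.5), 1.5 / 2.5)   # saturated limit (hr-1)/hr
  expect_error(levin_paf(1.2, 2), "\\[0, 1\\]")
  expect_error(levin_paf(0.5, 0), "> 0")
})

test_that("Levin's formula is monotone in prevalence and hazard ratio", {
  hrs <- c(1.01, 1.5, 2, 5, 20)
  ps <- seq(0.05, 1, by = 0.05)
  for (hr in hrs) {
    v <- levin_paf(ps, hr)
    expect_true(all(diff(v) > 0))
    expect_true(all(v < 1))
  }
  for (p in c(0.05, 0.5, 0.95)) {
    v <- levin_paf(p, seq(1.05, 10, by = 0.05))
    expect_true(all(diff(v) > 0))
  }
})

test_that("combined carrier uses union semantics with complete-case missing", {
  d <- data.frame(rsA = c(0, 1, 0, NA, 2, 0),
                  rsB = c(0, 0, 2, 1, NA, 0))
  expect_equal(combined_carrier(d, c("rsA", "rsB")),
               c(0L, 1L, 1L, NA, NA, 0L))
  expect_equal(combined_carrier(d, "rsA"), c(0L, 1L, 0L, NA, 1L, 0L))
  expect_error(combined_carrier(d, character()), "nonempty")
  expect_error(combined_carrier(d, "rsZ"), "unknown snp_id")
})

test_that("single-SNP PAF recovers the generating truth", {
  panel <- one_snp_panel(prev = 0.2, b_f = log(2))
  ch <- simulate_cohort(cohort_config(n_individuals = 20000, panel = panel,
                                      seed = 44))
  cc <- sample_case_cohort(ch, 2000, seed = 44)
  res <- single_snp_paf(cc, "rs1", sex = NULL)
  expect_s3_class(res, "paf_result")
  expect_lt(abs(res$paf - levin_paf(0.2, 2)), 0.06)
  expect_equal(res$paf, levin_paf(res$p, res$hr), tolerance = 1e-12)
  expect_lt(abs(res$p - 0.2), 3 * sqrt(0.2 * 0.8 / res$n_subcohort))
})

test_that("a null SNP's PAF centers on zero", {
  pafs <- vapply(1:25, function(r) {
    panel <- one_snp_panel(prev = 0.3, b_f = 0, b_m = 0)
    ch <- simulate_cohort(cohort_config(n_individuals = 6000, panel = panel,
                                        seed = 600 + r))
    cc <- sample_case_cohort(ch, 1200, seed = 600 + r)
    single_snp_paf(cc, "rs1", robust = FALSE)$paf
  }, numeric(1))
  expect_lt(abs(mean(pafs)), 3 * sd(pafs) / sqrt(length(pafs)))
})

test_that("sex stratification uses disjoint subsets", {
  panel <- one_snp_panel(b_f = log(3), b_m = 0)
  ch <- simulate_cohort(cohort_config(n_individuals = 15000, panel = panel,
                                      seed = 50))
  cc <- sample_case_cohort(ch, 2000, seed = 50)
  f <- single_snp_paf(cc, "rs1", sex = "female")
  m <- single_snp_paf(cc, "rs1", sex = "male")
  expect_equal(f$n_used + m$n_used + f$n_dropped + m$n_dropped, nrow(cc))
  expect_gt(f$hr, m$hr)    # effect simulated in women only
  set.seed(8)
  cc2 <- cc[sample(nrow(cc)), , drop = FALSE]
  f2 <- single_snp_paf(cc2, "rs1", sex = "female")
  expect_equal(f$paf, f2$paf, tolerance = 1e-10)
})

test_that("cumulative curve is prefix-consistent with non-decreasing prevalence", {
  panel <- snp_panel(c("rsA", "rsB", "rsC"), c("GA", "GB", "GC"),
                     rep("minor_allele_risk", 3), c(0.11, 0.2, 0.05),
                     c(log(2), log(1.4), log(3)), c(log(2), log(1.4), log(3)))
  ch <- simulate_cohort(cohort_config(n_individuals = 15000, panel = panel,
                                      seed = 77))
  cc <- sample_case_cohort(ch, 2500, seed = 77)
  cc$rsA[c(3, 10)] <- NA   # exercise the shared complete-case rule
  curve <- cumulative_paf_curve(cc, c("rsA", "rsB", "rsC"))
  expect_s3_class(curve, "paf_curve")
  expect_equal(curve$snp_id, c("rsA", "rsB", "rsC"))
  expect_true(all(diff(curve$p) >= 0))
  expect_equal(attr(curve, "n_dropped"), 2)

  # the single-SNP prefix equals the single-SNP estimate on the same
  # complete-case individuals
  cc_cc <- cc[!is.na(cc$rsA) & !is.na(cc$rsB) & !is.na(cc$rsC), ]
  one <- single_snp_paf(cc_cc, "rsA", robust = FALSE)
  expect_equal(curve$paf[1], one$paf, tolerance = 1e-10)
  expect_equal(curve$hr[1], one$hr, tolerance = 1e-10)
})

test_that("adding a null SNP leaves the true cumulative PAF unchanged", {
  # analytic truth by enumeration: union with a null SNP dilutes the hazard
  # ratio but raises prevalence so the PAF is preserved
  t1 <- true_union_paf(0.2, log(2))
  t2 <- true_union_paf(c(0.2, 0.3), c(log(2), 0))
  expect_equal(t1$paf, 1 / 6, tolerance = 1e-12)
  expect_equal(t2$paf, t1$paf, tolerance = 1e-12)

  # and the estimator tracks that truth on simulated data
  panel <- snp_panel(c("rsA", "rsB"), c("GA", "GB"),
                     rep("minor_allele_risk", 2),
                     c(1 - sqrt(0.8), 1 - sqrt(0.7)),
                     c(log(2), 0), c(log(2), 0))
  pafs <- vapply(1:4, function(r) {
    ch <- simulate_cohort(cohort_config(n_individuals = 25000, panel = panel,
                                        bmi_log_hr = 0, seed = 900 + r))
    cc <- sample_case_cohort(ch, 3000, seed = 900 + r)
    curve <- cumulative_paf_curve(cc, c("rsA", "rsB"), adjust_bmi = FALSE)
    curve$paf[2] - curve$paf[1]
  }, numeric(1))
  expect_lt(abs(mean(pafs)), 0.045)
})

test_that("data-derived ordering sorts by PAF with forced SNPs last", {
  panel <- snp_panel(c("rsA", "rsB", "rsC"), c("GA", "GB", "GC"),
                     rep("minor_allele_risk", 3), c(0.05, 0.25, 0.15),
                     c(log(3), log(1.8), 0), c(log(3), log(1.8), 0))
  ch <- simulate_cohort(cohort_config(n_individuals = 20000, panel = panel,
                                      seed = 91))
  cc <- sample_case_cohort(ch, 2500, seed = 91)
  curve <- cumulative_paf_curve(cc, c("rsA", "rsB", "rsC"),
                                order = "data", force_last = "rsC")
  expect_equal(curve$snp_id[3], "rsC")
  one <- vapply(c("rsA", "rsB"), function(s)
    single_snp_paf(cc, s, robust = FALSE)$paf, numeric(1))
  expect_equal(curve$snp_id[1], names(which.max(one)))
})

test_that("age-band clipping partitions risk time and events correctly", {
  # entry 40, exit 60, event at 60: risk time in both of the first two
  # default bands, the event counted only in the second
  d <- data.frame(id = 1, sex = "female", entry_age = 40, exit_age = 60,
                  event = TRUE, bmi = 25, in_subcohort = TRUE, is_case = TRUE)
  b1 <- pafcc:::clip_to_band(d, 0, 50)
  b2 <- pafcc:::clip_to_band(d, 50, 75)
  b3 <- pafcc:::clip_to_band(d, 75, Inf)
  expect_equal(c(b1$entry_age, b1$exit_age, b1$event), c(40, 50, 0))
  expect_equal(c(b2$entry_age, b2$exit_age, b2$event), c(50, 60, 1))
  expect_equal(nrow(b3), 0)

  # boundary age is half-open: an event exactly at 50 belongs to (0, 50]
  d$exit_age <- 50
  expect_equal(pafcc:::clip_to_band(d, 0, 50)$event, TRUE)
  expect_equal(nrow(pafcc:::clip_to_band(d, 50, 75)), 0)

  expect_error(pafcc:::check_bands(list(c(0, 50), c(60, Inf))),
               "cover \\(0, Inf\\)")
})

test_that("a single age band reproduces the unstratified curve", {
  panel <- one_snp_panel()
  ch <- simulate_cohort(cohort_config(n_individuals = 8000, panel = panel,
                                      seed = 33))
  cc <- sample_case_cohort(ch, 1500, seed = 33)
  whole <- cumulative_paf_curve(cc, "rs1")
  bands <- age_band_cumulative_paf(cc, "rs1", bands = list(c(0, Inf)))
  expect_equal(bands[[1]]$paf, whole$paf, tolerance = 1e-10)

  # an empty band is flagged unavailable, not fabricated
  res <- age_band_cumulative_paf(cc, "rs1",
                                 bands = list(c(0, 1), c(1, Inf)))
  expect_s3_class(res[[1]], "paf_band_unavailable")
  expect_s3_class(res[[2]], "paf_curve")
})

test_that("band-specific hazard ratios agree under an age-constant effect", {
  hrs <- matrix(NA_real_, 8, 2)
  panel <- one_snp_panel(prev = 0.3, b_f = log(2))
  for (r in 1:8) {
    ch <- simulate_cohort(cohort_config(n_individuals = 20000, panel = panel,
                                        bmi_log_hr = 0, seed = 1200 + r))
    cc <- sample_case_cohort(ch, 3000, seed = 1200 + r)
    bands <- age_band_cumulative_paf(cc, "rs1", adjust_bmi = FALSE,
                                     bands = list(c(0, 62), c(62, Inf)))
    hrs[r, ] <- c(bands[[1]]$hr, bands[[2]]$hr)
  }
  expect_lt(abs(mean(log(hrs[, 1])) - mean(log(hrs[, 2]))), 0.25)
})
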