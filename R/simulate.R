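#' Configuration for the synthetic cohort generator
#'
#' Describes a two-sex source cohort with independent Hardy-Weinberg loci and
#' proportional-hazards event times on the age scale. Defaults emulate a
#' Norwegian population-based cohort: inclusion from age 25, about 18 years of
#' follow-up, and a Gompertz baseline hazard `h0(a) = lambda * exp(gamma * a)`
#' calibrated so that noncarrier cumulative incidence by age 90 is roughly 7%,
#' which over ~18 years of follow-up yields a case fraction of the same order
#' as large population-based venous thromboembolism cohorts (~1.5%).
#'
#' @param n_individuals cohort size (>= 2).
#' @param prop_female proportion of women.
#' @param entry_age_mean,entry_age_sd,entry_age_min,entry_age_max truncated
#'   normal entry-age distribution, years.
#' @param max_followup administrative end of follow-up, years after entry.
#' @param admin_censor_age upper age bound for follow-up, years.
#' @param lambda,gamma Gompertz baseline hazard parameters (`lambda > 0`;
#'   `gamma = 0` gives the exponential limit).
#' @param bmi_mean,bmi_sd body mass index distribution, kg/m^2.
#' @param bmi_log_hr log hazard ratio per standard deviation of BMI.
#' @param panel a [snp_panel()]; genotypes are drawn independently per SNP
#'   under Hardy-Weinberg at `risk_allele_freq`, and carriers' hazards are
#'   multiplied by `exp(log_hr_female)` or `exp(log_hr_male)`.
#' @param seed integer seed; every task (genotypes per SNP, sexes, ages, BMI,
#'   event times) draws from a named substream derived from it, so adding a
#'   SNP does not perturb unrelated draws.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 93000,
                          prop_female = 0.529,
                          entry_age_mean = 47, entry_age_sd = 15,
                          entry_age_min = 25, entry_age_max = 90,
                          max_followup = 18,
                          admin_censor_age = 100,
                          lambda = 2e-6, gamma = 0.09,
                          bmi_mean = 26.2, bmi_sd = 4.1,
                          bmi_log_hr = log(1.3),
                          panel = vte_snp_panel(),
                          seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              prop_female = prop_female,
              entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
              entry_age_min = entry_age_min, entry_age_max = entry_age_max,
              max_followup = max_followup,
              admin_censor_age = admin_censor_age,
              lambda = lambda, gamma = gamma,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_log_hr = bmi_log_hr,
              panel = panel, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!inherits(cfg$panel, "snp_panel")) stop("panel must be a snp_panel",
                                              call. = FALSE)
  if (cfg$n_individuals < 2) stop("n_individuals must be >= 2", call. = FALSE)
  if (cfg$lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (cfg$prop_female < 0 || cfg$prop_female > 1)
    stop("prop_female must lie in [0, 1]", call. = FALSE)
  if (cfg$entry_age_min < 0 || cfg$entry_age_max <= cfg$entry_age_min)
    stop("entry age bounds invalid (need 0 <= min < max)", call. = FALSE)
  if (cfg$max_followup <= 0) stop("max_followup must be > 0", call. = FALSE)
  if (cfg$admin_censor_age <= cfg$entry_age_min)
    stop("admin_censor_age must exceed the minimum entry age", call. = FALSE)
  invisible(cfg)
}

# Gompertz cumulative baseline hazard and its inverse.
gompertz_H <- function(a, lambda, gamma) {
  if (gamma == 0) lambda * a else lambda / gamma * (exp(gamma * a) - 1)
}
gompertz_Hinv <- function(h, lambda, gamma) {
  if (gamma == 0) h / lambda else log(1 + gamma * h / lambda) / gamma
}

#' Simulate a source cohort
#'
#' Genotypes are drawn independently per SNP under Hardy-Weinberg equilibrium
#' (genotype probabilities `(1-q)^2, 2q(1-q), q^2`). The hazard of an
#' individual at age `a` is `h0(a) * exp(sum_j beta_sex_j * carrier_j +
#' beta_bmi * z_bmi)` with Gompertz `h0`; event ages are drawn by inverse
#' transform from the cumulative hazard conditional on survival to the entry
#' age. Exit age is the minimum of the event age, `entry + max_followup` and
#' `admin_censor_age`, with the event flag set iff the event age is the
#' minimum.
#'
#' @param config a [cohort_config()].
#' @return Data frame of class `cohort_table` with columns `id`, `sex`,
#'   `entry_age`, `exit_age`, `event`, `bmi` and one risk-allele-count column
#'   per panel SNP; the panel is attached as attribute `"panel"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 500,
#'                      panel = snp_panel("rs1", "G1", "minor_allele_risk",
#'                                        0.2, log(2), log(2)),
#'                      seed = 42)
#' head(simulate_cohort(cfg))
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_individuals
  panel <- config$panel

  set.seed(derive_seed(config$seed, "sex"))
  sex <- factor(ifelse(runif(n) < config$prop_female, "female", "male"),
                levels = c("female", "male"))

  set.seed(derive_seed(config$seed, "entry_age"))
  entry <- rtruncnorm(n, config$entry_age_mean, config$entry_age_sd,
                      config$entry_age_min,
                      min(config$entry_age_max, config$admin_censor_age - 1))

  set.seed(derive_seed(config$seed, "bmi"))
  bmi <- pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 14)

  geno <- matrix(NA_integer_, n, nrow(panel),
                 dimnames = list(NULL, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    q <- panel$risk_allele_freq[j]
    set.seed(derive_seed(config$seed, paste0("geno:", panel$snp_id[j])))
    geno[, j] <- rbinom(n, 2L, q)
  }

  beta_snp <- matrix(ifelse(rep(sex == "female", nrow(panel)),
                            rep(panel$log_hr_female, each = n),
                            rep(panel$log_hr_male, each = n)),
                     n, nrow(panel))
  lp <- rowSums((geno >= 1L) * beta_snp) +
    config$bmi_log_hr * (bmi - config$bmi_mean) / config$bmi_sd
  risk <- exp(lp)

  set.seed(derive_seed(config$seed, "event_time"))
  u <- runif(n)
  # P(T > t | T > entry) = exp(-(H(t) - H(entry)) * risk)
  h_event <- gompertz_H(entry, config$lambda, config$gamma) - log(u) / risk
  t_event <- gompertz_Hinv(h_event, config$lambda, config$gamma)
  t_admin <- pmin(entry + config$max_followup, config$admin_censor_age)
  exit <- pmin(t_event, t_admin)
  event <- t_event <= t_admin

  out <- data.frame(id = seq_len(n), sex = sex, entry_age = entry,
                    exit_age = exit, event = event, bmi = bmi)
  out <- cbind(out, as.data.frame(geno))
  attr(out, "panel") <- panel
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Truncated normal draws by inversion (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  stats::qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Draw a case-cohort sample from a source cohort
#'
#' Retains all incident cases plus a subcohort sampled uniformly at random
#' from the full source cohort. Every person (including cases) has the same
#' probability of entering the subcohort, so cases may by chance also be
#' subcohort members; such rows carry both flags.
#'
#' @param cohort a `cohort_table` from [simulate_cohort()] or [read_cohort()].
#' @param subcohort_size number of subcohort members to draw
#'   (`0 < subcohort_size <= nrow(cohort)`).
#' @param seed integer seed for the sampling substream.
#' @return Data frame of class `case_cohort` (subset of the cohort rows, plus
#'   logical columns `in_subcohort` and `is_case`) with attributes
#'   `subcohort_size`, `source_size`, `sampling_fraction` and the panel.
#' @export
sample_case_cohort <- function(cohort, subcohort_size, seed = 1L) {
  n <- nrow(cohort)
  if (subcohort_size <= 0 || subcohort_size > n)
    stop("subcohort_size must lie in (0, ", n, "]", call. = FALSE)
  set.seed(derive_seed(seed, "subcohort"))
  sub_idx <- sample.int(n, subcohort_size)
  in_sub <- logical(n)
  in_sub[sub_idx] <- TRUE
  keep <- in_sub | cohort$event
  out <- cohort[keep, , drop = FALSE]
  out$in_subcohort <- in_sub[keep]
  out$is_case <- cohort$event[keep]
  rownames(out) <- NULL
  attr(out, "panel") <- attr(cohort, "panel")
  attr(out, "subcohort_size") <- as.integer(subcohort_size)
  attr(out, "source_size") <- n
  attr(out, "sampling_fraction") <- subcohort_size / n
  class(out) <- c("case_cohort", "data.frame")
  out
}

#' @export
print.case_cohort <- function(x, ...) {
  cat("Case-cohort sample: ", nrow(x), " rows (",
      sum(x$is_case), " cases, subcohort ", attr(x, "subcohort_size"),
      " of ", attr(x, "source_size"), " source individuals, ",
      sum(x$is_case & x$in_subcohort), " overlap)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
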