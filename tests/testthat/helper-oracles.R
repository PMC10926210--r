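# Independent oracles and small data constructors shared across tests.
# Everything here is deliberately written without touching the package's
# fitting internals, so it can serve as a cross-check.

# Breslow log partial likelihood for delayed-entry data, by direct enumeration
# of risk sets: subject i is at risk at event time t iff entry_i < t <= exit_i.
plik_breslow <- function(beta, entry, exit, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    t <- exit[i]
    at_risk <- entry < t & t <= exit
    ll <- ll + x[i] * beta - log(sum(exp(x[at_risk] * beta)))
  }
  ll
}

# Grid-search maximizer of the brute-force partial likelihood.
grid_mle <- function(entry, exit, status, x, lo = -3, hi = 3, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, plik_breslow, numeric(1),
               entry = entry, exit = exit, status = status, x = x)
  grid[which.max(ll)]
}

# Six-individual delayed-entry fixture with a binary exposure and two distinct
# event ages (one of them tied across two subjects).
tiny_surv_data <- function() {
  data.frame(
    id = 1:6,
    sex = "female",
    entry_age = c(30, 32, 35, 31, 40, 38),
    exit_age = c(50, 50, 60, 55, 60, 58),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    bmi = c(24, 27, 25, 26, 30, 23),
    x = c(1, 0, 1, 0, 0, 1)
  )
}

# Single-SNP panel with carrier prevalence `prev` and carrier log-HR `b`.
one_snp_panel <- function(prev = 0.2, b_f = log(2), b_m = b_f,
                          snp_id = "rs1", gene = "G1") {
  snp_panel(snp_id, gene, "minor_allele_risk", 1 - sqrt(1 - prev), b_f, b_m)
}

# True combined (union) exposure prevalence and marginal hazard ratio for
# independent Hardy-Weinberg loci with multiplicative carrier effects, by
# enumeration over all carrier combinations. The reference group is
# noncarrier at every locus (multiplier 1), so the union-exposed group's
# hazard ratio is the carrier-probability-weighted mean multiplier.
true_union_paf <- function(prevs, loghrs) {
  k <- length(prevs)
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  pr <- apply(combos, 1, function(z)
    prod(ifelse(z == 1, prevs, 1 - prevs)))
  mult <- exp(combos %*% loghrs)
  exposed <- rowSums(combos) > 0
  p_u <- sum(pr[exposed])
  hr_u <- sum(pr[exposed] * mult[exposed]) / p_u
  list(p = p_u, hr = hr_u, paf = levin_paf(p_u, hr_u))
}

# Exponential survival data with a binary covariate, optional piecewise
# effect reversal at `t_change` (hazard multiplier exp(b1) before, exp(b2)
# after), entry at 0 and administrative censoring at `cens`.
sim_exp_surv <- function(n, b1, b2 = b1, t_change = Inf, rate = 0.1,
                         cens = 10, p_x = 0.5) {
  x <- rbinom(n, 1, p_x)
  u <- runif(n)
  h1 <- rate * exp(b1 * x)
  h2 <- rate * exp(b2 * x)
  t1 <- -log(u) / h1
  t <- ifelse(t1 <= t_change, t1, t_change + (-log(u) - h1 * t_change) / h2)
  data.frame(entry_age = 0, exit_age = pmin(t, cens) + 1e-12,
             event = t <= cens, x = x)
}
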