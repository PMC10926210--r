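---
title: "Attributable fractions for prothrombotic genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable fractions for prothrombotic genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafcc)
```

## The estimand and the design

The population attributable fraction (PAF) of an exposure is the proportion
of cases that would not occur if the exposed had the unexposed group's
hazard. For a carrier-coded genotype with population carrier prevalence $p$
and carrier-vs-noncarrier hazard ratio $HR$, Levin's formula gives

$$\mathrm{PAF} = \frac{p\,(HR - 1)}{p\,(HR - 1) + 1}.$$

`levin_paf()` implements exactly this, with domain checks ($0 \le p \le 1$,
$HR > 0$); the PAF is negative for protective exposures, zero at $HR = 1$,
and tends to $(HR-1)/HR$ as $p \to 1$.

The data design is a case cohort: all incident venous thromboembolism (VTE)
cases from a source cohort plus a subcohort drawn uniformly at random from
the full cohort, so cases can by chance also be subcohort members. Two
consequences drive the whole package:

* the subcohort is the population-representative piece, so **carrier
  prevalence is always estimated from subcohort members only** (using
  cases + subcohort would overstate $p$);
* hazard ratios need a risk-set construction that respects the sampling.
  We use **Prentice weighting**: subcohort members are at risk over their
  whole follow-up $(a_{\text{entry}}, a_{\text{exit}}]$, while cases outside
  the subcohort enter the risk set only immediately before their own event
  age. An `"unweighted"` option treats all retained rows as ordinary cohort
  rows; it is provided for sensitivity because source analyses of this
  design do not always state how the sampling entered the model, and nothing
  here should be read as asserting that a naive analysis is valid.

Age is the time scale: entry at the age of study inclusion (left
truncation), exit at the age of event or censoring. The hazard model is
adjusted for body mass index; BMI is standardized to zero mean and unit SD
before entering the model, purely for numerical conditioning — the carrier
hazard ratio is unchanged by any linear rescaling of a co-adjusted
covariate.

## The partial likelihood fitter

`coxcc()` maximizes the delayed-entry Cox partial likelihood by
Newton-Raphson with step-halving; the iteration runs in compiled code.
Numerical choices:

* initialization at $\beta = 0$; covariates centered before fitting;
* ties by Breslow (default; matching the default of the commercial package
  typically used for such analyses) or Efron;
* convergence when the gradient max-norm falls below $10^{-8}$, with at most
  50 iterations. For large samples the gradient's floating-point noise floor
  can exceed $10^{-8}$; if the objective can no longer improve and the
  Newton increment is below $10^{-9}(1 + \lVert\beta\rVert_\infty)$, the fit
  is accepted when the gradient is below $10^{-4}$ on the event-count scale
  (coefficients are then accurate to far more digits than reported);
* a coefficient exceeding 15 in absolute value with an unconverged gradient
  is flagged as a suspected monotone likelihood (complete separation) and
  reported as non-convergence — no finite estimate is fabricated;
* a constant covariate, or data with zero events, is an error.

Prentice risk sets are realized by shifting the entry age of
outside-subcohort cases to their event age minus $10^{-9} \times
\max(\text{exit age})$. This is exact whenever distinct event ages differ by
more than that epsilon (always, for the continuous-time simulator; exactly
tied ages are handled correctly by the tie corrections).

Variance is reported two ways: model-based (inverse information) for
diagnostics, and the score-residual sandwich (infinitesimal jackknife over
individuals, the same quantity `survival::coxph(robust = TRUE)` computes) as
the default standard error, which remains valid under the case-cohort
sampling. Under Efron ties the score residuals use the Breslow-form
baseline increments; with untied event times — the situation the simulator
produces — the two forms coincide.

`check_proportional_hazards()` regresses scaled Schoenfeld residuals on
event age and reports a 1-df chi-square score test per covariate (identity
or rank transform of age). The test is validated two ways in the suite:
rejection rate close to the nominal level under proportional hazards, and
high rejection against an effect that reverses sign at the median event
time.

## The cumulative multi-SNP model

The cumulative PAF of a SNP set uses the **union exposure**: carrier at at
least one SNP of the set, reference noncarrier at all of them. The source
analyses describe "adding SNPs one-by-one" without a formula; the union
indicator is the construction that keeps "fraction attributable to the set"
well-defined and makes the combined prevalence non-decreasing along the
curve by set inclusion. A joint multivariable decomposition (summing
coefficient-weighted attributions) is deliberately out of scope.

Choices worth knowing:

* The default order is the fixed published 6-SNP order
  (`cumulative_model_snps()`: rs8176719, rs2036914, rs2289252, rs6025,
  rs2066865, rs1799963), so the model is reproducible on any dataset.
  `order = "data"` instead sorts by descending single-SNP PAF with forced
  SNPs appended last — prothrombin F2 is forced in by default despite a low
  PAF because of its considerable hazard ratio.
* One complete-case set (nonmissing at *all* SNPs of the full model, and
  BMI) is used for every prefix, so the six estimates along a curve are
  computed on identical samples.
* An instructive invariant, proved by enumeration in the test suite: adding
  a SNP with $HR = 1$ to the model leaves the *true* cumulative PAF
  unchanged — the union prevalence rises but the union hazard ratio is
  diluted in exactly compensating proportion.

Age-band stratification clips each individual's risk interval to each band
$(\ell, h]$: entry clipped up to $\ell$, exit down to $h$, the event counted
only if the event age lies in the band; individuals with no risk time in a
band are excluded, and under Prentice weighting outside-subcohort cases
whose event falls outside the band contribute nothing. Published accounts
of such stratified analyses are inconsistent about whether the boundaries at
50 and 75 years are open or closed, and do not state whether risk time was
clipped or individuals classified once; we clip, use half-open bands, and
leave the boundaries configurable rather than guessing which printed variant
was intended. Bands with no events are flagged unavailable, not fabricated.

## Bias-corrected bootstrap

Intervals are BC — bias-corrected percentile, no acceleration term; the
source description says "bias-corrected", not "bias-corrected and
accelerated", so BCa is not implemented. With $B$ replicates
$\theta^*_1,\dots,\theta^*_B$ and point estimate $\hat\theta$:

$$z_0 = \Phi^{-1}\!\left(\frac{\#\{\theta^* < \hat\theta\} +
\tfrac12\#\{\theta^* = \hat\theta\}}{B}\right),$$

and the endpoints are the empirical quantiles at levels
$\Phi(2z_0 + z_{\alpha/2})$ and $\Phi(2z_0 + z_{1-\alpha/2})$. The half-tie
convention keeps $z_0$ finite at small $B$ when many replicates equal the
point estimate. Quantiles use R's default interpolation (`type = 7`),
recorded in the output so intervals reproduce bit for bit. If all
replicates fall on one side of $\hat\theta$, the interval is clamped to the
replicate extremes and flagged degenerate.

The resampling unit under this design is not identifiable from published
descriptions, so both options ship: `"stratified_design"` (default)
resamples subcohort members and outside-subcohort cases independently with
replacement, preserving both stratum sizes; `"iid_rows"` resamples all rows
as one pool. Neither is labeled as "the published scheme". Each replicate
re-runs the *entire* estimator — prevalence, Cox fit, Levin formula — and
failed replicates are dropped and counted (more than 10% failures aborts).
Per-replicate seeds derive from (seed, replicate index), so results are
independent of execution order. The default $B = 10{,}000$ matches the
published setting; validation runs use smaller $B$ (below).

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the structure the estimators assume:

* **Genotypes**: independent Hardy-Weinberg loci, genotype probabilities
  $(1-q)^2, 2q(1-q), q^2$. The packaged 17-SNP panel (`vte_snp_panel()`)
  carries the published subcohort risk-allele frequencies (sex-weighted
  average of the female and male values) and sex-specific carrier log
  hazard ratios equal to the log of the published HRs.
* **Event times**: proportional hazards on the age scale with a Gompertz
  baseline $h_0(a) = \lambda e^{\gamma a}$, sampled by inverse transform
  conditional on survival to the entry age; $\gamma = 0$ degrades gracefully
  to the exponential limit. Defaults $\lambda = 2\times10^{-6}$,
  $\gamma = 0.09$ per year give a noncarrier cumulative incidence of about
  7% by age 90 — VTE incidence rises steeply with age — and a case fraction
  over ~18 years of follow-up of the same order as large Scandinavian
  cohorts (~1.5%).
* **Population**: entry ages from a truncated normal (mean 47, SD 15,
  minimum 25 years, emulating an adult general-population survey), sex an
  independent Bernoulli (52.9% female), BMI normal (26.2, SD 4.1 kg/m²)
  with default log HR per SD of log 1.3, administrative censoring at entry
  + 18 years or age 100.
* **Sampling**: `sample_case_cohort()` keeps all cases plus a uniform
  subcohort; the sampling fraction is a free parameter because the source
  cohorts' exact fraction is not stated.

One global seed drives a named substream per task (each SNP's genotypes,
sexes, ages, BMI, event times, sampling, each bootstrap replicate), so
adding a SNP to the panel does not perturb any other draw.

Deliberate non-features, and hence limits on what passing tests show about
real data: loci are simulated independently although the two F11 SNPs are
correlated in reality, so simulated cumulative curves slightly overstate
what correlated panels add; there is no competing mortality, no
reproductive or cancer covariates, no genotyping error or
platform-specific missingness; and BMI is the only adjustment variable. The
simulator validates the estimators' statistical behavior, not the
published cohort's substantive results.

## Validation problem sizes

The test suite sizes its simulations as follows: Hardy-Weinberg prevalence
at $n = 50{,}000$; estimator bias and bootstrap coverage on 200 replicate
case-cohort studies of $n = 20{,}000$ with subcohort 2,000, true carrier
prevalence 0.2 and true HR 2.0 ($\mathrm{PAF} = 1/6$), with $B = 1{,}000$
bootstrap replicates per study; oracle equivalence against a brute-force
grid maximizer (step $10^{-4}$) on a six-individual fixture and against
`survival::coxph` (delayed entry, both tie methods, robust variance) on
full-cohort data; proportional-hazards calibration on 200 null datasets of
$n = 300$. These sizes were chosen so each check has clear statistical
resolution for the property it tests.

## Printed-input mode and known source inconsistencies

`paf_from_printed()` reproduces the published per-SNP PAF arithmetic
directly from printed inputs (subcohort genotype counts and published HRs),
with no fitting — the entry point for checking the package against the
published table. Two inconsistencies in the printed source are preserved,
not resolved: the FGG rs2066865 female heterozygote count (2845) disagrees
with its printed percentage (36.1%), and only the percentages are consistent
with the published prevalence 0.42 for that row; and a few published PAFs
(e.g. ABO women, 16.9%) differ by about 0.1 point from the recomputation
because the printed HR is rounded to two decimals. The packaged tables store
counts and percentages exactly as printed, and prevalence-from-counts is
used everywhere.
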