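# pafcc

Population attributable fractions (PAF) of venous thromboembolism (VTE) for
carrier-coded prothrombotic genotypes, estimated from case-cohort data.

## The problem

VTE has a strong genetic component: a panel of common SNPs (factor V Leiden
rs6025, the prothrombin variant rs1799963, the ABO non-O blood-group site
rs8176719, two F11 variants, FGG rs2066865, and others) each raises risk
modestly, but because carriers are common the fraction of disease burden they
account for is substantial. The PAF answers "what fraction of cases would not
occur if carriers had the noncarriers' hazard", via Levin's formula

    PAF = p (HR - 1) / ( p (HR - 1) + 1 )

with `p` the carrier prevalence in the population and `HR` the hazard ratio
for carriers vs noncarriers. `pafcc` implements the full estimation pipeline
used in population-based case-cohort studies of VTE genetics:

* **Carrier coding** (`classify_carrier`, `carrier_prevalence`,
  `allele_frequency`): an individual with >= 1 risk allele is a carrier,
  dosage ignored; six panel SNPs code the *major* allele as the risk allele,
  and rs8176719 treats the non-deleted G allele (non-O blood type) as the
  risk allele. Genotypes can be read from cohort TSV files or VCF
  (`read_genotypes_vcf`).
* **Case-cohort Cox regression** (`coxcc`): all incident cases plus a random
  subcohort; Prentice risk sets (subcohort members at risk over their whole
  follow-up, outside-subcohort cases only just before their own event), age
  as the time scale with delayed entry at inclusion age, BMI adjustment,
  Breslow or Efron ties, sandwich (robust) standard errors, and Schoenfeld
  residual checks of proportional hazards
  (`check_proportional_hazards`).
* **PAF estimation** (`single_snp_paf`, `cumulative_paf_curve`,
  `age_band_cumulative_paf`): carrier prevalence always estimated from the
  subcohort (the population-representative part of the design); cumulative
  multi-SNP models use the union exposure "carrier at >= 1 SNP of the set" vs
  "noncarrier at all", with SNPs added in the published order ABO, F11
  (rs2036914), F11 (rs2289252), FVL, FGG, F2, on one shared complete-case
  set; age-band stratification clips each risk interval to the band.
* **Bias-corrected bootstrap** (`bootstrap_paf`, `bias_corrected_interval`):
  BC (not BCa) percentile intervals, default 10,000 replicates, resampling
  the subcohort and the outside-subcohort cases as separate strata.
* **Synthetic cohorts** (`simulate_cohort`, `sample_case_cohort`): two-sex
  cohorts with independent Hardy-Weinberg loci at the published subcohort
  allele frequencies (`vte_snp_panel()`), Gompertz baseline hazard on the age
  scale, proportional-hazards event times by inverse transform, and
  case-cohort sampling in which cases can also fall in the subcohort. The
  individual-level study data are not public; the simulator provides data
  with the same statistical structure for validating every estimator.
* **Pipeline runners** (`run_individual_table`, `run_cumulative`,
  `run_age_stratified`, `paf_from_printed`): config-driven reproduction of
  the per-SNP table and cumulative curves, with deterministic seed-stamped
  outputs.

## Worked example

```r
library(pafcc)

cohort <- simulate_cohort(cohort_config(n_individuals = 50000, seed = 42))
cc <- sample_case_cohort(cohort, subcohort_size = 7000, seed = 42)
cc
#> Case-cohort sample: 9562 rows (2977 cases, subcohort 7000 of 50000 source
#> individuals, 415 overlap)

single_snp_paf(cc, "rs6025", sex = "female")
#> PAF for rs6025 (female)
#>   carrier prevalence: 0.0708 (260/3673 subcohort)
#>   hazard ratio:       1.70 (95% CI 1.32-2.20)
#>   PAF:                4.7%
#>   n = 4723, events = 1214, dropped = 0

cumulative_paf_curve(cc, cumulative_model_snps(), sex = "female")
#> Cumulative PAF curve (female): n = 4723
#>     snp_id n_snps      p    hr   paf ci_low ci_high
#>  rs8176719      1 0.6322 1.142  8.2%     NA      NA
#>  rs2036914      2 0.9183 1.386 26.2%     NA      NA
#>  rs2289252      3 0.9717 1.413 28.6%     NA      NA
#>     rs6025      4 0.9736 1.371 26.5%     NA      NA
#>  rs2066865      5 0.9845 1.335 24.8%     NA      NA
#>  rs1799963      6 0.9845 1.335 24.8%     NA      NA
```

Reading the curve: after adding each SNP, `p` is the subcohort prevalence of
"carrier at >= 1 SNP of the prefix" (non-decreasing by construction), `hr` the
BMI-adjusted Prentice-weighted hazard ratio of that union exposure, and `paf`
Levin's formula applied to the two. The simulated female curve is lower than
the published one mainly because one random cohort draw gives hazard ratios
below the published point estimates for several high-prevalence SNPs; the
bootstrap columns are filled when the curve is run through
`run_cumulative()` or `bootstrap_paf()`.

The printed-input mode reproduces the published per-SNP arithmetic with no
fitting at all:

```r
tab <- paf_from_printed()
subset(tab, snp_id == "rs6025")
#>    gene snp_id    sex n_total n_het n_hom      p   hr    paf paf_pct published_paf_pct
#> 21  FVL rs6025 female    6909   434    10 0.0643 2.48 0.0869     8.7               8.7
#> 22  FVL rs6025   male    6160   420     5 0.0690 2.17 0.0747     7.5               7.5
```

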