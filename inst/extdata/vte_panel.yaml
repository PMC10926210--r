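# 17-SNP venous thromboembolism panel.
# risk_allele_freq: subcohort risk-allele frequency (sex-weighted average of
#   the female (n=6909) and male (n=6160) subcohort frequencies).
# log_hr_female / log_hr_male: log of the published sex-specific carrier
#   hazard ratios; used as simulation parameters by simulate_cohort().
- snp_id: rs1613662
  gene: GP6
  coding_rule: major_allele_risk
  risk_allele_freq: 0.8261
  log_hr_female: -0.1053605
  log_hr_male: 0.4824261
- snp_id: rs1801020
  gene: F12
  coding_rule: major_allele_risk
  risk_allele_freq: 0.7441
  log_hr_female: 0.0392207
  log_hr_male: -0.1165338
- snp_id: rs4524
  gene: F5
  coding_rule: major_allele_risk
  risk_allele_freq: 0.7285
  log_hr_female: 0.2390169
  log_hr_male: 0.6780335
- snp_id: rs2036914
  gene: F11
  coding_rule: major_allele_risk
  risk_allele_freq: 0.5306
  log_hr_female: 0.2390169
  log_hr_male: 0.1655144
- snp_id: rs1039084
  gene: STXBP5
  coding_rule: major_allele_risk
  risk_allele_freq: 0.5149
  log_hr_female: 0.1397619
  log_hr_male: 0.0295588
- snp_id: rs1884841
  gene: TC2N
  coding_rule: major_allele_risk
  risk_allele_freq: 0.4306
  log_hr_female: 0.1823216
  log_hr_male: 0.0295588
- snp_id: rs710446
  gene: KNG1
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.4126
  log_hr_female: 0.0676586
  log_hr_male: -0.0304592
- snp_id: rs2289252
  gene: F11
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.3916
  log_hr_female: 0.2468601
  log_hr_male: 0.1739533
- snp_id: rs8176719
  gene: ABO
  coding_rule: abo_deletion
  risk_allele_freq: 0.3835
  log_hr_female: 0.2851790
  log_hr_male: 0.3646431
- snp_id: rs1063857
  gene: VWF
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.3816
  log_hr_female: 0.0487902
  log_hr_male: 0.0099503
- snp_id: rs5985
  gene: F13
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.2668
  log_hr_female: 0.0676586
  log_hr_male: 0.1397619
- snp_id: rs2066865
  gene: FGG
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.2393
  log_hr_female: 0.1397619
  log_hr_male: 0.1823216
- snp_id: rs2227589
  gene: SERP
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.0875
  log_hr_female: 0.1823216
  log_hr_male: 0.0
- snp_id: rs3813948
  gene: C4BPB
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.0765
  log_hr_female: 0.0099503
  log_hr_male: -0.0725707
- snp_id: rs6025
  gene: FVL
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.0339
  log_hr_female: 0.9082586
  log_hr_male: 0.7747272
- snp_id: rs3136520
  gene: F2
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.0305
  log_hr_female: -0.0512933
  log_hr_male: 0.1484200
- snp_id: rs1799963
  gene: F2
  coding_rule: minor_allele_risk
  risk_allele_freq: 0.0065
  log_hr_female: 0.1570038
  log_hr_male: 0.5822156
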