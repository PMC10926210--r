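#' Define a SNP panel
#'
#' A SNP panel describes the exposure definitions used throughout the package:
#' one row per SNP with its identifier, gene label, carrier coding rule,
#' population risk-allele frequency (used by the cohort simulator to draw
#' Hardy-Weinberg genotypes) and sex-specific simulation log-hazard ratios.
#'
#' Coding rules:
#' \describe{
#'   \item{`minor_allele_risk`}{the minor allele is the risk allele (most SNPs).}
#'   \item{`major_allele_risk`}{the major allele is the risk allele, so the
#'     risk-allele count is high in most individuals.}
#'   \item{`abo_deletion`}{the non-deleted (G) allele marks non-O blood type and
#'     is the risk allele; homozygous deletion carriers (blood type O) are the
#'     reference. Behaves like any other risk-allele count internally; the rule
#'     only changes how VCF genotypes are translated to counts.}
#' }
#'
#' @param snp_id character vector of unique SNP identifiers (e.g. `"rs6025"`).
#' @param gene character vector of gene labels.
#' @param coding_rule one of `"minor_allele_risk"`, `"major_allele_risk"`,
#'   `"abo_deletion"` per SNP.
#' @param risk_allele_freq risk-allele frequency in `[0, 1]` per SNP.
#' @param log_hr_female,log_hr_male simulation log-hazard ratios for carriers
#'   (vs noncarriers) used by [simulate_cohort()].
#' @return A data frame of class `snp_panel`.
#' @seealso [vte_snp_panel()] for the packaged 17-SNP venous thromboembolism
#'   panel, [read_panel()] to load a panel from a YAML file.
#' @export
#' @examples
#' snp_panel("rs6025", "FVL", "minor_allele_risk", 0.034,
#'           log_hr_female = log(2.48), log_hr_male = log(2.17))
snp_panel <- function(snp_id, gene, coding_rule, risk_allele_freq,
                      log_hr_female = 0, log_hr_male = 0) {
  rules <- c("minor_allele_risk", "major_allele_risk", "abo_deletion")
  panel <- data.frame(
    snp_id = as.character(snp_id),
    gene = as.character(gene),
    coding_rule = as.character(coding_rule),
    risk_allele_freq = as.numeric(risk_allele_freq),
    log_hr_female = as.numeric(rep_len(log_hr_female, length(snp_id))),
    log_hr_male = as.numeric(rep_len(log_hr_male, length(snp_id))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(panel$snp_id))
    stop("snp_id must be unique within a panel", call. = FALSE)
  if (!all(panel$coding_rule %in% rules))
    stop("coding_rule must be one of: ", paste(rules, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(panel$risk_allele_freq)) ||
      any(panel$risk_allele_freq < 0) || any(panel$risk_allele_freq > 1))
    stop("risk_allele_freq must lie in [0, 1]", call. = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Read a SNP panel from a YAML file
#'
#' The file holds a list of entries mirroring the [snp_panel()] fields:
#' `snp_id`, `gene`, `coding_rule`, `risk_allele_freq`, `log_hr_female`,
#' `log_hr_male`.
#'
#' @param path path to a YAML panel definition.
#' @return A `snp_panel` data frame.
#' @export
read_panel <- function(path) {
  entries <- yaml::read_yaml(path)
  if (!is.list(entries) || length(entries) == 0)
    stop("panel file is empty or not a YAML list: ", path, call. = FALSE)
  need <- c("snp_id", "gene", "coding_rule", "risk_allele_freq")
  for (e in entries) {
    miss <- setdiff(need, names(e))
    if (length(miss))
      stop("panel entry missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  get <- function(f, default = NULL) {
    vapply(entries, function(e) {
      v <- e[[f]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing field ", f, call. = FALSE)
        v <- default
      }
      v
    }, if (f %in% c("snp_id", "gene", "coding_rule")) character(1) else numeric(1))
  }
  snp_panel(
    snp_id = get("snp_id"), gene = get("gene"),
    coding_rule = get("coding_rule"),
    risk_allele_freq = get("risk_allele_freq"),
    log_hr_female = get("log_hr_female", 0),
    log_hr_male = get("log_hr_male", 0)
  )
}

#' The packaged 17-SNP venous thromboembolism panel
#'
#' Seventeen SNPs with recognized association with venous thromboembolism,
#' carrier-coded. Risk-allele frequencies are subcohort estimates from a
#' Norwegian population-based case-cohort (sex-weighted average of the female
#' and male subcohort frequencies); the simulation log-hazard ratios are the
#' logs of the published sex-specific carrier hazard ratios, so cohorts
#' simulated from this panel emulate that study population. Six SNPs
#' (rs2036914, rs1801020, rs1039084, rs1884841, rs1613662, rs4524) are coded
#' with the major allele as the risk allele; rs8176719 uses the ABO deletion
#' rule (G allele = non-O blood type = risk).
#'
#' @return A `snp_panel` data frame with 17 rows.
#' @export
#' @examples
#' vte_snp_panel()
vte_snp_panel <- function() {
  read_panel(system.file("extdata", "vte_panel.yaml", package = "pafcc",
                         mustWork = TRUE))
}

#' The published 6-SNP cumulative model order
#'
#' The fixed SNP order of the cumulative PAF model: ABO (rs8176719),
#' F11 (rs2036914), F11 (rs2289252), FVL (rs6025), FGG (rs2066865) and
#' F2 (rs1799963). SNPs were ordered by descending individual PAF, with
#' prothrombin (F2) appended despite its low PAF because of its considerable
#' hazard ratio.
#'
#' @return Character vector of six SNP identifiers.
#' @export
cumulative_model_snps <- function() {
  c("rs8176719", "rs2036914", "rs2289252", "rs6025", "rs2066865", "rs1799963")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel with", nrow(x), "loci\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
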