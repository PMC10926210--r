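#' Classify individuals as carriers or noncarriers
#'
#' Carrier status is dichotomous: an individual carrying at least one copy of
#' the risk allele is a carrier, regardless of dosage; zero copies is a
#' noncarrier. No distinction is made between hetero- and homozygous carriers.
#'
#' @param g integer vector of risk-allele counts, values in `{0, 1, 2, NA}`.
#' @param snp_id optional SNP label used in error messages.
#' @return Factor with levels `noncarrier`, `carrier`; `NA` where the genotype
#'   is missing.
#' @export
#' @examples
#' classify_carrier(c(0, 1, 2, NA))
classify_carrier <- function(g, snp_id = NULL) {
  g <- check_genotype(g, snp_id)
  factor(ifelse(is.na(g), NA, ifelse(g >= 1, "carrier", "noncarrier")),
         levels = c("noncarrier", "carrier"))
}

# Validate a risk-allele count vector; names the offending individuals and SNP.
check_genotype <- function(g, snp_id = NULL) {
  if (is.factor(g)) g <- as.character(g)
  g <- suppressWarnings(as.numeric(g))
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)))
  if (length(bad)) {
    stop("invalid risk-allele count",
         if (!is.null(snp_id)) paste0(" for ", snp_id),
         " at individual(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": values must be 0, 1, 2 or NA", call. = FALSE)
  }
  as.integer(g)
}

#' Carrier prevalence in a subset of individuals
#'
#' The proportion of carriers (risk-allele count >= 1) among individuals with
#' a nonmissing genotype in the given subset. Missing genotypes are excluded
#' from the denominator (per-SNP complete case).
#'
#' @inheritParams classify_carrier
#' @param mask logical or integer index selecting individuals; default all.
#' @return List with `prevalence`, `n_carriers` and `n` (nonmissing
#'   denominator).
#' @export
#' @examples
#' carrier_prevalence(c(0, 1, 2, NA, 0))  # 2 carriers of 4 genotyped
carrier_prevalence <- function(g, mask = NULL, snp_id = NULL) {
  g <- check_genotype(g, snp_id)
  if (!is.null(mask)) g <- g[mask]
  if (length(g) == 0) stop("mask selects no individuals", call. = FALSE)
  ok <- !is.na(g)
  if (!any(ok))
    stop("carrier prevalence undefined: all genotypes missing",
         if (!is.null(snp_id)) paste0(" for ", snp_id), call. = FALSE)
  n_car <- sum(g[ok] >= 1L)
  list(prevalence = n_car / sum(ok), n_carriers = n_car, n = sum(ok))
}

#' Risk-allele frequency in a subset of individuals
#'
#' `(heterozygotes + 2 * homozygotes) / (2 * nonmissing individuals)`.
#'
#' @inheritParams carrier_prevalence
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(c(1, 1, 0, 2))  # 4 risk alleles of 8
allele_frequency <- function(g, mask = NULL, snp_id = NULL) {
  g <- check_genotype(g, snp_id)
  if (!is.null(mask)) g <- g[mask]
  if (length(g) == 0) stop("mask selects no individuals", call. = FALSE)
  ok <- !is.na(g)
  if (!any(ok))
    stop("allele frequency undefined: all genotypes missing",
         if (!is.null(snp_id)) paste0(" for ", snp_id), call. = FALSE)
  sum(g[ok]) / (2 * sum(ok))
}

#' Read panel genotypes from a VCF file as risk-allele counts
#'
#' Extracts GT fields for the panel's sites and translates them to risk-allele
#' counts according to each SNP's coding rule: for `minor_allele_risk` the ALT
#' allele is counted as the risk allele, for `major_allele_risk` the REF allele
#' is counted (count = 2 - ALT dosage), and for `abo_deletion` the longer of
#' REF/ALT (the non-deleted allele, marking non-O blood type) is the risk
#' allele. Missing genotypes (`./.`) become `NA`. Sites are matched by the ID
#' column against `panel$snp_id`.
#'
#' Requires the `vcfR` package.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param panel a [snp_panel()].
#' @return Data frame of risk-allele counts, one column per panel SNP found in
#'   the file (columns for absent sites are `NA`), one row per sample.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf() requires the 'vcfR' package", call. = FALSE)
  stopifnot(inherits(panel, "snp_panel"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  out <- as.data.frame(
    matrix(NA_integer_, nrow = length(samples), ncol = nrow(panel),
           dimnames = list(samples, panel$snp_id))
  )
  for (i in seq_len(nrow(panel))) {
    row <- which(fix[, "ID"] == panel$snp_id[i])
    if (length(row) == 0) next
    if (length(row) > 1)
      stop("site ", panel$snp_id[i], " appears more than once in ", path,
           call. = FALSE)
    ref <- fix[row, "REF"]
    alt <- fix[row, "ALT"]
    # ALT dosage from the GT string (phased or unphased, diploid)
    alleles <- strsplit(gsub("\\|", "/", gt[row, ]), "/", fixed = FALSE)
    alt_count <- vapply(alleles, function(a) {
      if (length(a) != 2 || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    risk_is_alt <- switch(panel$coding_rule[i],
      minor_allele_risk = TRUE,
      major_allele_risk = FALSE,
      abo_deletion = nchar(alt) > nchar(ref)
    )
    out[[panel$snp_id[i]]] <- if (risk_is_alt) alt_count else 2L - alt_count
  }
  out
}
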