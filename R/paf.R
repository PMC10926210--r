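#' Levin's population attributable fraction
#'
#' `PAF = p (HR - 1) / (p (HR - 1) + 1)`, where `p` is the prevalence of
#' carriers in the population and `HR` the hazard ratio in carriers vs
#' noncarriers. The PAF is the proportion of cases attributable to the
#' exposure; it is negative when `HR < 1`, zero when `HR = 1`, and approaches
#' `(HR - 1)/HR` in the exposure-saturated limit `p = 1`.
#'
#' @param p carrier prevalence, in `[0, 1]`. Vectorized.
#' @param hr hazard ratio, `> 0`. Vectorized.
#' @return PAF as a proportion (strictly below 1).
#' @export
#' @examples
#' levin_paf(444 / 6909, 2.48)  # 0.0869 -> reported as 8.7%
#' levin_paf(0.5, 2)            # 1/3
levin_paf <- function(p, hr) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("hr must be > 0", call. = FALSE)
  x <- p * (hr - 1)
  x / (x + 1)
}

#' Combined carrier indicator over a set of SNPs
#'
#' The union exposure of the cumulative model: an individual is a combined
#' carrier iff they carry at least one risk allele at \emph{any} SNP in the
#' set; the reference group is noncarrier at \emph{all} SNPs. Individuals with
#' a missing genotype at any SNP in the set are returned as `NA` and thereby
#' excluded from complete-case analyses.
#'
#' @param data a cohort or case-cohort data frame holding one risk-allele
#'   count column per SNP.
#' @param snp_set character vector of SNP ids (columns of `data`).
#' @return Integer vector: 1 combined carrier, 0 reference, `NA` missing.
#' @export
combined_carrier <- function(data, snp_set) {
  if (length(snp_set) == 0) stop("snp_set must be nonempty", call. = FALSE)
  unknown <- setdiff(snp_set, names(data))
  if (length(unknown))
    stop("unknown snp_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  G <- as.matrix(data[, snp_set, drop = FALSE])
  carrier <- as.integer(rowSums(G >= 1L) > 0)
  carrier[rowSums(is.na(G)) > 0] <- NA_integer_
  carrier
}

#' PAF of a single SNP from a case-cohort sample
#'
#' Carrier prevalence is estimated from subcohort members only (the subcohort
#' is the population-representative part of the design), the hazard ratio from
#' a Prentice-weighted Cox model with age as the time scale adjusted for BMI,
#' and the PAF by Levin's formula. Individuals missing the genotype or BMI are
#' dropped (complete case).
#'
#' @param sample a `case_cohort` sample.
#' @param snp_id SNP column to analyze.
#' @param sex `"female"` or `"male"`; `NULL` analyzes both sexes together.
#' @param adjust_bmi adjust the hazard model for standardized BMI (default).
#' @param weighting,ties passed to the Cox fitter.
#' @param robust compute sandwich standard errors for the hazard ratio.
#' @return Object of class `paf_result`: `exposure_label`, `sex`, `p` (with
#'   numerator/denominator), `hr` with confidence interval, `paf`, empty
#'   bootstrap interval slots (`ci_low`, `ci_high`, filled by
#'   [bootstrap_paf()]), and `n_used`.
#' @export
single_snp_paf <- function(sample, snp_id, sex = NULL, adjust_bmi = TRUE,
                           weighting = "prentice", ties = "breslow",
                           robust = TRUE) {
  if (!snp_id %in% names(sample))
    stop("unknown snp_id: ", snp_id, call. = FALSE)
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("female", "male"))
    sample <- sample[sample$sex == sex, , drop = FALSE]
  }
  g <- check_genotype(sample[[snp_id]], snp_id)
  carrier <- as.integer(g >= 1L)
  prev <- carrier_prevalence(g, mask = sample$in_subcohort, snp_id = snp_id)

  X <- if (adjust_bmi) cbind(carrier = carrier,
                             bmi = standardize(sample$bmi))
       else cbind(carrier = carrier)
  fit <- coxcc_core(sample$entry_age, sample$exit_age,
                    as.integer(sample$event), sample$in_subcohort, X,
                    weighting = weighting, ties = ties, robust = robust)
  hr <- unname(fit$hr["carrier"])
  out <- list(
    exposure_label = snp_id, sex = if (is.null(sex)) "both" else sex,
    p = prev$prevalence, n_carriers = prev$n_carriers,
    n_subcohort = prev$n, hr = hr,
    hr_ci = c(unname(fit$ci_low["carrier"]), unname(fit$ci_high["carrier"])),
    paf = levin_paf(prev$prevalence, hr),
    ci_low = NA_real_, ci_high = NA_real_,
    n_used = fit$n, n_dropped = fit$n_dropped, n_events = fit$n_events,
    converged = fit$converged, fit = fit
  )
  class(out) <- "paf_result"
  out
}

standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

#' @export
print.paf_result <- function(x, ...) {
  cat("PAF for ", x$exposure_label, " (", x$sex, ")\n", sep = "")
  cat(sprintf("  carrier prevalence: %.4f (%d/%d subcohort)\n",
              x$p, x$n_carriers, x$n_subcohort))
  cat(sprintf("  hazard ratio:       %.2f (95%% CI %.2f-%.2f)\n",
              x$hr, x$hr_ci[1], x$hr_ci[2]))
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (95%% CI %.1f%% to %.1f%%)", 100 * x$ci_low, 100 * x$ci_high)
  cat(sprintf("  PAF:                %.1f%%%s\n", 100 * x$paf, ci))
  cat(sprintf("  n = %d, events = %d, dropped = %d\n",
              x$n_used, x$n_events, x$n_dropped))
  invisible(x)
}

#' Cumulative PAF curve over an ordered SNP set
#'
#' SNPs are added one by one; after each addition the exposure is the combined
#' carrier indicator (carrier at >= 1 SNP of the prefix, reference noncarrier
#' at all of them), its prevalence is estimated from the subcohort, its hazard
#' ratio from the Prentice-weighted Cox model, and the cumulative PAF by
#' Levin's formula. A single complete-case set — individuals nonmissing at
#' \emph{all} SNPs of the full model (and BMI, if adjusted) — is used for every
#' prefix so the curve is internally comparable. The combined prevalence is
#' non-decreasing along the curve by construction.
#'
#' @inheritParams single_snp_paf
#' @param panel_order ordered character vector of SNP ids. The default is the
#'   published fixed 6-SNP order ([cumulative_model_snps()]); pass
#'   `order = "data"` to derive the order from the data by descending
#'   single-SNP PAF with `force_last` SNPs appended at the end.
#' @param order `"fixed"` (use `panel_order` as given) or `"data"`.
#' @param force_last SNPs appended last under data-derived ordering despite a
#'   low individual PAF (default prothrombin rs1799963, kept for its
#'   considerable hazard ratio).
#' @return Object of class `paf_curve`: a data frame with one row per prefix
#'   (`snp_id`, `n_snps`, `p`, `hr`, `paf`, `ci_low`, `ci_high`) plus
#'   attributes `sex`, `n_used`, `n_dropped`, `age_band`.
#' @export
cumulative_paf_curve <- function(sample, panel_order = cumulative_model_snps(),
                                 sex = NULL, adjust_bmi = TRUE,
                                 weighting = "prentice", ties = "breslow",
                                 order = c("fixed", "data"),
                                 force_last = "rs1799963") {
  order <- match.arg(order)
  if (length(panel_order) == 0) stop("panel_order must be nonempty",
                                     call. = FALSE)
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("female", "male"))
    sample <- sample[sample$sex == sex, , drop = FALSE]
  }
  unknown <- setdiff(panel_order, names(sample))
  if (length(unknown))
    stop("unknown snp_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  # one shared complete-case set for every prefix
  G <- as.matrix(sample[, panel_order, drop = FALSE])
  cc <- rowSums(is.na(G)) == 0
  if (adjust_bmi) cc <- cc & !is.na(sample$bmi)
  n_dropped <- sum(!cc)
  sample <- sample[cc, , drop = FALSE]

  if (order == "data") {
    main <- setdiff(panel_order, force_last)
    paf1 <- vapply(main, function(s)
      single_snp_paf(sample, s, sex = NULL, adjust_bmi = adjust_bmi,
                     weighting = weighting, ties = ties,
                     robust = FALSE)$paf, numeric(1))
    panel_order <- c(main[base::order(-paf1)],
                     intersect(panel_order, force_last))
  }

  bmi_z <- if (adjust_bmi) standardize(sample$bmi) else NULL
  rows <- vector("list", length(panel_order))
  for (k in seq_along(panel_order)) {
    expo <- combined_carrier(sample, panel_order[seq_len(k)])
    n_car <- sum(expo[sample$in_subcohort] == 1L)
    if (n_car == 0 || sum(sample$event) == 0) {
      warning("curve truncated at ", k, " SNPs: no combined carriers or no events")
      rows <- rows[seq_len(k - 1)]
      break
    }
    prev <- carrier_prevalence(expo, mask = sample$in_subcohort)
    X <- if (adjust_bmi) cbind(carrier = expo, bmi = bmi_z)
         else cbind(carrier = expo)
    fit <- coxcc_core(sample$entry_age, sample$exit_age,
                      as.integer(sample$event), sample$in_subcohort, X,
                      weighting = weighting, ties = ties, robust = FALSE)
    rows[[k]] <- data.frame(
      snp_id = panel_order[k], n_snps = k, p = prev$prevalence,
      hr = unname(fit$hr["carrier"]),
      paf = levin_paf(prev$prevalence, unname(fit$hr["carrier"])),
      ci_low = NA_real_, ci_high = NA_real_
    )
  }
  curve <- do.call(rbind, rows)
  attr(curve, "sex") <- if (is.null(sex)) "both" else sex
  attr(curve, "n_used") <- nrow(sample)
  attr(curve, "n_dropped") <- n_dropped
  attr(curve, "age_band") <- NULL
  attr(curve, "snp_order") <- panel_order
  class(curve) <- c("paf_curve", "data.frame")
  curve
}

#' @export
print.paf_curve <- function(x, ...) {
  band <- attr(x, "age_band")
  cat("Cumulative PAF curve (", attr(x, "sex"),
      if (!is.null(band)) paste0(", ages (", band[1], ", ",
                                 if (is.finite(band[2])) band[2] else "inf",
                                 "]"),
      "): n = ", attr(x, "n_used"), "\n", sep = "")
  y <- as.data.frame(x)
  y$paf <- sprintf("%.1f%%", 100 * y$paf)
  print(y, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.paf_curve <- function(x, col = "steelblue", add = FALSE, ...) {
  paf <- 100 * x$paf
  if (!add) {
    plot(x$n_snps, paf, type = "b", pch = 16, col = col,
         xlab = "Number of SNPs in model", ylab = "Cumulative PAF (%)",
         xaxt = "n", ...)
    axis(1, at = x$n_snps, labels = x$snp_id, las = 2, cex.axis = 0.7)
  } else {
    lines(x$n_snps, paf, type = "b", pch = 16, col = col)
  }
  invisible(x)
}

#' Age-band stratified cumulative PAF curves
#'
#' Each individual's risk interval is intersected with each age band: entry is
#' clipped up to the band start, exit down to the band end, and the event is
#' counted only if the event age falls inside the band (bands are half-open,
#' `(low, high]`). Individuals with no risk time in a band are excluded from
#' that band; under Prentice weighting, non-subcohort cases whose event falls
#' outside the band contribute nothing and are dropped. The cumulative curve
#' is then computed on the clipped data.
#'
#' @inheritParams cumulative_paf_curve
#' @param bands list of `c(low, high)` pairs, non-overlapping and covering
#'   `(0, Inf)`. Default `(0, 50], (50, 75], (75, Inf)`.
#' @return List of `paf_curve` objects (one per band, named `"(low,high]"`);
#'   bands with zero events yield an entry flagged unavailable rather than a
#'   fabricated curve.
#' @export
age_band_cumulative_paf <- function(sample,
                                    panel_order = cumulative_model_snps(),
                                    sex = NULL, adjust_bmi = TRUE,
                                    weighting = "prentice", ties = "breslow",
                                    bands = list(c(0, 50), c(50, 75),
                                                 c(75, Inf))) {
  check_bands(bands)
  out <- vector("list", length(bands))
  names(out) <- vapply(bands, function(b)
    paste0("(", b[1], ",", if (is.finite(b[2])) b[2] else "Inf", "]"),
    character(1))
  for (i in seq_along(bands)) {
    clipped <- clip_to_band(sample, bands[[i]][1], bands[[i]][2])
    if (nrow(clipped) == 0 || sum(clipped$event) == 0) {
      out[[i]] <- structure(list(available = FALSE, age_band = bands[[i]],
                                 reason = "no events in band"),
                            class = "paf_band_unavailable")
      next
    }
    curve <- cumulative_paf_curve(clipped, panel_order = panel_order,
                                  sex = sex, adjust_bmi = adjust_bmi,
                                  weighting = weighting, ties = ties)
    attr(curve, "age_band") <- bands[[i]]
    out[[i]] <- curve
  }
  out
}

check_bands <- function(bands) {
  if (!is.list(bands) || length(bands) == 0)
    stop("bands must be a nonempty list of c(low, high) pairs", call. = FALSE)
  m <- do.call(rbind, bands)
  m <- m[base::order(m[, 1]), , drop = FALSE]
  if (m[1, 1] != 0 || !is.infinite(m[nrow(m), 2]) ||
      (nrow(m) > 1 && any(m[-1, 1] != m[-nrow(m), 2])))
    stop("bands must be non-overlapping and cover (0, Inf)", call. = FALSE)
  invisible(bands)
}

# Intersect each risk interval with (low, high]; keep rows with positive
# clipped risk time; events counted only if the event age is in the band.
clip_to_band <- function(sample, low, high) {
  entry2 <- pmax(sample$entry_age, low)
  exit2 <- pmin(sample$exit_age, high)
  event2 <- sample$event & sample$exit_age > low & sample$exit_age <= high
  keep <- exit2 > entry2
  if ("in_subcohort" %in% names(sample))
    keep <- keep & (sample$in_subcohort | event2)  # Prentice: off-band cases drop
  out <- sample[keep, , drop = FALSE]
  out$entry_age <- entry2[keep]
  out$exit_age <- exit2[keep]
  out$event <- event2[keep]
  for (a in c("panel", "subcohort_size", "source_size", "sampling_fraction"))
    attr(out, a) <- attr(sample, a)
  class(out) <- class(sample)
  out
}

#' @export
print.paf_band_unavailable <- function(x, ...) {
  cat("Age band (", x$age_band[1], ", ",
      if (is.finite(x$age_band[2])) x$age_band[2] else "Inf",
      "]: unavailable (", x$reason, ")\n", sep = "")
  invisible(x)
}
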