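#' Printed-input PAF arithmetic
#'
#' Reproduces the published per-SNP PAF arithmetic without any survival
#' fitting: carrier prevalence is computed from printed subcohort genotype
#' counts (`(heterozygotes + homozygotes) / n`), the hazard ratio is taken as
#' printed, and Levin's formula is applied. Defaults use the packaged printed
#' tables of the 17-SNP venous thromboembolism panel.
#'
#' @param counts data frame like [printed_genotype_counts()]: columns `gene`,
#'   `snp_id`, `sex`, `n_total`, `n_het`, `n_hom`.
#' @param hrs data frame like [published_hazard_ratios()]: columns `snp_id`,
#'   `sex`, `hr` (and optionally the published `paf_pct` for comparison).
#' @return Data frame with one row per SNP and sex: prevalence `p` (from
#'   counts), `hr`, `paf` (proportion), `paf_pct` (percent, 1 decimal) and,
#'   when available, the published PAF.
#' @export
#' @examples
#' tab <- paf_from_printed()
#' subset(tab, snp_id == "rs6025")   # FVL: women 8.7%, men 7.5%
paf_from_printed <- function(counts = printed_genotype_counts(),
                             hrs = published_hazard_ratios()) {
  need_c <- c("snp_id", "sex", "n_total", "n_het", "n_hom")
  need_h <- c("snp_id", "sex", "hr")
  if (!all(need_c %in% names(counts)))
    stop("counts must have columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  if (!all(need_h %in% names(hrs)))
    stop("hrs must have columns: ", paste(need_h, collapse = ", "),
         call. = FALSE)
  names(hrs)[names(hrs) == "paf_pct"] <- "published_paf_pct"
  m <- merge(counts, hrs, by = c("snp_id", "sex"), suffixes = c("", ".hr"))
  m$p <- (m$n_het + m$n_hom) / m$n_total
  m$paf <- levin_paf(m$p, m$hr)
  m$paf_pct <- round(100 * m$paf, 1)
  keep <- intersect(c("gene", "snp_id", "sex", "n_total", "n_het", "n_hom",
                      "p", "hr", "paf", "paf_pct", "published_paf_pct"),
                    names(m))
  gene_col <- if ("gene" %in% names(m)) m$gene else m$snp_id
  out <- m[base::order(gene_col, m$snp_id, m$sex), keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged printed tables
#'
#' `printed_genotype_counts()` returns the printed subcohort genotype
#' distribution of the 17-SNP panel (per sex: heterozygote and homozygote
#' carrier counts with the printed percentages and allele frequencies).
#' `published_hazard_ratios()` returns the published sex-specific carrier
#' hazard ratios, prevalences and PAFs with their confidence intervals.
#'
#' Note one internal inconsistency of the printed source, preserved as
#' printed: the FGG (rs2066865) female row's heterozygote count (2845)
#' disagrees with its printed percentage (36.1%); the percentages, not the
#' counts, are consistent with the published prevalence (0.42) for that row.
#'
#' @return A data frame.
#' @export
printed_genotype_counts <- function() {
  read.delim(system.file("extdata", "subcohort_genotype_counts.tsv",
                         package = "pafcc", mustWork = TRUE))
}

#' @rdname printed_genotype_counts
#' @export
published_hazard_ratios <- function() {
  read.delim(system.file("extdata", "published_hr.tsv",
                         package = "pafcc", mustWork = TRUE))
}

#' Per-SNP PAF table for a case-cohort analysis
#'
#' For each panel SNP and requested sex: subcohort carrier prevalence, hazard
#' ratio with 95% CI (BMI-adjusted, age as time scale) and PAF with a
#' bias-corrected bootstrap 95% CI. Rows are ordered alphabetically by gene.
#' Per-SNP failures are recorded in the row's `note` column and the run
#' continues.
#'
#' @param config an `analysis_config` (see [read_analysis_config()] /
#'   [as_analysis_config()]).
#' @param sample optionally, a pre-built `case_cohort` sample (otherwise the
#'   config's data source is materialized).
#' @return Data frame of class `paf_table`; written to
#'   `<out_dir>/individual_paf.tsv` when the config names an output
#'   directory.
#' @export
run_individual_table <- function(config, sample = NULL) {
  cfg <- if (inherits(config, "analysis_config")) config else
    as_analysis_config(config)
  if (is.null(sample)) sample <- config_sample(cfg)
  panel <- cfg$panel
  spec <- bootstrap_spec(n_replicates = cfg$bootstrap$n_replicates,
                         alpha = cfg$bootstrap$alpha, seed = cfg$seed)
  rows <- list()
  excl <- character()
  for (sx in cfg$sexes) {
    for (i in seq_len(nrow(panel))) {
      sid <- panel$snp_id[i]
      row <- data.frame(gene = panel$gene[i], snp_id = sid, sex = sx,
                        prevalence = NA_real_, hr = NA_real_,
                        hr_low = NA_real_, hr_high = NA_real_,
                        paf = NA_real_, paf_low = NA_real_,
                        paf_high = NA_real_, n_used = NA_integer_,
                        n_dropped = NA_integer_, note = "")
      res <- tryCatch({
        pr <- single_snp_paf(sample, sid, sex = sx,
                             weighting = cfg$weighting, ties = cfg$ties)
        sub <- sample[sample$sex == sx, , drop = FALSE]
        est <- paf_estimator(sid, weighting = cfg$weighting, ties = cfg$ties)
        bt <- bootstrap_paf(sub, est, spec)
        row$prevalence <- pr$p
        row$hr <- pr$hr; row$hr_low <- pr$hr_ci[1]; row$hr_high <- pr$hr_ci[2]
        row$paf <- pr$paf
        row$paf_low <- bt$ci_low; row$paf_high <- bt$ci_high
        row$n_used <- pr$n_used; row$n_dropped <- pr$n_dropped
        row
      }, error = function(e) {
        row$note <- conditionMessage(e)
        row
      })
      if (!is.na(res$n_dropped))
        excl <- c(excl, sprintf("%s/%s: %d rows dropped (complete case)",
                                sx, sid, res$n_dropped))
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[base::order(out$gene, out$snp_id, out$sex), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paf_table", "data.frame")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(cfg$out_dir, "individual_paf.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_report(cfg, file.path(cfg$out_dir, "individual_paf_report.txt"),
                     "individual PAF table", excl)
  }
  out
}

# Scalar PAF estimator closures used by the bootstrap: recompute prevalence,
# Cox hazard ratio and Levin PAF from scratch on each resampled dataset.
paf_estimator <- function(snp_id, adjust_bmi = TRUE, weighting = "prentice",
                          ties = "breslow") {
  force(snp_id)
  function(s) {
    g <- s[[snp_id]]
    carrier <- as.integer(g >= 1L)
    insub <- s$in_subcohort
    gs <- carrier[insub]
    p <- mean(gs[!is.na(gs)])
    X <- if (adjust_bmi) cbind(carrier = carrier, bmi = standardize(s$bmi))
         else cbind(carrier = carrier)
    fit <- coxcc_core(s$entry_age, s$exit_age, as.integer(s$event), insub, X,
                      weighting = weighting, ties = ties, robust = FALSE)
    levin_paf(p, unname(fit$hr["carrier"]))
  }
}

cumulative_estimator <- function(panel_order, adjust_bmi = TRUE,
                                 weighting = "prentice", ties = "breslow") {
  force(panel_order)
  function(s) cumulative_paf_curve(s, panel_order = panel_order,
                                   adjust_bmi = adjust_bmi,
                                   weighting = weighting, ties = ties)
}

#' Cumulative PAF analysis per sex
#'
#' Builds the cumulative multi-SNP PAF curve for each requested sex, with
#' bias-corrected bootstrap intervals for every prefix of the model, and
#' writes TSV/JSON outputs plus a plain-text run report (seed, options,
#' complete-case counts, configuration hash). Outputs are deterministic:
#' rerunning with the same config and seed reproduces identical files.
#'
#' @inheritParams run_individual_table
#' @return Named list of `paf_curve` objects, one per sex.
#' @export
run_cumulative <- function(config, sample = NULL) {
  cfg <- if (inherits(config, "analysis_config")) config else
    as_analysis_config(config)
  if (is.null(sample)) sample <- config_sample(cfg)
  spec <- bootstrap_spec(n_replicates = cfg$bootstrap$n_replicates,
                         alpha = cfg$bootstrap$alpha, seed = cfg$seed)
  curves <- list()
  excl <- character()
  for (sx in cfg$sexes) {
    sub <- sample[sample$sex == sx, , drop = FALSE]
    for (a in c("panel", "subcohort_size", "source_size", "sampling_fraction"))
      attr(sub, a) <- attr(sample, a)
    curve <- cumulative_paf_curve(sub, panel_order = cfg$model_snps,
                                  weighting = cfg$weighting, ties = cfg$ties)
    bt <- bootstrap_paf(sub, cumulative_estimator(cfg$model_snps,
                                                  weighting = cfg$weighting,
                                                  ties = cfg$ties), spec)
    curve$ci_low <- bt$ci_low[curve$snp_id]
    curve$ci_high <- bt$ci_high[curve$snp_id]
    excl <- c(excl, sprintf("%s: %d rows dropped (complete case on %s + BMI)",
                            sx, attr(curve, "n_dropped"),
                            paste(cfg$model_snps, collapse = ",")))
    curves[[sx]] <- curve
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- do.call(rbind, lapply(names(curves), function(sx) {
      d <- as.data.frame(curves[[sx]]); d$sex <- sx; d
    }))
    write.table(flat, file.path(cfg$out_dir, "cumulative_paf.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(curves, function(cv) as.data.frame(cv)),
      file.path(cfg$out_dir, "cumulative_paf.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE
    )
    write_run_report(cfg, file.path(cfg$out_dir, "cumulative_paf_report.txt"),
                     "cumulative PAF curves", excl)
  }
  curves
}

#' Age-band stratified cumulative PAF analysis per sex
#'
#' @inheritParams run_individual_table
#' @return Nested list: per sex, a list of `paf_curve` objects per age band
#'   (bands with no events flagged unavailable). No bootstrap is run here;
#'   use [bootstrap_paf()] with a clipped sample for band-level intervals.
#' @export
run_age_stratified <- function(config, sample = NULL) {
  cfg <- if (inherits(config, "analysis_config")) config else
    as_analysis_config(config)
  if (is.null(sample)) sample <- config_sample(cfg)
  bands <- lapply(cfg$age_bands, function(b) {
    b <- as.numeric(b)
    if (is.na(b[2])) b[2] <- Inf
    b
  })
  out <- list()
  for (sx in cfg$sexes) {
    sub <- sample[sample$sex == sx, , drop = FALSE]
    for (a in c("panel", "subcohort_size", "source_size", "sampling_fraction"))
      attr(sub, a) <- attr(sample, a)
    out[[sx]] <- age_band_cumulative_paf(sub, panel_order = cfg$model_snps,
                                         weighting = cfg$weighting,
                                         ties = cfg$ties, bands = bands)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- list()
    for (sx in names(out)) for (bn in names(out[[sx]])) {
      cv <- out[[sx]][[bn]]
      if (inherits(cv, "paf_curve")) {
        d <- as.data.frame(cv); d$sex <- sx; d$band <- bn
        flat[[length(flat) + 1]] <- d
      }
    }
    if (length(flat))
      write.table(do.call(rbind, flat),
                  file.path(cfg$out_dir, "age_band_paf.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_report(cfg, file.path(cfg$out_dir, "age_band_paf_report.txt"),
                     "age-band cumulative PAF", character())
  }
  out
}

# Plain-text run report: configuration hash, seed, options and the
# complete-case exclusion counts (individuals are never dropped silently).
# Deliberately free of timestamps so reruns are byte-identical.
write_run_report <- function(cfg, path, what, exclusions) {
  # fingerprint of the analytic configuration: exclude the output location
  # and replace file paths by the loaded panel's contents, so the hash is
  # stable across machines and scratch directories
  plain <- cfg[setdiff(names(cfg), c("panel", "panel_file", "out_dir"))]
  plain$panel <- as.data.frame(cfg$panel)
  hash <- config_hash(paste(deparse(plain), collapse = "\n"))
  lines <- c(
    paste0("pafcc run report: ", what),
    paste0("config_hash: ", hash),
    paste0("seed: ", cfg$seed),
    paste0("weighting: ", cfg$weighting, "; ties: ", cfg$ties),
    paste0("bootstrap: B = ", cfg$bootstrap$n_replicates,
           ", alpha = ", cfg$bootstrap$alpha),
    paste0("model_snps: ", paste(cfg$model_snps, collapse = ", ")),
    "complete-case exclusions:",
    if (length(exclusions)) paste0("  ", exclusions) else "  none"
  )
  writeLines(lines, path)
  invisible(path)
}
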