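#' Write / read a cohort table
#'
#' Tab-delimited text with a header row and columns `id`, `sex`, `entry_age`,
#' `exit_age`, `event`, `bmi`, optionally `in_subcohort` and `is_case`, then
#' one column per SNP with risk-allele counts 0/1/2 or `NA`. `read_cohort`
#' validates the schema and per-row constraints (`exit_age > entry_age`,
#' genotype values in `{0,1,2,NA}`) and reports offending line numbers.
#'
#' @param cohort a `cohort_table` or `case_cohort` data frame.
#' @param path file path.
#' @param panel optional [snp_panel()]; if supplied, every `snp_id` must have
#'   a column and the panel is attached to the result.
#' @return `read_cohort` returns a `cohort_table` (or `case_cohort` when the
#'   file carries `in_subcohort`/`is_case` columns).
#' @export
write_cohort <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, panel = NULL) {
  x <- read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                  stringsAsFactors = FALSE)
  core <- c("id", "sex", "entry_age", "exit_age", "event", "bmi")
  miss <- setdiff(core, names(x))
  if (length(miss))
    stop("cohort file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  flags <- intersect(c("in_subcohort", "is_case"), names(x))
  snp_cols <- setdiff(names(x), c(core, flags))
  if (!is.null(panel)) {
    unknown <- setdiff(snp_cols, panel$snp_id)
    if (length(unknown))
      stop("cohort file has column(s) not in the panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    absent <- setdiff(panel$snp_id, snp_cols)
    if (length(absent))
      stop("cohort file lacks panel SNP column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!all(x$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male' (line ",
         which(!x$sex %in% c("female", "male"))[1] + 1, ")", call. = FALSE)
  x$sex <- factor(x$sex, levels = c("female", "male"))
  for (v in c("entry_age", "exit_age", "bmi"))
    if (!is.numeric(x[[v]]))
      stop("column ", v, " is not numeric in ", path, call. = FALSE)
  bad <- which(!(x$exit_age > x$entry_age))
  if (length(bad))
    stop("exit_age must exceed entry_age (line ", bad[1] + 1, ")",
         call. = FALSE)
  x$event <- as.logical(x$event)
  if (anyNA(x$event)) stop("event column must be logical (TRUE/FALSE)",
                           call. = FALSE)
  for (s in snp_cols) {
    x[[s]] <- tryCatch(check_genotype(x[[s]], s), error = function(e)
      stop("in ", path, ": ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(panel)) attr(x, "panel") <- panel
  if (all(c("in_subcohort", "is_case") %in% names(x))) {
    x$in_subcohort <- as.logical(x$in_subcohort)
    x$is_case <- as.logical(x$is_case)
    attr(x, "subcohort_size") <- sum(x$in_subcohort)
    attr(x, "source_size") <- NA_integer_
    attr(x, "sampling_fraction") <- NA_real_
    class(x) <- c("case_cohort", "data.frame")
  } else {
    class(x) <- c("cohort_table", "data.frame")
  }
  x
}

#' Read an analysis configuration from YAML
#'
#' The configuration drives the pipeline runners ([run_individual_table()],
#' [run_cumulative()], [run_age_stratified()]). Recognized fields:
#' `cohort_file` (read data) or `simulate` (a list of [cohort_config()]
#' fields), `panel_file` (defaults to the packaged 17-SNP panel),
#' `subcohort_size`, `model_snps` (defaults to [cumulative_model_snps()]),
#' `sexes`, `age_bands` (list of `[low, high]` pairs), `weighting`, `ties`,
#' `bootstrap` (`n_replicates`, `alpha`), `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_analysis_config(cfg)
}

#' @rdname read_analysis_config
#' @param cfg a named list with the fields above.
#' @export
as_analysis_config <- function(cfg) {
  defaults <- list(
    panel_file = NULL, subcohort_size = NULL,
    model_snps = cumulative_model_snps(),
    sexes = c("female", "male"),
    age_bands = list(c(0, 50), c(50, 75), c(75, Inf)),
    weighting = "prentice", ties = "breslow",
    bootstrap = list(n_replicates = 10000L, alpha = 0.05),
    seed = 1L, out_dir = NULL
  )
  cfg <- modifyList(defaults, cfg)
  cfg$panel <- if (is.null(cfg$panel_file)) vte_snp_panel() else
    read_panel(cfg$panel_file)
  if (!all(cfg$model_snps %in% cfg$panel$snp_id))
    stop("model_snps must be a subset of the panel's snp_ids", call. = FALSE)
  if (!all(cfg$sexes %in% c("female", "male")))
    stop("sexes must be 'female' and/or 'male'", call. = FALSE)
  if (is.null(cfg$cohort_file) && is.null(cfg$simulate))
    stop("config must provide either cohort_file or simulate", call. = FALSE)
  class(cfg) <- "analysis_config"
  cfg
}

# Materialize the analysis dataset declared by a config.
config_sample <- function(cfg) {
  if (!is.null(cfg$cohort_file)) {
    x <- read_cohort(cfg$cohort_file, panel = cfg$panel)
    if (inherits(x, "case_cohort")) return(x)
    if (is.null(cfg$subcohort_size))
      stop("subcohort_size required to sample a case-cohort from a full cohort",
           call. = FALSE)
    return(sample_case_cohort(x, cfg$subcohort_size, seed = cfg$seed))
  }
  sim <- cfg$simulate
  sim$panel <- cfg$panel
  if (is.null(sim$seed)) sim$seed <- cfg$seed
  cc_size <- cfg$subcohort_size
  if (is.null(cc_size))
    stop("subcohort_size required when simulating", call. = FALSE)
  cohort <- simulate_cohort(do.call(cohort_config, sim))
  sample_case_cohort(cohort, cc_size, seed = cfg$seed)
}
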