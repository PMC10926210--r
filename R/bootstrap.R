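#' Bootstrap specification
#'
#' @param n_replicates number of bootstrap replicates (default 10,000, the
#'   published setting; fewer than 100 triggers an instability warning at run
#'   time).
#' @param alpha two-sided miscoverage level (default 0.05 for 95% intervals).
#' @param seed integer seed; each replicate draws from a substream derived
#'   from `(seed, replicate index)`, so results do not depend on scheduling.
#' @param resampling `"stratified_design"` (default) resamples subcohort
#'   members and outside-subcohort cases independently, preserving each
#'   stratum's size — this respects the case-cohort design; `"iid_rows"`
#'   resamples all rows as one pool, for sensitivity.
#' @return List of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_replicates = 10000L, alpha = 0.05, seed = 1L,
                           resampling = c("stratified_design", "iid_rows")) {
  resampling <- match.arg(resampling)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(n_replicates = as.integer(n_replicates), alpha = alpha,
                 seed = as.integer(seed), resampling = resampling),
            class = "bootstrap_spec")
}

#' Bias-corrected percentile bootstrap interval
#'
#' The BC (not BCa: no acceleration term) interval. The bias-correction
#' constant is `z0 = qnorm((#\{theta* < theta\} + 0.5 #\{theta* = theta\}) / B)`
#' (half-tie convention), and the endpoints are the empirical quantiles of the
#' replicates at adjusted levels `pnorm(2 z0 + qnorm(alpha/2))` and
#' `pnorm(2 z0 + qnorm(1 - alpha/2))`. Quantiles use R's default interpolation
#' (`type = 7`), recorded in the result so intervals are reproducible
#' bit-for-bit. When every replicate falls on one side of the point estimate,
#' `z0` is infinite; the interval degenerates to the replicate extremes and is
#' flagged.
#'
#' @param replicates numeric vector of bootstrap estimates (non-finite values
#'   are dropped; at least 2 finite values required).
#' @param point the point estimate on the original sample.
#' @param alpha two-sided miscoverage level.
#' @return List with `low`, `high`, `z0`, the adjusted quantile `levels`,
#'   `degenerate` flag and `quantile_type` (7).
#' @export
#' @examples
#' bias_corrected_interval(c(1:10), point = 4, alpha = 0.05)
bias_corrected_interval <- function(replicates, point, alpha = 0.05) {
  replicates <- replicates[is.finite(replicates)]
  B <- length(replicates)
  if (B < 2) stop("need at least 2 finite replicates", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  frac <- (sum(replicates < point) + 0.5 * sum(replicates == point)) / B
  z0 <- qnorm(frac)
  degenerate <- !is.finite(z0)
  if (degenerate) {
    warning("all replicates on one side of the point estimate; ",
            "interval clamped to replicate extremes", call. = FALSE)
    lev <- c(0, 1)
    ci <- range(replicates)
  } else {
    lev <- pnorm(2 * z0 + qnorm(c(alpha / 2, 1 - alpha / 2)))
    ci <- unname(quantile(replicates, probs = lev, type = 7))
  }
  list(low = ci[1], high = ci[2], z0 = z0, levels = lev,
       degenerate = degenerate, quantile_type = 7L)
}

#' Bootstrap confidence interval for a PAF estimator
#'
#' Re-runs the full estimator (prevalence, Cox fit, Levin PAF) on resampled
#' case-cohort data and forms bias-corrected percentile intervals. Under the
#' default design-respecting scheme each replicate resamples (a) subcohort
#' members and (b) cases outside the subcohort independently, with
#' replacement, preserving each stratum's size. Replicates on which the
#' estimator fails (e.g. a degenerate Cox fit) are dropped and counted; more
#' than 10% failures aborts with the failure mode named.
#'
#' @param sample a `case_cohort` sample.
#' @param estimator function taking a resampled `case_cohort` data frame and
#'   returning a numeric scalar or named vector (e.g. a cumulative curve); a
#'   `paf_result` return value is reduced to its `$paf`.
#' @param spec a [bootstrap_spec()].
#' @return Object of class `paf_boot`: `point`, `ci_low`, `ci_high` (vectors
#'   if the estimator is vector-valued), the replicate matrix, `n_failed`,
#'   the interval metadata and the spec.
#' @export
bootstrap_paf <- function(sample, estimator, spec = bootstrap_spec()) {
  stopifnot(inherits(spec, "bootstrap_spec"))
  if (spec$n_replicates < 100)
    warning("fewer than 100 bootstrap replicates: interval unstable",
            call. = FALSE)
  reduce <- function(v) if (inherits(v, "paf_result")) v$paf else
    if (inherits(v, "paf_curve")) setNames(v$paf, v$snp_id) else v
  point <- reduce(estimator(sample))  # must succeed on the original sample
  k <- length(point)

  idx_sub <- which(sample$in_subcohort)
  idx_out <- which(!sample$in_subcohort)
  n_rows <- nrow(sample)
  cols <- as.list(as.data.frame(sample))
  attrs <- attributes(sample)[c("panel", "subcohort_size", "source_size",
                                "sampling_fraction")]
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  cls <- class(sample)

  reps <- matrix(NA_real_, spec$n_replicates, k)
  colnames(reps) <- names(point)
  last_error <- NULL
  for (b in seq_len(spec$n_replicates)) {
    set.seed(derive_seed(spec$seed, paste0("boot:", b)))
    idx <- if (spec$resampling == "stratified_design") {
      c(idx_sub[sample.int(length(idx_sub), replace = TRUE)],
        if (length(idx_out))
          idx_out[sample.int(length(idx_out), replace = TRUE)])
    } else {
      sample.int(n_rows, replace = TRUE)
    }
    # column-wise subsetting: avoids data.frame row-name bookkeeping, which
    # would dominate the runtime at B = 10,000
    boot_df <- lapply(cols, `[`, idx)
    attr(boot_df, "row.names") <- c(NA_integer_, -length(idx))
    for (a in names(attrs)) attr(boot_df, a) <- attrs[[a]]
    class(boot_df) <- cls
    val <- tryCatch(reduce(estimator(boot_df)), error = function(e) {
      last_error <<- conditionMessage(e)
      NULL
    })
    if (!is.null(val) && length(val) == k) reps[b, ] <- as.numeric(val)
  }
  ok <- rowSums(is.na(reps)) == 0
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * spec$n_replicates)
    stop("bootstrap failed on ", n_failed, " of ", spec$n_replicates,
         " replicates; last failure: ", last_error, call. = FALSE)
  ints <- lapply(seq_len(k), function(j)
    bias_corrected_interval(reps[ok, j], point[j], spec$alpha))
  out <- list(point = point,
              ci_low = setNames(vapply(ints, `[[`, numeric(1), "low"),
                                names(point)),
              ci_high = setNames(vapply(ints, `[[`, numeric(1), "high"),
                                 names(point)),
              replicates = reps[ok, , drop = FALSE],
              n_failed = n_failed, intervals = ints, spec = spec)
  class(out) <- "paf_boot"
  out
}

#' @export
print.paf_boot <- function(x, ...) {
  cat("Bias-corrected bootstrap (B = ", nrow(x$replicates),
      if (x$n_failed) paste0(", ", x$n_failed, " failed"),
      ", alpha = ", x$spec$alpha, ", ", x$spec$resampling, ")\n", sep = "")
  tab <- data.frame(point = x$point, ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, 4))
  invisible(x)
}
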