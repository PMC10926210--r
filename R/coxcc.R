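#' Cox regression for case-cohort data with age as the time scale
#'
#' Fits a Cox proportional hazards model to a case-cohort sample by maximizing
#' the weighted partial likelihood on the age scale with delayed entry (left
#' truncation at the entry age). Under Prentice weighting, subcohort members
#' are at risk over `(entry_age, exit_age]` while cases outside the subcohort
#' enter the risk set only immediately before their own event age; the
#' `"unweighted"` option instead treats every retained row as at risk over its
#' full interval (a naive analysis, provided for sensitivity).
#'
#' Estimation is Newton-Raphson with step-halving on the log partial
#' likelihood (which is concave), declaring convergence when the gradient
#' max-norm drops below `tol`. A monotone likelihood (complete separation) is
#' flagged as non-convergence rather than reported as a finite estimate.
#' Standard errors are robust (score-residual sandwich, the infinitesimal
#' jackknife over individuals); the model-based inverse-information variance
#' is also retained for diagnostics.
#'
#' @param formula one-sided formula giving the linear predictor, e.g.
#'   `~ carrier + bmi`; terms are looked up in `data`. The survival outcome is
#'   taken from the fixed columns `entry_age`, `exit_age`, `event`.
#' @param data a `case_cohort` sample (see [sample_case_cohort()]) or any data
#'   frame with columns `entry_age`, `exit_age`, `event` and, for Prentice
#'   weighting, `in_subcohort` (absent means full cohort: all rows subcohort).
#' @param weighting `"prentice"` (default) or `"unweighted"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param robust compute sandwich standard errors (default `TRUE`).
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `coxcc`: coefficients, hazard ratios with 95%
#'   confidence intervals, robust and model-based variance matrices, the log
#'   partial likelihood, convergence diagnostics and counts.
#' @seealso [check_proportional_hazards()], [single_snp_paf()]
#' @export
#' @examples
#' panel <- snp_panel("rs1", "G1", "minor_allele_risk", 0.25, log(2), log(2))
#' ch <- simulate_cohort(cohort_config(n_individuals = 4000, panel = panel,
#'                                     seed = 7))
#' cc <- sample_case_cohort(ch, subcohort_size = 1000, seed = 7)
#' cc$carrier <- as.integer(cc$rs1 >= 1)
#' coxcc(~ carrier + bmi, cc)
coxcc <- function(formula, data, weighting = c("prentice", "unweighted"),
                  ties = c("breslow", "efron"), robust = TRUE,
                  tol = 1e-8, max_iter = 50L) {
  weighting <- match.arg(weighting)
  ties <- match.arg(ties)
  need <- c("entry_age", "exit_age", "event")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  mf <- model.frame(formula, data = data, na.action = stats::na.pass)
  X <- model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0) stop("formula specifies no covariates", call. = FALSE)

  in_sub <- if ("in_subcohort" %in% names(data)) as.logical(data$in_subcohort)
            else rep(TRUE, nrow(data))
  entry <- as.numeric(data$entry_age)
  exit <- as.numeric(data$exit_age)
  status <- as.integer(as.logical(data$event))

  fit <- coxcc_core(entry, exit, status, in_sub, X, weighting = weighting,
                    ties = ties, robust = robust, tol = tol,
                    max_iter = max_iter)
  fit$formula <- formula
  fit$call <- match.call()
  fit
}

# Internal fitting path taking plain vectors and a numeric design matrix;
# coxcc() and the PAF estimators (including bootstrap replicates, where
# formula processing would dominate the runtime) all funnel through here.
coxcc_core <- function(entry, exit, status, in_sub, X,
                       weighting = "prentice", ties = "breslow",
                       robust = TRUE, tol = 1e-8, max_iter = 50L) {
  ok <- complete.cases(X) & !is.na(entry) & !is.na(exit) & !is.na(status) &
    !is.na(in_sub)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    X <- X[ok, , drop = FALSE]
    entry <- entry[ok]; exit <- exit[ok]; status <- status[ok]
    in_sub <- in_sub[ok]
  }

  if (any(exit <= entry))
    stop("exit_age must exceed entry_age for all analyzed rows", call. = FALSE)
  if (sum(status) == 0) stop("no events in the analysis data", call. = FALSE)

  if (weighting == "prentice") {
    drop_rows <- !in_sub & status == 0L
    if (any(drop_rows)) {
      warning(sum(drop_rows),
              " non-case row(s) outside the subcohort dropped under Prentice weighting")
      keep <- !drop_rows
      X <- X[keep, , drop = FALSE]
      entry <- entry[keep]; exit <- exit[keep]
      status <- status[keep]; in_sub <- in_sub[keep]
    }
    # non-subcohort cases enter the risk set just before their own event
    shift <- !in_sub & status == 1L
    if (any(shift)) {
      eps <- 1e-9 * max(exit)
      entry[shift] <- exit[shift] - eps
    }
  }

  for (j in seq_len(ncol(X)))
    if (var(X[, j]) == 0)
      stop("covariate '", colnames(X)[j],
           "' is constant among analyzed individuals: flat likelihood",
           call. = FALSE)

  eng <- cox_fit_engine(entry, exit, status, X, ties = ties,
                        tol = tol, max_iter = max_iter)

  beta <- eng$coef
  vmod <- solve(eng$info)
  rvar <- NULL
  if (robust) {
    U <- cox_score_residuals(eng)
    rvar <- vmod %*% crossprod(U) %*% vmod
    dimnames(rvar) <- dimnames(vmod)
  }
  se <- sqrt(diag(if (robust) rvar else vmod))
  z <- qnorm(0.975)
  fit <- list(
    coefficients = beta,
    var = vmod, rvar = rvar,
    se = sqrt(diag(vmod)), robust_se = if (robust) se else NULL,
    hr = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    loglik = eng$loglik, n = length(status), n_events = sum(status),
    n_dropped = n_dropped, converged = eng$converged,
    n_iterations = eng$iter, ties = ties, weighting = weighting,
    formula = NULL, xcenter = eng$xcenter,
    engine = eng, call = NULL
  )
  class(fit) <- "coxcc"
  fit
}

# Internal Newton-Raphson maximizer of the delayed-entry Cox partial
# likelihood (the iteration itself runs in compiled code). Rows may arrive in
# any order; sorting by exit time is done here and the permutation retained so
# residuals can be mapped back. Covariates are centered for numerical range;
# coefficients are unaffected.
cox_fit_engine <- function(entry, exit, status, X, ties = "breslow",
                           tol = 1e-8, max_iter = 50L) {
  ord <- order(exit)
  entry_s <- entry[ord]; exit_s <- exit[ord]; status_s <- as.integer(status[ord])
  xcenter <- colMeans(X)
  Xs <- X[ord, , drop = FALSE]
  Xs <- Xs - rep(xcenter, each = nrow(Xs))
  efron <- identical(ties, "efron")

  res <- cox_fit_cpp(entry_s, exit_s, status_s, Xs, efron, tol,
                     as.integer(max_iter), 15)
  if (!res$converged) {
    warning("partial likelihood did not converge",
            if (res$monotone)
              " (possible monotone likelihood / complete separation)",
            call. = FALSE)
  }
  beta <- setNames(as.numeric(res$coef), colnames(X))
  info <- res$info
  dimnames(info) <- list(colnames(X), colnames(X))
  list(coef = beta, info = info, loglik = res$loglik, grad = res$grad,
       converged = res$converged, iter = res$iter, xcenter = xcenter,
       entry = entry_s, exit = exit_s, status = status_s, X = Xs,
       ord = ord, ties = ties)
}

# Per-event-time risk-set summaries at the fitted coefficients; computed on
# demand (residuals, sandwich variance, proportional-hazards test).
engine_detail <- function(eng) {
  cox_eval_cpp(eng$entry, eng$exit, eng$status, eng$X, unname(eng$coef),
               identical(eng$ties, "efron"), TRUE)
}

# Score residuals (one p-vector per analyzed row, original row order).
# Breslow-form baseline increments are used; identical to the Efron form when
# event times are untied.
cox_score_residuals <- function(eng) {
  d <- engine_detail(eng)
  K <- length(d$etime)
  p <- ncol(eng$X)
  dL <- d$nevent / d$S0
  A <- c(0, cumsum(dL))
  B <- rbind(rep(0, p), apply(dL * d$xbar, 2, cumsum))
  kstop <- findInterval(eng$exit, d$etime)
  kstart <- findInterval(eng$entry, d$etime)
  r <- exp(as.vector(eng$X %*% eng$coef))
  sumdL <- A[kstop + 1] - A[kstart + 1]
  U <- matrix(0, length(eng$exit), p)
  for (j in seq_len(p)) {
    sumdLx <- B[kstop + 1, j] - B[kstart + 1, j]
    xbar_at <- rep(0, length(eng$exit))
    ev <- eng$status == 1L
    xbar_at[ev] <- d$xbar[match(eng$exit[ev], d$etime), j]
    U[, j] <- eng$status * (eng$X[, j] - xbar_at) -
      r * (eng$X[, j] * sumdL - sumdLx)
  }
  U[order(eng$ord), , drop = FALSE]  # back to input row order
}

#' @export
coef.coxcc <- function(object, ...) object$coefficients

#' @export
vcov.coxcc <- function(object, ...) {
  if (!is.null(object$rvar)) object$rvar else object$var
}

#' @export
logLik.coxcc <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.coxcc <- function(object, parm, level = 0.95, ...) {
  se <- if (!is.null(object$robust_se)) object$robust_se else object$se
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.coxcc <- function(x, digits = 4, ...) {
  cat("Case-cohort Cox model (", x$weighting, " weighting, ", x$ties,
      " ties)\n", sep = "")
  cat("n =", x$n, " events =", x$n_events,
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " rows dropped, complete case)"),
      "\n")
  se <- if (!is.null(x$robust_se)) x$robust_se else x$se
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = x$hr, se = se,
                    lower95 = x$ci_low, upper95 = x$ci_high,
                    check.names = FALSE)
  print(round(tab, digits))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.coxcc <- function(object, ...) {
  se <- if (!is.null(object$robust_se)) object$robust_se else object$se
  z <- object$coefficients / se
  tab <- cbind(coef = object$coefficients, hr = object$hr, se = se,
               z = z, p = 2 * pnorm(-abs(z)),
               lower95 = object$ci_low, upper95 = object$ci_high)
  out <- list(coefficients = tab, n = object$n, n_events = object$n_events,
              loglik = object$loglik, converged = object$converged,
              weighting = object$weighting, ties = object$ties)
  class(out) <- "summary.coxcc"
  out
}

#' @export
print.summary.coxcc <- function(x, digits = 4, ...) {
  cat("Case-cohort Cox model (", x$weighting, " weighting, ", x$ties,
      " ties)\nn = ", x$n, ", events = ", x$n_events,
      ", log partial likelihood = ", format(x$loglik, digits = 7), "\n\n",
      sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.coxcc <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- model.matrix(object$formula,
                    model.frame(object$formula, newdata,
                                na.action = stats::na.pass))
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  lp <- as.vector(sweep(X, 2, object$xcenter) %*% object$coefficients)
  if (type == "lp") lp else exp(lp)
}

#' Residuals from a case-cohort Cox fit
#'
#' `"score"` residuals are one vector per analyzed row (the building block of
#' the sandwich variance); `"schoenfeld"` residuals are one vector per event
#' (covariate minus the risk-set mean at the event age); the
#' `"scaled_schoenfeld"` variant rescales them by the inverse average
#' information and adds the coefficient, as used by the proportional-hazards
#' test.
#'
#' @param object a `coxcc` fit.
#' @param type residual type.
#' @param ... unused.
#' @return A matrix (rows = individuals for `"score"`, events otherwise);
#'   Schoenfeld matrices carry the event ages as attribute `"time"`.
#' @export
residuals.coxcc <- function(object,
                            type = c("score", "schoenfeld",
                                     "scaled_schoenfeld"), ...) {
  type <- match.arg(type)
  eng <- object$engine
  if (type == "score") return(cox_score_residuals(eng))
  d <- engine_detail(eng)
  ev <- which(eng$status == 1L)
  times <- eng$exit[ev]
  k <- match(times, d$etime)
  S <- eng$X[ev, , drop = FALSE] - d$xbar[k, , drop = FALSE]
  colnames(S) <- names(object$coefficients)
  if (type == "scaled_schoenfeld") {
    dtot <- sum(eng$status)
    S <- dtot * S %*% solve(eng$info) +
      matrix(object$coefficients, nrow(S), ncol(S), byrow = TRUE)
    colnames(S) <- names(object$coefficients)
  }
  attr(S, "time") <- times
  S
}

#' Test the proportional hazards assumption via Schoenfeld residuals
#'
#' Scaled Schoenfeld residuals are regressed on the event age; a chi-square
#' score test (1 df per covariate) against a linear trend in age is reported,
#' following the standard scaled-residual construction. A small p-value
#' indicates that the covariate's hazard ratio drifts with age.
#'
#' @param fit a converged `coxcc` fit with at least 2 events.
#' @param transform transformation of event age used as the regressor
#'   (`"identity"` or `"rank"`).
#' @return Data frame with one row per covariate: `chisq`, `df`, `p`.
#' @export
check_proportional_hazards <- function(fit, transform = c("identity", "rank")) {
  stopifnot(inherits(fit, "coxcc"))
  transform <- match.arg(transform)
  if (fit$n_events < 2)
    stop("proportional hazards test requires at least 2 events", call. = FALSE)
  S <- residuals.coxcc(fit, type = "schoenfeld")
  g <- attr(S, "time")
  if (transform == "rank") g <- rank(g)
  gc <- g - mean(g)
  dtot <- fit$n_events
  vbar <- diag(fit$engine$info) / dtot  # average per-event covariance
  num <- as.vector(crossprod(gc, S))
  den <- vbar * sum(gc^2)
  chisq <- ifelse(den > 0, num^2 / den, 0)
  data.frame(covariate = names(fit$coefficients), chisq = chisq, df = 1,
             p = pchisq(chisq, 1, lower.tail = FALSE),
             row.names = NULL)
}
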