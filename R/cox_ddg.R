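## Univariate Cox machinery and the 1-D data-driven grouping (DDg).

#' Fit a Cox model with a single binary covariate
#'
#' Maximum partial-likelihood estimate of the log hazard ratio of the
#' group-1 (high-risk) side versus group 0, with Breslow handling of ties,
#' standard error from the observed information, and a Wald chi-square(1)
#' p-value.
#'
#' @param times Non-negative survival times (years).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Binary group membership (0/1); both groups must be
#'   non-empty and at least one event must be observed.
#' @return An object of class `cox_fit`: list(beta, se, wald_stat, p_value, n).
#' @export
fit_cox_binary <- function(times, events, group) {
  n <- length(times)
  if (length(events) != n || length(group) != n)
    stop("times, events and group must have equal length", call. = FALSE)
  group <- as.integer(group)
  if (!all(group %in% c(0L, 1L))) stop("group must be binary 0/1", call. = FALSE)
  if (sum(group) == 0L || sum(group) == n)
    stop("inadmissible partition: one group is empty", call. = FALSE)
  if (sum(events) < 1)
    stop("inadmissible partition: no events observed", call. = FALSE)
  fit <- coxph(Surv(times, events) ~ group, ties = "breslow")
  beta <- unname(fit$coefficients[1L])
  se <- unname(sqrt(fit$var[1L, 1L]))
  wald <- (beta / se)^2
  structure(list(beta = beta, se = se, wald_stat = wald,
                 p_value = pchisq(wald, df = 1, lower.tail = FALSE), n = n),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> beta = %.4f (se %.4f), Wald p = %.3g, n = %d\n",
              x$beta, x$se, x$p_value, x$n))
  invisible(x)
}

default_min_group <- function(n) max(5L, ceiling(0.10 * n))

#' 1-D data-driven grouping: survival-optimal expression cutoff
#'
#' Dichotomizes patients on a single gene by searching candidate cutoffs
#' (empirical quantiles of the expression row) and keeping the cutoff whose
#' binary Cox fit minimizes the Wald p-value.  Values equal to the cutoff
#' fall on the low side.  The high-risk side is the one with positive log
#' hazard ratio.  The reported p-value is the selection minimum,
#' unadjusted for the multiplicity of the cutoff grid; cross-cohort
#' reproducibility is the intended guard against selection optimism.
#'
#' @param times,events Survival outcome as in [fit_cox_binary()].
#' @param expr_row Numeric expression values, one per patient.
#' @param quantile_grid Candidate cutoff quantiles.
#' @param min_group Minimum size of each side; default `max(5, 10%% of n)`.
#' @return An object of class `ddg1d`: list(cutoff, quantile, direction,
#'   fit, p_value).
#' @export
ddg_1d <- function(times, events, expr_row,
                   quantile_grid = seq(0.10, 0.90, by = 0.05),
                   min_group = NULL) {
  n <- length(expr_row)
  if (length(times) != n || length(events) != n)
    stop("times, events and expr_row must have equal length", call. = FALSE)
  if (is.null(min_group)) min_group <- default_min_group(n)
  if (min_group < 5L) stop("min_group must be at least 5", call. = FALSE)
  cuts <- unname(quantile(expr_row, quantile_grid, type = 7))
  best <- NULL
  for (i in seq_along(cuts)) {
    grp <- as.integer(expr_row > cuts[i])
    n1 <- sum(grp)
    if (n1 < min_group || (n - n1) < min_group) next
    if (sum(events) < 1) next
    fit <- fit_cox_binary(times, events, grp)
    if (is.null(best) || fit$p_value < best$p_value) {
      best <- list(cutoff = cuts[i], quantile = quantile_grid[i],
                   direction = if (fit$beta > 0) "high_is_HR" else "low_is_HR",
                   fit = fit, p_value = fit$p_value)
    }
  }
  if (is.null(best))
    stop("no admissible cutoff (groups below min_group everywhere)", call. = FALSE)
  class(best) <- "ddg1d"
  best
}

#' @export
print.ddg1d <- function(x, ...) {
  cat(sprintf("<ddg1d> cutoff %.4f (q=%.2f), %s, Wald p = %.3g\n",
              x$cutoff, x$quantile, x$direction, x$p_value))
  invisible(x)
}
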