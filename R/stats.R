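#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Tests whether two score samples were drawn from the same distribution.
#' The statistic is the supremum of the absolute difference between the two
#' empirical CDFs; the p-value uses the asymptotic two-sided Kolmogorov
#' distribution with effective size n1*n2/(n1+n2).
#'
#' @param a,b numeric samples (each non-empty).
#' @return an object of class `"ks_result"`: `statistic`, `p_value`, `n1`,
#'   `n2`.
#' @export
ks_compare <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(kt$statistic),
                 p_value = min(max(unname(kt$p.value), .Machine$double.xmin), 1),
                 n1 = length(a), n2 = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Proportional-hazards association per 1 SD of a score
#'
#' Fits a univariate Cox model of conversion time on the covariate
#' standardized internally to unit SD, so the hazard ratio is per 1 SD unit
#' in score. Tied event times use the Breslow approximation. The result is
#' invariant to any positive rescaling of the covariate.
#'
#' @param covariate numeric score per subject (SD must be positive).
#' @param time event/censoring time (months, > 0).
#' @param event 1 = converted, 0 = censored; at least one event required.
#' @return an object of class `"cox_result"`: `coefficient` (log hazard per
#'   SD), `hazard_ratio`, `ci95_low`, `ci95_high`, `z_statistic`, `p_value`,
#'   `n`, `n_events`, `sd_used`.
#' @export
cox_per_sd <- function(covariate, time, event) {
  covariate <- as.numeric(covariate)
  stopifnot(length(covariate) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) stop("no events: proportional-hazards model is undefined")
  s <- sd(covariate)
  if (!is.finite(s) || s <= 0) stop("covariate has zero variance")
  z <- (covariate - mean(covariate)) / s
  fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "breslow")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    warning("monotone partial likelihood (perfect separation): estimates diverge",
            call. = FALSE)
  zstat <- beta / se
  structure(list(coefficient = beta, hazard_ratio = exp(beta),
                 ci95_low = exp(beta - 1.96 * se),
                 ci95_high = exp(beta + 1.96 * se),
                 z_statistic = zstat,
                 p_value = 2 * stats::pnorm(-abs(zstat)),
                 se = se, n = length(time), n_events = sum(event),
                 sd_used = s),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH per 1 SD: HR = %.3f (95%% CI %.3f, %.3f), z = %.3f, p = %.3g (%d events / %d subjects)\n",
              x$hazard_ratio, x$ci95_low, x$ci95_high, x$z_statistic,
              x$p_value, x$n_events, x$n))
  invisible(x)
}

#' Stratified medians with pairwise KS p-values
#'
#' Lays out per-metric, per-stratum medians and the KS p-value for each
#' pairwise stratum comparison — the table structure used for cognitive
#' status, age (< 75 vs >= 75) and functional status (FAQ <= 2 vs > 2)
#' contrasts. No multiple-testing adjustment is applied. Empty strata are
#' reported as missing rows, never dropped silently.
#'
#' @param scores named list of numeric vectors (one per metric), all of the
#'   same length n.
#' @param strata length-n factor or vector defining the partition.
#' @return data frame: metric, one median column per stratum, and one
#'   KS p-value column per stratum pair.
#' @export
stratified_table <- function(scores, strata) {
  stopifnot(is.list(scores), length(scores) >= 1)
  strata <- as.factor(strata)
  lev <- levels(strata)
  pairs <- if (length(lev) >= 2) utils::combn(lev, 2, simplify = FALSE) else list()
  rows <- lapply(names(scores), function(metric) {
    v <- scores[[metric]]
    stopifnot(length(v) == length(strata))
    med <- vapply(lev, function(l) {
      x <- v[strata == l]
      if (!length(x)) NA_real_ else median(x)
    }, 0)
    ps <- vapply(pairs, function(pr) {
      x1 <- v[strata == pr[1]]; x2 <- v[strata == pr[2]]
      if (!length(x1) || !length(x2)) NA_real_
      else ks_compare(x1, x2)$p_value
    }, 0)
    out <- data.frame(metric = metric, t(med))
    names(out)[-1] <- paste0("median_", lev)
    if (length(pairs)) {
      pm <- data.frame(t(ps))
      names(pm) <- vapply(pairs, function(pr)
        paste0("p_", pr[1], "_vs_", pr[2]), "")
      out <- cbind(out, pm)
    }
    out
  })
  do.call(rbind, rows)
}
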