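#' @include AllClasses.R
NULL

# median split with ties going to the low group
.medianSplit <- function(expression) {
  factor(ifelse(expression > median(expression), "high", "low"),
         levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test on a median expression split
#'
#' Splits subjects at the median expression (ties to the low group), fits
#' product-limit survival curves per group and computes the two-group
#' log-rank statistic.
#'
#' @param tab data.frame with \code{time}, \code{event} (0/1) and
#'   \code{expression}.
#' @return list with \code{fit} (a \code{survfit} object), \code{group}
#'   (the split), \code{chi2} and \code{p}. All-censored input yields
#'   \code{p = NA} with \code{degenerate = TRUE}.
#' @export
kmLogrank <- function(tab) {
  stopifnot(all(c("time", "event", "expression") %in% colnames(tab)))
  if (any(tab$time <= 0)) stop("survival times must be positive")
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1")
  grp <- .medianSplit(tab$expression)
  if (min(table(grp)) < 2)
    stop("median split left a group with fewer than 2 subjects")
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = tab)
  if (sum(tab$event) == 0) {
    return(list(fit = fit, group = grp, chi2 = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = tab)
  chi2 <- sd$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(fit = fit, group = grp, chi2 = chi2, p = p, degenerate = FALSE)
}

#' Cox proportional-hazards fit on the median split
#'
#' Fits a Cox model (Breslow tie handling) on the binary high/low covariate
#' and tests the proportional-hazards assumption with the scaled Schoenfeld
#' residual trend test; \code{ph_ok} is TRUE when that test's p-value
#' exceeds \code{phAlpha}.
#'
#' @param tab data.frame with \code{time}, \code{event}, \code{expression}.
#' @param phAlpha cut-off for the proportional-hazards test.
#' @return list with \code{log_hazard} (high vs low), \code{se}, \code{p},
#'   \code{ph_p}, \code{ph_ok}, \code{converged}.
#' @export
coxFit <- function(tab, phAlpha = 0.1) {
  stopifnot(all(c("time", "event", "expression") %in% colnames(tab)))
  grp <- .medianSplit(tab$expression)
  events <- table(grp[tab$event == 1])
  if (any(events == 0) || length(events) < 2) {
    warning("a group has no events; the partial likelihood is monotone")
    return(list(log_hazard = NA_real_, se = NA_real_, p = NA_real_,
                ph_p = NA_real_, ph_ok = NA, converged = FALSE))
  }
  d <- data.frame(time = tab$time, event = tab$event, grp = grp)
  fit <- survival::coxph(survival::Surv(time, event) ~ grp, data = d,
                         ties = "breslow")
  s <- summary(fit)
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  phP <- if (is.null(zph)) NA_real_ else zph$table["grp", "p"]
  list(
    log_hazard = unname(stats::coef(fit)),
    se = unname(s$coefficients[, "se(coef)"]),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    score_chi2 = unname(s$sctest["test"]),
    ph_p = phP,
    ph_ok = if (is.na(phP)) NA else phP > phAlpha,
    converged = TRUE
  )
}
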