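#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function with right censoring,
#' via [survival::survfit()].
#'
#' @param records Data frame with `time` (> 0) and `event` (0/1).
#' @return Data frame (`time`, `n_risk`, `n_event`, `n_censor`, `survival`),
#'   one row per distinct observed time; `survival` is nonincreasing from 1.
#' @export
km_curve <- function(records) {
  records <- validate_survival_records(records)
  if (nrow(records) == 0) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test on the pooled event times of two groups
#' (via [survival::survdiff()]); p-value from the chi-square distribution
#' with one degree of freedom. When there are no events at all the test is
#' vacuous and p = 1 is returned.
#'
#' @param records_a,records_b Survival record data frames (`time`, `event`).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
logrank_test <- function(records_a, records_b) {
  records_a <- validate_survival_records(records_a)
  records_b <- validate_survival_records(records_b)
  if (nrow(records_a) == 0 || nrow(records_b) == 0) stop("both groups must be nonempty")
  pooled <- data.frame(
    time = c(records_a$time, records_b$time),
    event = c(records_a$event, records_b$event),
    grp = rep(c("a", "b"), c(nrow(records_a), nrow(records_b)))
  )
  if (sum(pooled$event) == 0) {
    return(list(statistic = 0, df = 1L, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = pooled)
  list(statistic = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for predicted risk groups
#'
#' Partial-likelihood fit (Efron tie handling) of the event hazard on the
#' predicted risk group, optionally adjusted for covariates. Records with
#' missing covariate values are dropped and counted in the result. Monotone
#' likelihood (complete separation) and other non-convergence is flagged
#' rather than silently reported.
#'
#' @param records Data frame with `time`, `event`, `risk_group` and any
#'   covariate columns.
#' @param covariates Character vector of covariate column names to adjust for
#'   (default none: univariate fit on `risk_group`).
#' @return Object of class `reo_cox`: `table` (term, HR, 95% CI bounds, Wald
#'   p), `fit` (the underlying `coxph` object), `n`, `n_dropped`, `n_events`,
#'   `converged`, and `logrank_p` (score-test p of the fit).
#' @export
cox_fit <- function(records, covariates = NULL) {
  records <- validate_survival_records(records)
  if (is.null(records$risk_group)) stop("records need a 'risk_group' column")
  vars <- c("risk_group", covariates)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols) > 0) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "))
  }
  use <- stats::complete.cases(records[, c("time", "event", vars), drop = FALSE])
  n_dropped <- sum(!use)
  dat <- records[use, , drop = FALSE]
  if (length(unique(dat$risk_group)) < 2) stop("need at least two distinct risk groups")
  if (sum(dat$event) == 0) stop("no events in the data")
  if (setequal(unique(dat$risk_group), c("low_risk", "high_risk"))) {
    # report the hazard of the high-risk group relative to low risk
    dat$risk_group <- factor(dat$risk_group, levels = c("low_risk", "high_risk"))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(vars, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  coefs <- s$coefficients[, "coef"]
  ses <- s$coefficients[, "se(coef)"]
  if (any(is.na(coefs)) || any(!is.finite(ses)) || any(abs(coefs) > 15, na.rm = TRUE)) {
    converged <- FALSE
  }
  table <- data.frame(
    term = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = table, fit = fit, n = nrow(dat), n_dropped = n_dropped,
                 n_events = sum(dat$event), converged = converged,
                 logrank_p = unname(s$sctest["pvalue"])),
            class = "reo_cox")
}

#' @export
print.reo_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%d records, %d events%s)\n",
              x$n, x$n_events,
              if (x$n_dropped > 0) sprintf(", %d dropped for missing covariates", x$n_dropped)
              else ""))
  if (!x$converged) cat("  WARNING: fit did not converge (monotone likelihood?)\n")
  tab <- x$table
  tab$hr <- sprintf("%.2f", tab$hr)
  tab$ci <- sprintf("%.2f-%.2f", x$table$ci_lower, x$table$ci_upper)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab[, c("term", "hr", "ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.reo_cox <- function(object, ...) summary(object$fit, ...)

#' Schoenfeld residual test of proportional hazards
#'
#' Correlation test of the scaled Schoenfeld residuals against event-time
#' rank (via [survival::cox.zph()] with the rank transform). Requires a
#' converged fit with at least three events.
#'
#' @param fit A `reo_cox` object from [cox_fit()].
#' @return Data frame (`term`, `chisq`, `df`, `p_value`) including a
#'   `GLOBAL` row.
#' @export
schoenfeld_test <- function(fit) {
  stopifnot(inherits(fit, "reo_cox"))
  if (!fit$converged) stop("cannot test proportional hazards on a non-converged fit")
  if (fit$n_events < 3) stop("need at least three events for the Schoenfeld test")
  z <- survival::cox.zph(fit$fit, transform = "rank")
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p_value = z$table[, "p"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Administrative censoring at a follow-up horizon
#'
#' Restricts the analysis to the first `horizon` months of follow-up: records
#' with time beyond the horizon are censored at the horizon (the standard
#' reading of an "n-year" survival analysis).
#'
#' @param records Survival records.
#' @param horizon Horizon in the time unit of `records` (e.g. 60 months for a
#'   5-year analysis).
#' @return The records with `time` truncated and `event` zeroed beyond the
#'   horizon.
#' @export
censor_at_horizon <- function(records, horizon) {
  records <- validate_survival_records(records)
  if (horizon <= 0) stop("horizon must be positive")
  over <- records$time > horizon
  records$event[over] <- 0
  records$time[over] <- horizon
  records
}
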