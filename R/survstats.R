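#' Kaplan-Meier product-limit curve
#'
#' Thin wrapper over [survival::survfit()] returning the estimator as a
#' plain data frame (one row per distinct observed time) for programmatic
#' use. With no events the curve is flat at 1.
#'
#' @param times Positive follow-up times.
#' @param events 0 = censored, 1 = event.
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_curve <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param times Positive follow-up times.
#' @param events 0 = censored, 1 = event.
#' @param group Two-level grouping vector.
#' @return list with `chi2` (1-df statistic) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  check_surv(times, events)
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stop("log-rank test requires exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' @keywords internal
check_surv <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  invisible(NULL)
}

#' Cox proportional-hazards fit
#'
#' Wrapper over [survival::coxph()] with Efron handling of tied event
#' times. Rows with a missing value or the literal token `"unknown"` in any
#' covariate are removed casewise (with a message); covariates constant
#' after deletion are an error reported by name. Character/factor
#' covariates are modelled through the usual treatment contrasts.
#'
#' @param times Positive follow-up times.
#' @param events 0 = censored, 1 = event.
#' @param covariates data.frame of covariates, one row per observation.
#' @return list of class `reosig_cox` with elements `coefficients` (a
#'   data.frame: `term`, `coef`, `hr`, `se`, `p`, `ci_low`, `ci_high`),
#'   `n_used`, `events`, and the underlying `fit`.
#' @export
cox_fit <- function(times, events, covariates) {
  check_surv(times, events)
  if (!is.data.frame(covariates) || ncol(covariates) == 0L)
    stop("covariates must be a non-empty data.frame")
  if (nrow(covariates) != length(times))
    stop("covariates must have one row per observation")
  unknown <- Reduce(`|`, lapply(covariates, function(x)
    is.na(x) | (is.character(x) & x == "unknown")))
  if (any(unknown))
    message(sum(unknown),
            " observation(s) dropped casewise for unknown covariate values")
  keep <- !unknown
  times <- times[keep]; events <- events[keep]
  covariates <- covariates[keep, , drop = FALSE]
  if (sum(events) < 1L) stop("no events after casewise deletion")
  constant <- vapply(covariates, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[constant], collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  res <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    hr = co[, "exp(coef)"],
                    se = co[, "se(coef)"],
                    p = co[, "Pr(>|z|)"],
                    ci_low = ci[, "lower .95"],
                    ci_high = ci[, "upper .95"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = res, n_used = s$n, events = s$nevent,
                 fit = fit),
            class = "reosig_cox")
}

#' @export
print.reosig_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d\n", x$n_used, x$events))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over all usable pairs of observations -- those in which the shorter
#' observed time belongs to an event, and the two times differ -- the
#' C-index is the fraction in which the observation failing earlier carried
#' the higher predicted risk, with ties in the predictor counted as 1/2.
#' Risk may be any ordinal score, including a binary high(1)/low(0) label.
#'
#' @param risk Per-sample predicted risk (higher = worse prognosis).
#' @param times Positive follow-up times.
#' @param events 0 = censored, 1 = event.
#' @return Concordance estimate in `[0, 1]`.
#' @export
c_index <- function(risk, times, events) {
  check_surv(times, events)
  if (length(risk) != length(times)) stop("risk/times length mismatch")
  risk <- as.numeric(risk)
  n <- length(times)
  # pair (i, j) usable iff t_i < t_j and event_i == 1 (either order)
  dt <- outer(times, times, `<`)
  ev <- matrix(events == 1, n, n)
  usable <- dt & ev               # row index fails first
  dr <- outer(risk, risk, `-`)    # risk_i - risk_j
  conc <- sum(usable & dr > 0)
  ties <- sum(usable & dr == 0)
  n_usable <- sum(usable)
  if (n_usable == 0L) stop("no usable pairs for the C-index")
  (conc + 0.5 * ties) / n_usable
}

#' Compare survival between predicted risk groups
#'
#' Bundles the evaluation statistics reported for a two-group risk
#' classifier: the log-rank test, the hazard ratio (high vs low) with its
#' Wald 95% confidence interval from a univariate Cox model, and Harrell's
#' C-index of the binary risk label against the observed outcome.
#'
#' @param times Positive follow-up times.
#' @param events 0 = censored, 1 = event.
#' @param risk_group Character/factor vector with levels "high"/"low".
#' @return list with `n`, `n_high`, `n_low`, `events`, `logrank_chi2`,
#'   `logrank_p`, `hr`, `ci95` (length-2), `c_index`.
#' @export
compare_survival <- function(times, events, risk_group) {
  check_surv(times, events)
  if (!all(risk_group %in% c("high", "low")))
    stop("risk_group must contain only \"high\"/\"low\"")
  if (length(unique(risk_group)) != 2L)
    stop("both risk groups must be non-empty")
  lr <- logrank_test(times, events, risk_group)
  hi <- as.integer(risk_group == "high")
  cf <- cox_fit(times, events, data.frame(risk_high = hi))
  ci <- c_index(hi, times, events)
  list(n = length(times), n_high = sum(hi), n_low = sum(1L - hi),
       events = sum(events),
       logrank_chi2 = lr$chi2, logrank_p = lr$p,
       hr = cf$coefficients$hr[1L],
       ci95 = c(cf$coefficients$ci_low[1L], cf$coefficients$ci_high[1L]),
       c_index = ci)
}
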