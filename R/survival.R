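#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival-curve estimate. At each distinct event time t the
#' risk set contains every record with observed time >= t, so records
#' censored exactly at an event time count as at risk for that event (events
#' precede censorings at ties, the common convention). S(0) = 1 and the curve
#' steps down at event times only.
#'
#' @param time positive observation times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return object of class `km_fit`: data.frame with one row per distinct
#'   observed time and columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (survival probability just after `time`).
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("no survival records")
  if (any(!is.finite(time) | time <= 0)) stop("times must be finite and positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_fit", "data.frame"))
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to `tau`: a robust summary used to
#' decide which of two groups survives longer.
#'
#' @param fit a [km_curve()] result.
#' @param tau upper integration limit; defaults to the largest observed time.
#' @return restricted mean survival time.
#' @export
km_rmst <- function(fit, tau = max(fit$time)) {
  stopifnot(inherits(fit, "km_fit"))
  tt <- c(0, fit$time[fit$time <= tau], tau)
  ss <- c(1, fit$surv[fit$time <= tau])            # S is right-continuous
  sum(diff(tt) * ss)
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank test with 1 degree of freedom. At every
#' distinct event time across the pooled sample, the observed events in group
#' A are compared with their hypergeometric expectation given the risk sets;
#' the statistic is `(O_A - E_A)^2 / V` with `V` the summed hypergeometric
#' variance, and the p-value is the chi-square upper tail.
#'
#' @param time_a,event_a times and event indicators for group A.
#' @param time_b,event_b times and event indicators for group B.
#' @return list with `statistic`, `p_value`, `observed` and `expected`
#'   (length-2 vectors, groups A and B), and `n` (group sizes). With zero
#'   events overall the statistic is 0 and p = 1, with a warning.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0)
    stop("both groups must be nonempty")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  if (sum(event) == 0) {
    warning("no events in either group; log-rank statistic is 0")
    return(list(statistic = 0, p_value = 1,
                observed = c(0, 0), expected = c(0, 0),
                n = c(length(time_a), length(time_b))))
  }
  et <- sort(unique(time[event == 1]))
  o_a <- e_a <- v <- 0
  for (t in et) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    o_a <- o_a + d1
    e_a <- e_a + d * n1 / n_t
    if (n_t > 1)
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  o <- c(o_a, sum(event) - o_a)
  e <- c(e_a, sum(event) - e_a)
  stat <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o, expected = e,
       n = c(length(time_a), length(time_b)))
}

#' Read a clinical survival table
#'
#' Tab- or comma-delimited file with header columns `sample_id`, `time`,
#' `event`. Time units (days, months) are passed through unchanged.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  cl <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(cl)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(cl$time) | cl$time <= 0))
    stop("survival times must be finite and positive")
  if (!all(cl$event %in% c(0, 1))) stop("event must be 0 or 1")
  cl[, req]
}

.sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else ""
}
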