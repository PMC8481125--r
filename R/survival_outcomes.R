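# Retrospective outcome statistics: Kaplan-Meier estimates and medians,
# Mantel-Cox log-rank tests with log-rank-based hazard ratios, stratified
# layouts, and Fisher-exact response-rate comparisons.
#
# Hazard ratios use the Mantel-Haenszel/log-rank form (O_A/E_A)/(O_B/E_B)
# with a CI of exp(log HR +/- 1.96 * sqrt(1/E_A + 1/E_B)); Cox regression is
# deliberately not used, since the reported clinical HRs are log-rank HRs.

#' Kaplan-Meier estimate with the median survival time
#'
#' Product-limit estimator (ties decrement simultaneously). The median is
#' the smallest observed time at which the survival function is at or below
#' 0.5 (the earliest such time when S(t) sits exactly at 0.5 over an
#' interval), and `NA` when S never reaches 0.5.
#'
#' @param time Positive event/censoring times (months).
#' @param event 1 = event observed, 0 = censored.
#' @return An object of class `"km_fit"`: list with `time`, `surv`,
#'   `n_risk`, `n_event` (per distinct observed time), `median` and `n`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$median   # 2
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv <- fit$surv
  med <- if (any(surv <= 0.5 + 1e-12)) {
    min(fit$time[surv <= 0.5 + 1e-12])
  } else {
    NA_real_
  }
  structure(list(time = fit$time, surv = surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(time)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s\n", x$n,
              sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-sided Mantel-Cox log-rank test with hazard ratio
#'
#' Observed-vs-expected event counts over the pooled event times
#' (hypergeometric variance, ties allowed). The hazard ratio is reported
#' with the first factor level of `group` as the numerator arm.
#'
#' @param time Positive times for both arms.
#' @param event 0/1 event indicators.
#' @param group Two-level factor (or character) arm labels.
#' @return List with `chisq`, `p`, `hr`, `hr_ci` (95%), `obs`, `exp` (per
#'   arm), `groups` and `numerator`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, length(time) == length(event),
            length(time) == length(group))
  if (sum(event) == 0) {
    stop("no events observed in either group", call. = FALSE)
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- as.numeric(sd_fit$obs)
  expd <- as.numeric(sd_fit$exp)
  chisq <- as.numeric(sd_fit$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- (obs[1] / expd[1]) / (obs[2] / expd[2])
  se_log <- sqrt(1 / expd[1] + 1 / expd[2])
  ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  list(chisq = chisq, p = p, hr = hr, hr_ci = ci, obs = obs, exp = expd,
       groups = levels(group), numerator = levels(group)[1])
}

#' Stratified Kaplan-Meier medians and pairwise log-rank comparisons
#'
#' Reproduces the two retrospective layouts: group-vs-group within a drug
#' class (filter by TKI generation, stratify by group) and class-vs-class
#' within a group (filter by group, stratify by generation).
#'
#' @param records Data frame with columns `time_months`, `event`, and the
#'   stratifier column; typically also `group` and `tki_generation`.
#' @param stratifier Column name to stratify on. Records with `NA` in the
#'   stratifier fall into an explicit `"other"` stratum.
#' @param tki_generation Optional filter on the `tki_generation` column.
#' @param group Optional filter on the `group` column.
#' @return List with `strata` (per-stratum n, events, KM median) and
#'   `pairwise` (data frame of pairwise HRs with the first-listed stratum
#'   as numerator, 95% CI and log-rank p). Strata without events are
#'   reported but skipped in pairwise tests, with a warning.
#' @export
stratified_outcomes <- function(records, stratifier,
                                tki_generation = NULL, group = NULL) {
  stopifnot(is.data.frame(records),
            all(c("time_months", "event", stratifier) %in% names(records)))
  if (!is.null(tki_generation)) {
    records <- records[records$tki_generation %in% tki_generation, ]
  }
  if (!is.null(group)) records <- records[records$group %in% group, ]
  if (!nrow(records)) stop("no records after filtering", call. = FALSE)
  s <- as.character(records[[stratifier]])
  s[is.na(s)] <- "other"
  strata_names <- unique(s)
  strata <- do.call(rbind, lapply(strata_names, function(st) {
    idx <- s == st
    km <- km_estimate(records$time_months[idx], records$event[idx])
    data.frame(stratum = st, n = sum(idx),
               events = sum(records$event[idx]), median_months = km$median,
               stringsAsFactors = FALSE)
  }))
  with_events <- strata$stratum[strata$events > 0]
  if (length(with_events) < length(strata_names)) {
    warning(sprintf("stratum/strata without events skipped in pairwise tests: %s",
                    paste(setdiff(strata_names, with_events), collapse = ", ")))
  }
  pairwise <- NULL
  if (length(with_events) >= 2L) {
    pairs <- utils::combn(with_events, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      idx <- s %in% c(a, b)
      lr <- logrank_test(records$time_months[idx], records$event[idx],
                         factor(s[idx], levels = c(a, b)))
      data.frame(numerator = a, denominator = b, hr = lr$hr,
                 hr_lo = lr$hr_ci[1], hr_hi = lr$hr_ci[2],
                 chisq = lr$chisq, p = lr$p, stringsAsFactors = FALSE)
    }))
  }
  list(strata = strata, pairwise = pairwise)
}

#' Objective response rates with pairwise Fisher exact tests
#'
#' ORR = (complete + partial responses) / evaluable patients per group;
#' patients with best response `"NE"` (not evaluable) are excluded. Groups
#' with no evaluable patients are dropped with a warning. Pairwise
#' comparisons use the two-sided Fisher exact test (hypergeometric sum over
#' tables as extreme or more extreme than observed).
#'
#' @param responses Data frame with columns `group` and `best_response`
#'   (values among `"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`).
#' @param group_col Name of the grouping column (default `"group"`).
#' @return List with `orr` (per group: evaluable n, responders, ORR) and
#'   `pairwise` (group pair, two-sided Fisher p).
#' @export
orr_analysis <- function(responses, group_col = "group") {
  stopifnot(is.data.frame(responses),
            all(c(group_col, "best_response") %in% names(responses)))
  ok_levels <- c("CR", "PR", "SD", "PD", "NE")
  if (!all(responses$best_response %in% ok_levels)) {
    stop("best_response values must be among CR, PR, SD, PD, NE",
         call. = FALSE)
  }
  ev <- responses[responses$best_response != "NE", ]
  g <- as.character(ev[[group_col]])
  all_groups <- unique(as.character(responses[[group_col]]))
  empty <- setdiff(all_groups, unique(g))
  if (length(empty)) {
    warning(sprintf("group(s) with no evaluable patients excluded: %s",
                    paste(empty, collapse = ", ")))
  }
  if (length(unique(g)) < 2L) {
    stop("need at least 2 groups with evaluable patients", call. = FALSE)
  }
  orr <- do.call(rbind, lapply(unique(g), function(gr) {
    idx <- g == gr
    resp <- sum(ev$best_response[idx] %in% c("CR", "PR"))
    data.frame(group = gr, evaluable = sum(idx), responders = resp,
               orr = resp / sum(idx), stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(orr$group, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- orr[orr$group == pairs[1, k], ]
    b <- orr[orr$group == pairs[2, k], ]
    tab <- matrix(c(a$responders, a$evaluable - a$responders,
                    b$responders, b$evaluable - b$responders), nrow = 2)
    data.frame(group1 = a$group, group2 = b$group,
               p = stats::fisher.test(tab)$p.value, stringsAsFactors = FALSE)
  }))
  list(orr = orr, pairwise = pairwise)
}
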