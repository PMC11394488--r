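# Evaluation: classification metrics on the 0-100 scale, slide-to-patient
# aggregation, univariate Cox proportional-hazards risk stratification
# (Newton-Raphson on the Breslow partial likelihood), Kaplan-Meier tables,
# and the Pearson chi-squared association utility for cohort characteristics.

#' Classification metrics for one fold
#'
#' AUROC is the probability that a random RC score exceeds a random NRC score
#' (ties count one half); sensitivity is recall on RC, specificity recall on
#' NRC; all metrics are reported on the 0-100 scale.
#'
#' @param scores Predicted RC probabilities.
#' @param labels Character labels (RC/NRC).
#' @param threshold Classification threshold (default 0.5;
#'   `score >= threshold` calls RC).
#' @return Named list: `auroc`, `accuracy`, `specificity`, `sensitivity`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  assert_that(length(scores) == length(labels), "scores/labels length mismatch")
  pos <- scores[labels == "RC"]; neg <- scores[labels == "NRC"]
  assert_that(length(pos) > 0 && length(neg) > 0,
              "AUROC is undefined with a single class")
  # Mann-Whitney form: rank-sum of positives, ties averaged.
  rk <- rank(c(pos, neg))
  auroc <- (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  call_rc <- scores >= threshold
  list(
    auroc = 100 * auroc,
    accuracy = 100 * mean((labels == "RC") == call_rc),
    specificity = 100 * mean(!call_rc[labels == "NRC"]),
    sensitivity = 100 * mean(call_rc[labels == "RC"])
  )
}

#' Aggregate slide predictions to patients
#'
#' A patient's score is the maximum (default) or mean of their slides' RC
#' probabilities; the max rule scores a patient by their most suspicious
#' slide. The high-risk group is `score >= threshold`.
#'
#' @param predictions data.frame with `patient_id`, `p_rc` (and optionally
#'   `label`).
#' @param method `"max"` or `"mean"`.
#' @param threshold Group-assignment threshold (default 0.5).
#' @return data.frame: patient_id, score, group (high/low), label if present.
#' @export
aggregate_patient <- function(predictions, method = c("max", "mean"),
                              threshold = 0.5) {
  method <- match.arg(method)
  agg <- if (method == "max") max else mean
  ids <- sort(unique(predictions$patient_id))
  score <- vapply(ids, function(p) {
    agg(predictions$p_rc[predictions$patient_id == p])
  }, numeric(1))
  out <- data.frame(patient_id = ids, score = as.numeric(score),
                    group = ifelse(score >= threshold, "high", "low"),
                    stringsAsFactors = FALSE)
  if ("label" %in% names(predictions)) {
    out$label <- vapply(ids, function(p) {
      predictions$label[predictions$patient_id == p][1]
    }, character(1))
  }
  out
}

#' Univariate Cox proportional-hazards fit for risk stratification
#'
#' Maximizes the Breslow partial likelihood of a single binary covariate
#' (high- vs low-risk group) by Newton-Raphson to `|delta beta| < 1e-8`.
#' Times are administratively censored at `horizon` months before fitting,
#' matching the five-year framing. The 95% CI is the Wald interval
#' `exp(beta +/- 1.96 se)`.
#'
#' @param records data.frame with `time` (months), `event` (0/1), and `group`
#'   (`"high"`/`"low"`; high is the exposed level) — or `x` (0/1 numeric).
#' @param horizon Censoring horizon in months (default 60; `Inf` disables).
#' @return A `cox_result`: list with `beta`, `hr`, `se`, `ci_low`, `ci_high`,
#'   `p` (Wald), `n`, `n_events`, `converged`, `flag`.
#' @export
cox_univariate <- function(records, horizon = 60) {
  x <- if ("x" %in% names(records)) as.numeric(records$x)
       else as.numeric(records$group == "high")
  assert_that(all(x %in% c(0, 1)), "covariate must be binary")
  assert_that(length(unique(x)) == 2L, "one risk group is empty")
  time <- pmin(records$time, horizon)
  event <- as.integer(records$event & records$time <= horizon)
  assert_that(sum(event) >= 1, "no events in the cohort")

  fit <- cox_newton(time, event, x)
  hr <- exp(fit$beta)
  ci <- exp(fit$beta + c(-1, 1) * 1.96 * fit$se)
  p <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
  structure(
    list(beta = fit$beta, hr = hr, se = fit$se,
         ci_low = ci[1], ci_high = ci[2], p = p,
         n = length(x), n_events = sum(event),
         converged = fit$converged,
         flag = if (fit$converged) "ok" else "monotone_likelihood"),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox HR %.3f (95%% CI %.3f-%.3f, p = %.3g), %d events / %d subjects\n",
              x$hr, x$ci_low, x$ci_high, x$p, x$n_events, x$n))
  invisible(x)
}

# Newton-Raphson on the Breslow partial log-likelihood for one covariate.
# Risk sets are handled by sorting times decreasingly and accumulating
# cumulative sums; tied event times share one risk set (Breslow).
cox_newton <- function(time, event, x, tol = 1e-8, max_iter = 50) {
  ord <- order(-time, event)  # decreasing time; at equal times censored first
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  beta <- 0; converged <- FALSE
  for (it in seq_len(max_iter)) {
    ex <- exp(beta * x)
    s0 <- cumsum(ex)
    s1 <- cumsum(x * ex)
    # group indices by unique time so ties share the full risk set
    last_at_time <- cumsum(as.numeric(table(factor(time, levels = unique(time)))))
    risk_idx <- rep(last_at_time, diff(c(0, last_at_time)))
    U <- 0; I <- 0
    ev <- which(event == 1L)
    if (length(ev)) {
      S0 <- s0[risk_idx[ev]]; S1 <- s1[risk_idx[ev]]
      U <- sum(x[ev] - S1 / S0)
      I <- sum(S1 / S0 - (S1 / S0)^2)  # binary x: S2 = S1
    }
    if (I <= 1e-12) break
    step <- U / I
    if (abs(step) > 5) step <- sign(step) * 5  # damp runaway steps
    beta <- beta + step
    if (abs(step) < tol) { converged <- TRUE; break }
    if (abs(beta) > 15) break  # monotone likelihood
  }
  ex <- exp(beta * x)
  s0 <- cumsum(ex); s1 <- cumsum(x * ex)
  last_at_time <- cumsum(as.numeric(table(factor(time, levels = unique(time)))))
  risk_idx <- rep(last_at_time, diff(c(0, last_at_time)))
  ev <- which(event == 1L)
  S0 <- s0[risk_idx[ev]]; S1 <- s1[risk_idx[ev]]
  I <- sum(S1 / S0 - (S1 / S0)^2)
  list(beta = beta, se = 1 / sqrt(max(I, 1e-12)), converged = converged)
}

#' Kaplan-Meier product-limit table per risk group
#'
#' For each group, the estimate steps down at every event time by the factor
#' `(n_risk - n_event) / n_risk`; the curve starts at 1 and is non-increasing.
#'
#' @param records data.frame with `time`, `event`, `group`.
#' @param horizon Censoring horizon (default 60 months).
#' @return data.frame: group, time, n_risk, n_event, survival — including the
#'   time-0 row per group.
#' @export
km_table <- function(records, horizon = 60) {
  assert_that(nrow(records) >= 1, "empty group: no survival records")
  time <- pmin(records$time, horizon)
  event <- as.integer(records$event & records$time <= horizon)
  groups <- unique(records$group)
  out <- list()
  for (g in groups) {
    sel <- records$group == g
    assert_that(any(sel), "empty group %s", g)
    tg <- time[sel]; eg <- event[sel]
    ev_times <- sort(unique(tg[eg == 1L]))
    surv <- 1
    rows <- list(data.frame(group = g, time = 0, n_risk = sum(sel),
                            n_event = 0L, survival = 1))
    for (t in ev_times) {
      n_risk <- sum(tg >= t)
      n_event <- sum(tg == t & eg == 1L)
      surv <- surv * (n_risk - n_event) / n_risk
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, time = t, n_risk = n_risk, n_event = n_event,
        survival = surv
      )
    }
    out[[g]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-squared association test for an r x 2 contingency table
#'
#' No continuity correction; p-value from the chi-squared distribution with
#' `r - 1` degrees of freedom. This is the test used for categorical cohort
#' characteristics such as sex vs five-year recurrence.
#'
#' @param tab Non-negative integer matrix with r rows and 2 columns.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_assoc <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(ncol(tab) == 2L && nrow(tab) >= 2L, "table must be r x 2 with r >= 2")
  assert_that(all(tab >= 0) && all(tab == floor(tab)), "counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  assert_that(all(rs > 0) && all(cs > 0), "zero margin in contingency table")
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- nrow(tab) - 1L
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Build survival records from patient-level predictions and the cohort
#'
#' Joins predicted risk groups onto per-patient survival metadata.
#'
#' @param patient_preds Output of [aggregate_patient()].
#' @param cohort The slide-level cohort table.
#' @return data.frame: patient_id, time, event, group, label.
#' @export
survival_records <- function(patient_preds, cohort) {
  validate_cohort(cohort)
  per_pat <- unique(cohort[, c("patient_id", "label", "time_months", "event")])
  m <- merge(patient_preds, per_pat, by = "patient_id")
  data.frame(patient_id = m$patient_id, time = m$time_months,
             event = m$event, group = m$group,
             label = m$label.y %||% m$label,
             stringsAsFactors = FALSE)
}
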