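#' Kaplan-Meier product-limit curve
#'
#' Wraps `survival::survfit` (events precede censorings at tied times, the
#' product-limit convention) and returns the step function as a table.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame of class `KMCurve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(all(times > 0), all(events %in% c(0, 1)),
            length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Survival probability at a time point
#'
#' @param curve a `KMCurve`.
#' @param t time at which to evaluate S(t).
#' @return The product-limit estimate S(t).
#' @export
km_surv_at <- function(curve, t) {
  s <- c(1, curve$surv)
  idx <- findInterval(t, curve$time) + 1
  s[idx]
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square over the distinct event
#' times (delegates to `survival::survdiff`), df = number of groups - 1.
#'
#' @param groups group labels (>= 2 distinct values).
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return A list of class `LogRankResult`: `chi_square`, `df`, `p`.
#' @export
logrank <- function(groups, times, events) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("log-rank needs at least 2 groups")
  if (sum(events) < 1) stop("log-rank needs at least 1 event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  structure(list(chi_square = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p))
  invisible(x)
}

#' ROC AUC of a score against a survival outcome
#'
#' Builds a binary outcome from the clinical table — by default the raw
#' event indicator; with `horizon` set, death by the horizon, excluding
#' samples censored before it — then computes the AUC by the Mann-Whitney
#' rank formulation (tied scores count one half).
#'
#' @param score named numeric vector of per-sample scores.
#' @param clinical clinical data.frame with `sample_id`, `os_days`,
#'   `os_event`.
#' @param horizon optional time horizon in days.
#' @return A list of class `ROCResult`: `auc`, `mode`, `n_used`,
#'   `n_excluded`.
#' @export
score_auc <- function(score, clinical, horizon = NULL) {
  idx <- match(names(score), clinical$sample_id)
  if (any(is.na(idx))) stop("score names must all appear in clinical table")
  cl <- clinical[idx, , drop = FALSE]
  if (is.null(horizon)) {
    outcome <- cl$os_event
    used <- rep(TRUE, nrow(cl))
    mode <- "raw_event"
  } else {
    died_by <- cl$os_event == 1 & cl$os_days <= horizon
    survived_past <- cl$os_days > horizon
    used <- died_by | survived_past  # censored before horizon excluded
    outcome <- ifelse(died_by, 1, 0)[used]
    mode <- sprintf("horizon_%g", horizon)
  }
  s <- score[used]
  n_pos <- sum(outcome == 1); n_neg <- sum(outcome == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate outcome: need at least one positive and one negative")
  r <- rank(s)
  auc <- (sum(r[outcome == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, mode = mode, n_used = sum(used),
                 n_excluded = sum(!used)),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%s; %d used, %d excluded)\n",
              x$auc, x$mode, x$n_used, x$n_excluded))
  invisible(x)
}
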