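# Sensitivity/specificity of score > cutoff for event-by-horizon status,
# Kaplan-Meier method (Heagerty-Lumley-Pepe):
#   Se(c,t) = [1 - S(t | X > c)] P(X > c) / [1 - S(t)]
#   Sp(c,t) =      S(t | X <= c) P(X <= c) / S(t)
# with subgroup and overall survival estimated by KM and results clipped
# to [0, 1].
tdroc_point <- function(scores, times, events, horizon, cutoff) {
  st <- km_surv_at(times, events, horizon)
  hi <- scores > cutoff
  p_hi <- mean(hi)
  s_hi <- if (any(hi)) km_surv_at(times[hi], events[hi], horizon) else NA
  s_lo <- if (any(!hi)) km_surv_at(times[!hi], events[!hi], horizon) else NA
  se <- if (st >= 1) NA else (1 - s_hi) * p_hi / (1 - st)
  sp <- if (st <= 0) NA else s_lo * (1 - p_hi) / st
  c(sens = min(max(se, 0), 1), spec = min(max(sp, 0), 1))
}

#' Time-dependent ROC curve and AUC at a horizon
#'
#' Estimates, for every candidate cutoff of a continuous risk score, the
#' sensitivity and specificity for predicting death by `horizon` under
#' right censoring, using the Kaplan-Meier method (see details in the
#' methods vignette). When no censoring occurs before the horizon the
#' estimator reduces exactly to the empirical ROC of the score against
#' event-by-horizon status, and the AUC equals the Mann-Whitney statistic.
#' AUC is computed by the trapezoid rule over the (1 - Sp, Se) polyline
#' (sorted, with (0,0) and (1,1) appended); the raw per-cutoff estimates,
#' which can be locally non-monotone, are returned unaltered.
#'
#' @param scores numeric risk scores
#' @param times,events survival outcome
#' @param horizon prediction time in days (e.g. 365)
#' @return object of class `td_roc`: list with `horizon`, `table`
#'   (cutoff, sens, spec) and `auc`
#' @export
td_roc <- function(scores, times, events, horizon) {
  check_surv(times, events)
  if (any(!is.finite(scores))) stop_input("scores must be finite")
  if (length(scores) != length(times)) {
    stop_input("scores must match survival input")
  }
  if (!any(times <= horizon & events == 1)) {
    stop_input("no events observed before the horizon")
  }
  cuts <- sort(unique(scores))
  tab <- t(vapply(cuts, function(cc)
    tdroc_point(scores, times, events, horizon, cc), numeric(2)))
  tab <- data.frame(cutoff = cuts, sens = tab[, "sens"],
                    spec = tab[, "spec"])
  ok <- stats::complete.cases(tab)
  # snap away floating noise so ties sort correctly before integration
  fpr <- round(c(0, 1 - tab$spec[ok], 1), 10)
  tpr <- round(c(0, tab$sens[ok], 1), 10)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(horizon = horizon, table = tab, auc = auc),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at %g days: AUC = %.3f (%d cutoffs)\n",
              x$horizon, x$auc, nrow(x$table)))
  invisible(x)
}

#' AIC-based cutoff on the 1-year ROC curve
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' scores. For each candidate, a one-covariate Cox model on the
#' dichotomized score `I(score > c)` is fitted over the full follow-up and
#' its AIC (`2 - 2 logPL`) recorded; the `"aic"` method returns the
#' AIC-minimizing candidate (the default rule), the `"youden"` method
#' the candidate maximizing Se + Sp - 1 on the ROC at `horizon`. The
#' per-candidate table carries AIC, sensitivity, specificity and Youden
#' index at the horizon for all candidates.
#'
#' @param scores,times,events as in [td_roc()]
#' @param horizon ROC horizon in days (default 365)
#' @param method `"aic"` (default) or `"youden"`
#' @return list of class `cutoff_result`: `cutoff`, `method`, `table`
#' @export
aic_cutoff <- function(scores, times, events, horizon = 365,
                       method = c("aic", "youden")) {
  method <- match.arg(method)
  check_surv(times, events)
  u <- sort(unique(scores))
  if (length(u) < 2L) stop_input("need at least 2 distinct scores")
  cand <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  y <- survival::Surv(times, events)
  rows <- lapply(cand, function(cc) {
    g <- as.integer(scores > cc)
    if (all(g == 0L) || all(g == 1L)) return(NULL)
    # extreme candidates can separate the groups; only the AIC is used
    fit <- suppressWarnings(survival::coxph(y ~ g))
    ll <- fit$loglik[2]
    pt <- tdroc_point(scores, times, events, horizon, cc)
    data.frame(cutoff = cc, aic = 2 - 2 * ll,
               sens = pt["sens"], spec = pt["spec"],
               youden = pt["sens"] + pt["spec"] - 1)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L) {
    stop_input("all candidate cutoffs degenerate")
  }
  rownames(tab) <- NULL
  chosen <- if (method == "aic") tab$cutoff[which.min(tab$aic)] else
    tab$cutoff[which.max(tab$youden)]
  structure(list(cutoff = chosen, method = method, table = tab),
            class = "cutoff_result")
}

#' Assign high/low risk groups at a fixed cutoff
#'
#' Scores strictly above the cutoff are `high`, all others `low`. The
#' cutoff estimated on the training set is reused unchanged for the test
#' and entire sets.
#'
#' @param scores numeric scores
#' @param cutoff finite cutoff value
#' @return factor with levels `low`, `high`, named like `scores`
#' @export
assign_groups <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop_input("cutoff must be finite")
  stats::setNames(factor(ifelse(scores > cutoff, "high", "low"),
                         levels = c("low", "high")), names(scores))
}
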