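#' Kaplan-Meier product-limit curve
#'
#' Thin wrapper around [survival::survfit()] returning the step function as
#' a plain table (one row per observed time) with risk and event counts.
#'
#' @param times positive follow-up times (days)
#' @param events 0/1 event indicators
#' @return data.frame with columns `time, n_risk, n_event, n_censor, surv`
#' @export
km_curve <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

# KM survival probability at a single horizon, for an arbitrary subgroup.
# Used by the time-dependent ROC estimator.
km_surv_at <- function(times, events, horizon) {
  if (length(times) == 0L) return(NA_real_)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  idx <- which(fit$time <= horizon)
  if (length(idx) == 0L) return(1)
  fit$surv[max(idx)]
}

#' Log-rank test over two or more groups
#'
#' @param groups group labels (>= 2 non-empty groups)
#' @param times,events survival outcome
#' @return list with `statistic` (chi-square), `df` (groups - 1) and `p`
#' @export
logrank_test <- function(groups, times, events) {
  check_surv(times, events)
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop_input("log-rank requires at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization (Efron tie handling
#' by default) and returns coefficients with Wald inference plus the model
#' log partial likelihood and AIC = 2k - 2 logPL. Constant covariates are
#' rejected up front; non-convergence and infinite-coefficient warnings are
#' captured into the `converged`/`messages` fields rather than silently
#' returning numbers.
#'
#' @param x covariate matrix or data.frame (columns named)
#' @param times,events survival outcome
#' @param ties `"efron"` (default) or `"breslow"`
#' @param allow_constant keep constant covariates instead of erroring
#' @return object of class `survival_fit`: list with `table` (term, coef,
#'   se, hr, lower, upper, p), `loglik`, `aic`, `n`, `n_events`,
#'   `converged`, `messages`
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow"),
                    allow_constant = FALSE) {
  ties <- match.arg(ties)
  check_surv(times, events)
  x <- as.data.frame(x)
  if (nrow(x) != length(times)) stop_input("covariate rows must match times")
  num <- vapply(x, is.numeric, logical(1))
  cst <- vapply(x, function(v) length(unique(v[!is.na(v)])) < 2L, logical(1))
  if (any(cst) && !allow_constant) {
    stop_input("constant covariate: ", names(x)[cst][1])
  }
  dup <- duplicated(lapply(x, function(v) unname(v)))
  if (any(dup)) {
    stop_input("identical covariate entered twice: ", names(x)[dup][1])
  }
  orig <- names(x)
  names(x) <- make.names(orig, unique = TRUE)
  d <- cbind(x, .time = times, .event = events)
  msgs <- character()
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = d,
                    ties = ties),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  tab <- data.frame(
    term  = rownames(co),
    coef  = co[, "coef"],
    se    = co[, "se(coef)"],
    hr    = co[, "exp(coef)"],
    lower = ci[, 3],
    upper = ci[, 4],
    p     = co[, ncol(co)],
    row.names = NULL)
  # map syntactic names back to the caller's column names
  for (i in seq_along(orig)) {
    hit <- startsWith(tab$term, names(x)[i])
    tab$term[hit] <- paste0(orig[i], substring(tab$term[hit],
                                               nchar(names(x)[i]) + 1L))
  }
  k <- sum(!is.na(stats::coef(fit)))
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(table = tab, loglik = ll, aic = 2 * k - 2 * ll,
                 n = fit$n, n_events = fit$nevent,
                 converged = length(msgs) == 0L, messages = msgs,
                 model = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox fit: n=%d, events=%d, logPL=%.3f, AIC=%.3f%s\n",
              x$n, x$n_events, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$table, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#' @param p vector of p-values in \[0, 1\]
#' @return q-values (monotone step-up adjustment, capped at 1)
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation and rank tests
#'
#' Wrappers with the package's conventions: two-sided asymptotic p-values,
#' mid-rank tie handling, zero-variance inputs rejected for correlations.
#'
#' @param x,y numeric vectors
#' @return list with `estimate` and `p` (plus `statistic` where natural)
#' @name assoc_tests
NULL

#' @rdname assoc_tests
#' @export
pearson_test <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("zero variance input to pearson_test")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p = ct$p.value,
       statistic = unname(ct$statistic))
}

#' @rdname assoc_tests
#' @export
spearman_test <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("zero variance input to spearman_test")
  }
  exact <- length(x) <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  list(estimate = unname(ct$estimate), p = ct$p.value,
       statistic = unname(ct$statistic))
}

#' @rdname assoc_tests
#' @param a,b numeric samples from the two independent groups
#' @export
ranksum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_input("empty group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' @rdname assoc_tests
#' @param values numeric vector
#' @param g group labels for `values`
#' @export
kruskal_test <- function(values, g) {
  g <- factor(g)
  if (nlevels(droplevels(g)) < 2L) stop_input("kruskal_test needs >= 2 groups")
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' @rdname assoc_tests
#' @param tab contingency table (matrix of non-negative counts)
#' @param correct apply Yates continuity correction (default FALSE)
#' @export
chisq_test <- function(tab, correct = FALSE) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}
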