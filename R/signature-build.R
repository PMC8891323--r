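#' Split a cohort into training and test halves, stratified by event
#'
#' @param clinical clinical data.frame (`sample_id`, `os_event`)
#' @param ratio training fraction (default 0.5, the 1:1 split)
#' @param seed RNG seed; the split is deterministic given it
#' @param stratify stratify on the event indicator (default TRUE) so the
#'   event proportions of the halves differ by at most a few points
#' @return list with character vectors `train` and `test`
#' @export
split_cohort <- function(clinical, ratio = 0.5, seed = 1L,
                         stratify = TRUE) {
  if (nrow(clinical) < 20L) stop_input("need at least 20 samples to split")
  if (ratio <= 0 || ratio >= 1) stop_input("ratio must be in (0, 1)")
  strata <- if (stratify) clinical$os_event else rep(1L, nrow(clinical))
  train <- with_seed(seed, {
    unlist(lapply(split(clinical$sample_id, strata), function(ids) {
      sample(ids, round(ratio * length(ids)))
    }), use.names = FALSE)
  })
  list(train = sort(train),
       test = sort(setdiff(clinical$sample_id, train)))
}

#' Univariate Cox screen over pair features
#'
#' Fits one single-covariate Cox model per pair (training samples only)
#' and retains pairs with Wald p below the threshold. Pairs constant in
#' the training samples are skipped with a warning.
#'
#' @param pm pair matrix (pairs x samples), training columns
#' @param times,events survival outcome, aligned to `colnames(pm)`
#' @param p_threshold Wald p threshold (default 0.05)
#' @return list with `table` (pair, coef, hr, p for every tested pair),
#'   `candidates` (pair ids passing), `skipped` (constant pairs)
#' @export
univariate_screen <- function(pm, times, events, p_threshold = 0.05) {
  check_surv(times, events)
  if (ncol(pm) != length(times)) stop_input("pm columns must match times")
  f <- rowMeans(pm)
  const <- f == 0 | f == 1
  if (any(const)) {
    warning(sum(const), " constant pair(s) skipped in univariate screen",
            call. = FALSE)
  }
  keep <- rownames(pm)[!const]
  y <- survival::Surv(times, events)
  rows <- lapply(keep, function(pr) {
    v <- pm[pr, ]
    fit <- survival::coxph(y ~ v)
    s <- summary(fit)$coefficients
    data.frame(pair = pr, coef = s[1, "coef"], hr = s[1, "exp(coef)"],
               p = s[1, ncol(s)], stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(), coef = numeric(), hr = numeric(),
               p = numeric())
  rownames(tab) <- NULL
  list(table = tab, candidates = tab$pair[tab$p < p_threshold],
       skipped = rownames(pm)[const])
}

#' Lasso-Cox with seeded 10-fold cross-validation
#'
#' Penalized Cox partial likelihood over the candidate pairs; the penalty
#' is chosen at the CV-deviance-minimizing value (`lambda.min`;
#' `"lambda.1se"` selectable) with fold assignment fixed by `seed`.
#' An optional repeated-subsample mode (`repeats > 1`) reruns the CV fit
#' on `subsample_fraction` subsamples and keeps pairs selected in at least
#' `stability_fraction` of them.
#'
#' @param pm pair matrix restricted to training columns
#' @param candidates pair ids to offer the Lasso (>= 2)
#' @param times,events survival outcome
#' @param nfolds folds (default 10)
#' @param seed fold-assignment seed
#' @param rule `"lambda.min"` or `"lambda.1se"`
#' @param repeats,subsample_fraction,stability_fraction repeated-subsample
#'   stability selection (off by default)
#' @return list with `survivors`, `lambda`, `coef` (at the chosen
#'   penalty), `n_candidates`
#' @export
lasso_cox_cv <- function(pm, candidates, times, events, nfolds = 10,
                         seed = 1L, rule = c("lambda.min", "lambda.1se"),
                         repeats = 1L, subsample_fraction = 0.8,
                         stability_fraction = 0.5) {
  rule <- match.arg(rule)
  check_surv(times, events)
  if (length(candidates) < 2L) stop_input("need >= 2 candidate pairs")
  if (sum(events) < nfolds) stop_input("fewer events than folds")
  x <- t(pm[candidates, , drop = FALSE])
  y <- survival::Surv(times, events)
  one_fit <- function(x, y, sd) {
    foldid <- with_seed(sd, sample(rep(seq_len(nfolds),
                                       length.out = nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    b <- as.numeric(stats::coef(cv, s = rule))
    names(b) <- colnames(x)
    b
  }
  if (repeats <= 1L) {
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds),
                                         length.out = nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    lam <- if (rule == "lambda.min") cv$lambda.min else cv$lambda.1se
    b <- as.numeric(stats::coef(cv, s = rule))
    names(b) <- colnames(x)
    survivors <- names(b)[b != 0]
  } else {
    sel <- matrix(FALSE, repeats, ncol(x),
                  dimnames = list(NULL, colnames(x)))
    for (r in seq_len(repeats)) {
      idx <- with_seed(seed + r,
                       sample(nrow(x), round(subsample_fraction * nrow(x))))
      b_r <- one_fit(x[idx, , drop = FALSE], y[idx], seed + r)
      sel[r, ] <- b_r != 0
    }
    survivors <- colnames(x)[colMeans(sel) >= stability_fraction]
    b <- one_fit(x, y, seed)
    lam <- NA_real_
  }
  if (length(survivors) == 0L) {
    warning("Lasso selected no pairs at the CV-optimal penalty",
            call. = FALSE)
  }
  list(survivors = survivors, lambda = lam, coef = b,
       n_candidates = length(candidates))
}

#' Stepwise multivariate Cox over the Lasso survivors
#'
#' Bidirectional AIC-stepwise selection starting from the model containing
#' every survivor; the final multivariate coefficients define the pair
#' signature. Aliased (non-identifiable) covariates are dropped before
#' stepping, and the final AIC never exceeds the initial one.
#'
#' @param pm pair matrix restricted to training columns
#' @param survivors pair ids entering the full model
#' @param times,events survival outcome
#' @return object of class `pair_signature`: list with `pairs`, `beta`
#'   (named coefficients), `fit` (final [cox_fit()] table), `aic`,
#'   `trace` (selection counts and AICs), `train_ids`
#' @export
stepwise_cox <- function(pm, survivors, times, events) {
  check_surv(times, events)
  if (length(survivors) < 1L) stop_input("need at least one survivor pair")
  d <- as.data.frame(t(pm[survivors, , drop = FALSE]))
  syn <- make.names(survivors, unique = TRUE)
  names(d) <- syn
  d$.time <- times; d$.event <- events
  full <- survival::coxph(survival::Surv(.time, .event) ~ ., data = d)
  aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
  if (length(aliased)) {
    keep <- setdiff(syn, aliased)
    d <- d[, c(keep, ".time", ".event"), drop = FALSE]
    full <- survival::coxph(survival::Surv(.time, .event) ~ ., data = d)
    warning(length(aliased), " non-identifiable pair(s) dropped before ",
            "stepwise selection", call. = FALSE)
  }
  aic_full <- stats::AIC(full)
  fin <- if (length(stats::coef(full)) > 1L) {
    stats::step(full, direction = "both", trace = 0,
                scope = list(lower = ~1))
  } else full
  b <- stats::coef(fin)
  final_syn <- names(b)
  final_pairs <- survivors[match(final_syn, syn)]
  names(b) <- final_pairs
  ft <- cox_fit(d[, final_syn, drop = FALSE], times, events)
  ft$table$term <- final_pairs
  structure(list(pairs = final_pairs, beta = b, fit = ft,
                 aic = stats::AIC(fin),
                 trace = list(n_survivors = length(survivors),
                              n_final = length(final_pairs),
                              aic_initial = aic_full,
                              aic_final = stats::AIC(fin)),
                 train_ids = colnames(pm)),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("pair signature: %d pair(s), AIC %.2f\n",
              length(x$pairs), x$aic))
  print(data.frame(pair = x$pairs, beta = unname(x$beta)), digits = 4)
  invisible(x)
}

#' Risk score of each sample under a pair signature
#'
#' `score_s = sum_i beta_i * S_is` — the exact Cox linear predictor over
#' the signature pairs, with no centering.
#'
#' @param sig a [stepwise_cox()] signature
#' @param pm pair matrix containing every signature pair
#' @return named numeric vector of scores (one per column of `pm`)
#' @export
risk_scores <- function(sig, pm) {
  miss <- setdiff(sig$pairs, rownames(pm))
  if (length(miss)) stop_input("pair(s) missing from matrix: ", miss[1])
  as.numeric(crossprod(pm[sig$pairs, , drop = FALSE], sig$beta)) |>
    stats::setNames(colnames(pm))
}

#' Conventional expression-based lncRNA signature (comparison baseline)
#'
#' The field's standard construction: univariate Cox screen on
#' `log2(x + 1)` expression at `p_threshold` (default 0.001), stepwise
#' multivariate Cox over the survivors, risk = sum of expression times
#' coefficient, and a median split of the training risk into high/low
#' groups.
#'
#' @param expr an [expr_set()]
#' @param ids candidate genes (e.g. the IRlncRNA set)
#' @param times,events training survival outcome
#' @param train_ids training sample ids (columns of `expr`)
#' @param p_threshold univariate screen threshold (default 0.001)
#' @return list of class `expression_signature`: `genes`, `coef`, `cutoff`
#'   (median training risk), `train_risk`
#' @export
baseline_expression_signature <- function(expr, ids, times, events,
                                          train_ids,
                                          p_threshold = 0.001) {
  check_surv(times, events)
  x <- log2p1(expr$values[ids, train_ids, drop = FALSE])
  keep <- apply(x, 1, stats::sd) > 0
  x <- x[keep, , drop = FALSE]
  y <- survival::Surv(times, events)
  p <- vapply(rownames(x), function(g) {
    s <- summary(survival::coxph(y ~ x[g, ]))$coefficients
    s[1, ncol(s)]
  }, numeric(1))
  hits <- names(p)[p < p_threshold]
  if (length(hits) == 0L) {
    stop_input("no gene passes the univariate screen at p < ", p_threshold)
  }
  d <- as.data.frame(t(x[hits, , drop = FALSE]))
  syn <- make.names(hits, unique = TRUE)
  names(d) <- syn
  d$.time <- times; d$.event <- events
  full <- survival::coxph(survival::Surv(.time, .event) ~ ., data = d)
  fin <- if (length(hits) > 1L) {
    stats::step(full, direction = "both", trace = 0,
                scope = list(lower = ~1))
  } else full
  b <- stats::coef(fin)
  genes <- hits[match(names(b), syn)]
  names(b) <- genes
  risk <- as.numeric(crossprod(x[genes, , drop = FALSE], b))
  names(risk) <- train_ids
  structure(list(genes = genes, coef = b,
                 cutoff = stats::median(risk), train_risk = risk),
            class = "expression_signature")
}

#' Risk scores under an expression signature
#' @param sig an `expression_signature`
#' @param expr an [expr_set()]
#' @param sample_ids samples to score (default all)
#' @return named numeric vector
#' @export
expression_risk_scores <- function(sig, expr, sample_ids = NULL) {
  sample_ids <- sample_ids %||% colnames(expr$values)
  x <- log2p1(expr$values[sig$genes, sample_ids, drop = FALSE])
  stats::setNames(as.numeric(crossprod(x, sig$coef)), sample_ids)
}
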