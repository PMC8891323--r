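# Ordinal codings used whenever a categorical trait enters a Cox model or
# ROC comparison as a single numeric covariate.
encode_clinical <- function(clinical, var) {
  v <- clinical[[var]]
  switch(var,
    age = as.numeric(v),
    sex = as.numeric(factor(v)),
    grade = ifelse(v == "high", 2, 1),
    stage = match(v, c("I", "II", "III", "IV")),
    t_stage = as.numeric(sub("^T", "", v)),
    n_stage = as.numeric(sub("^N", "", v)) + 1,
    m_stage = as.numeric(sub("^M", "", v)) + 1,
    suppressWarnings(as.numeric(v)))
}

#' Cox models of survival on risk score and clinical covariates
#'
#' `mode = "uni"` fits each variable alone; `mode = "multi"` fits the risk
#' score jointly with all covariates — the independent-prognostic-factor
#' check. The risk score enters continuously; grade and stage are coded
#' ordinally; samples with missing covariates are dropped (complete-case)
#' and counted in the `n_dropped` attribute.
#'
#' @param scores named risk scores
#' @param clinical clinical data.frame (rows matched to `names(scores)`)
#' @param mode `"multi"` (default) or `"uni"`
#' @param covariates clinical variables to include
#' @return data.frame `(term, hr, lower, upper, p, mode)`
#' @export
clinical_cox <- function(scores, clinical,
                         mode = c("multi", "uni"),
                         covariates = c("age", "sex", "grade", "stage")) {
  mode <- match.arg(mode)
  cl <- clinical[match(names(scores), clinical$sample_id), ]
  d <- data.frame(risk_score = as.numeric(scores))
  for (v in covariates) d[[v]] <- encode_clinical(cl, v)
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  times <- cl$os_days[cc]; events <- cl$os_event[cc]
  fit_one <- function(cols) {
    ft <- cox_fit(d[, cols, drop = FALSE], times, events)
    ft$table[, c("term", "hr", "lower", "upper", "p")]
  }
  out <- if (mode == "multi") {
    fit_one(names(d))
  } else {
    do.call(rbind, lapply(names(d), function(v) fit_one(v)))
  }
  out$mode <- mode
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Chi-square association of risk group with clinicopathological traits
#'
#' One chi-square test (no continuity correction) of group x category per
#' trait; traits with a single observed category are skipped with a
#' warning, and the minimum expected cell count is reported so
#' small-expectation tables are visible.
#'
#' @param groups factor of high/low (or cluster) labels, named by sample
#' @param clinical clinical data.frame
#' @param traits categorical columns to test
#' @return data.frame `(trait, statistic, df, p, q, min_expected)`
#' @export
risk_group_associations <- function(groups, clinical,
                                    traits = c("sex", "grade", "stage",
                                               "t_stage", "n_stage",
                                               "m_stage")) {
  if (nlevels(droplevels(factor(groups))) < 2L) {
    stop_input("need at least 2 groups")
  }
  cl <- clinical[match(names(groups), clinical$sample_id), ]
  rows <- lapply(traits, function(tr) {
    v <- cl[[tr]]
    ok <- !is.na(v)
    tab <- table(droplevels(factor(groups[ok])), v[ok])
    if (ncol(tab) < 2L) {
      warning("trait ", tr, " has a single category; skipped",
              call. = FALSE)
      return(NULL)
    }
    ct <- chisq_test(tab)
    data.frame(trait = tr, statistic = ct$statistic, df = ct$df,
               p = ct$p, min_expected = min(ct$expected))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_input("no testable trait")
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("trait", "statistic", "df", "p", "q", "min_expected")]
}

#' Compare the risk score's ROC with clinical traits at one horizon
#'
#' Each clinical variable is coerced to a numeric risk proxy (ordinal
#' coding for stage/grade) and its time-dependent AUC computed on the same
#' samples and horizon as the risk score; constant or unencodable
#' variables are skipped.
#'
#' @param scores named risk scores
#' @param clinical clinical data.frame
#' @param horizon days (default 365)
#' @param variables clinical variables to compare
#' @return data.frame `(variable, auc, n)`
#' @export
roc_vs_clinical <- function(scores, clinical, horizon = 365,
                            variables = c("age", "sex", "grade",
                                          "stage")) {
  cl <- clinical[match(names(scores), clinical$sample_id), ]
  vals <- list(risk_score = as.numeric(scores))
  for (v in variables) vals[[v]] <- encode_clinical(cl, v)
  rows <- lapply(names(vals), function(v) {
    x <- vals[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) return(NULL)
    roc <- td_roc(x[ok], cl$os_days[ok], cl$os_event[ok], horizon)
    data.frame(variable = v, auc = roc$auc, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of immune infiltration with the risk score
#'
#' One correlation per (cell type, estimation method), computed on the
#' overlapping samples; combinations with fewer than `min_overlap` shared
#' samples are skipped. BH adjustment is applied within each method
#' family, and rows with `p < p_threshold` are flagged for the lollipop
#' display.
#'
#' @param scores named risk scores
#' @param infiltration data.frame from [read_infiltration()]
#' @param p_threshold flag threshold (default 0.05)
#' @param min_overlap minimum shared samples (default 10)
#' @return data.frame `(cell_type, method, rho, p, q, n, flagged)`
#' @export
infiltration_correlation <- function(scores, infiltration,
                                     p_threshold = 0.05,
                                     min_overlap = 10) {
  rows <- lapply(split(infiltration,
                       infiltration[, c("cell_type", "method")],
                       drop = TRUE), function(df) {
    common <- intersect(df$sample_id, names(scores))
    if (length(common) < min_overlap) return(NULL)
    sc <- df$score[match(common, df$sample_id)]
    if (stats::sd(sc) == 0) return(NULL)
    st <- spearman_test(scores[common], sc)
    data.frame(cell_type = df$cell_type[1], method = df$method[1],
               rho = st$estimate, p = st$p, n = length(common))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_input("no (cell type, method) with enough overlap")
  out <- do.call(rbind, lapply(split(out, out$method), function(d) {
    d$q <- bh_fdr(d$p); d
  }))
  out$flagged <- out$p < p_threshold
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of gene expression between risk groups
#'
#' Mann-Whitney test per gene (e.g. immune-checkpoint genes) between the
#' high and low groups; direction is the sign of the median difference
#' (high minus low). Genes absent from the matrix are skipped with a
#' warning.
#'
#' @param expr an [expr_set()]
#' @param genes gene ids to test
#' @param groups named high/low factor
#' @param p_threshold significance flag (default 0.05)
#' @return data.frame `(gene, statistic, p, q, direction, flagged)`
#' @export
group_expression_tests <- function(expr, genes, groups,
                                   p_threshold = 0.05) {
  absent <- setdiff(genes, rownames(expr$values))
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from matrix; skipped",
            call. = FALSE)
  }
  genes <- intersect(genes, rownames(expr$values))
  ids <- intersect(names(groups), colnames(expr$values))
  g <- droplevels(factor(groups[ids]))
  if (nlevels(g) != 2L) stop_input("need exactly 2 non-empty groups")
  hi <- ids[g == levels(g)[2]]; lo <- ids[g == levels(g)[1]]
  rows <- lapply(genes, function(gn) {
    a <- log2p1(expr$values[gn, hi]); b <- log2p1(expr$values[gn, lo])
    rt <- ranksum_test(a, b)
    data.frame(gene = gn, statistic = rt$statistic, p = rt$p,
               direction = sign(stats::median(a) - stats::median(b)))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$flagged <- out$p < p_threshold
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of predicted drug IC50 between risk groups
#'
#' One Mann-Whitney test per drug; `direction` is
#' `"sensitive_in_high"` when the high-risk group has the lower median
#' IC50, `"resistant_in_high"` otherwise.
#'
#' @param ic50 data.frame from [read_ic50()]
#' @param groups named high/low factor
#' @param p_threshold significance flag (default 0.05)
#' @return data.frame `(drug, statistic, p, q, direction, flagged)`
#' @export
group_ic50_tests <- function(ic50, groups, p_threshold = 0.05) {
  g <- droplevels(factor(groups))
  if (nlevels(g) != 2L) stop_input("need exactly 2 non-empty groups")
  hi <- names(groups)[g == "high"]; lo <- names(groups)[g == "low"]
  rows <- lapply(split(ic50, ic50$drug), function(df) {
    a <- df$ic50[df$sample_id %in% hi]
    b <- df$ic50[df$sample_id %in% lo]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    rt <- ranksum_test(a, b)
    data.frame(drug = df$drug[1], statistic = rt$statistic, p = rt$p,
               direction = ifelse(stats::median(a) < stats::median(b),
                                  "sensitive_in_high",
                                  "resistant_in_high"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_input("no drug with samples in both groups")
  out$q <- bh_fdr(out$p)
  out$flagged <- out$p < p_threshold
  rownames(out) <- NULL
  out
}
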