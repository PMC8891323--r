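#' Pipeline configuration with the study's default thresholds
#'
#' Collects every tunable threshold of the analysis with its default:
#' coexpression |r| > 0.4 at p < 0.001; differential expression
#' |log2FC| > 2 at FDR < 0.05; constancy filter bounds 0.2/0.8; 1:1
#' train/test split; univariate pair screen at p < 0.05; 10-fold
#' Lasso-Cox CV; ROC horizons 365/1095/1825 days with the AIC cutoff on
#' the 1-year curve; consensus clustering over k = 2..6 with k fixed to 3
#' in the replication profile. All stage seeds are derived from the
#' single `seed` by fixed small offsets so one integer replays the whole
#' run.
#'
#' @param seed master seed (mandatory for a reproducible run)
#' @param r_threshold,corr_p_threshold coexpression screen
#' @param lfc_threshold,fdr_threshold differential expression screen
#' @param pair_freq_low,pair_freq_high constancy filter bounds
#' @param split_ratio training fraction
#' @param univariate_p pair screen threshold
#' @param lasso_folds CV folds
#' @param horizons ROC horizons in days
#' @param cutoff_method `"aic"` or `"youden"`
#' @param k_range,consensus_reps,consensus_fraction consensus clustering
#' @param fixed_k number of clusters (NULL = data-driven delta-area
#'   selection; default 3, the replication profile)
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1L,
                       r_threshold = 0.4, corr_p_threshold = 0.001,
                       lfc_threshold = 2, fdr_threshold = 0.05,
                       pair_freq_low = 0.2, pair_freq_high = 0.8,
                       split_ratio = 0.5, univariate_p = 0.05,
                       lasso_folds = 10,
                       horizons = c(365, 1095, 1825),
                       cutoff_method = "aic",
                       k_range = 2:6, consensus_reps = 100,
                       consensus_fraction = 0.8, fixed_k = 3) {
  cfg <- as.list(environment())
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg$seed <- as.integer(seed)
  # fixed derivation of per-stage seeds from the master seed
  cfg$stage_seeds <- cfg$seed + c(split = 11L, lasso = 23L, cluster = 37L)
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pair-signature analysis on one cohort
#'
#' Executes, in order: gene classification, immune coexpression screen,
#' differential expression, pair encoding and constancy filtering,
#' stratified 1:1 split, univariate Cox screen, 10-fold CV Lasso-Cox,
#' AIC-stepwise multivariate Cox, risk scoring, AIC cutoff on the 1-year
#' training ROC, group assignment (training cutoff reused everywhere),
#' ROC/AUC at all horizons for training/test/entire sets, Kaplan-Meier
#' log-rank, clinical Cox and chi-square associations, immune and drug
#' association statistics (for the tables present), and consensus
#' subtyping on the final signature's pairs. If the Lasso selects nothing
#' the pipeline falls back to the top univariate pairs (logged in the
#' manifest).
#'
#' @param cohort an `lnc_cohort` (from [generate_cohort()] or
#'   [read_cohort()])
#' @param config a [run_config()]
#' @param out_dir optional directory; when given, every stage table is
#'   written as TSV
#' @return list of class `lnc_run` with stage outputs and a `manifest` of
#'   per-stage counts
#' @export
run_all <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  expr <- cohort$expr
  clinical <- cohort$clinical
  notes <- character()

  sets <- stage("classify_genes",
                classify_genes(cohort$annotation, cohort$immune_symbols))

  ir <- stage("coexpression_filter",
              coexpression_filter(expr, sets$lncrna, sets$immune,
                                  r_threshold = cfg$r_threshold,
                                  p_threshold = cfg$corr_p_threshold))

  de <- stage("differential_expression",
              differential_expression(expr, ir$lncrna,
                                      lfc_threshold = cfg$lfc_threshold,
                                      fdr_threshold = cfg$fdr_threshold))
  deir <- de$gene[de$direction != "ns"]
  if (length(deir) < 2L) {
    stop("pipeline stage 'differential_expression' failed: fewer than 2 ",
         "DEIRlncRNAs", call. = FALSE)
  }

  pm_all <- stage("encode_pairs", encode_pairs(expr, deir))
  pm <- stage("filter_pairs",
              filter_pairs(pm_all, cfg$pair_freq_low, cfg$pair_freq_high))

  # clinical rows are restricted to samples present in the pair matrix
  clinical <- clinical[clinical$sample_id %in% colnames(pm), ]
  split <- stage("split_cohort",
                 split_cohort(clinical, ratio = cfg$split_ratio,
                              seed = cfg$stage_seeds[["split"]]))
  surv_of <- function(ids) {
    cl <- clinical[match(ids, clinical$sample_id), ]
    list(times = cl$os_days, events = cl$os_event)
  }
  tr <- surv_of(split$train)
  pm_tr <- pm[, split$train, drop = FALSE]

  uni <- stage("univariate_screen",
               univariate_screen(pm_tr, tr$times, tr$events,
                                 p_threshold = cfg$univariate_p))
  if (length(uni$candidates) == 0L) {
    stop("pipeline stage 'univariate_screen' failed: no prognostic pair",
         call. = FALSE)
  }

  if (length(uni$candidates) >= 2L) {
    las <- stage("lasso_cox_cv",
                 lasso_cox_cv(pm_tr, uni$candidates, tr$times, tr$events,
                              nfolds = cfg$lasso_folds,
                              seed = cfg$stage_seeds[["lasso"]]))
    survivors <- las$survivors
    if (length(survivors) == 0L) {
      ut <- uni$table[uni$table$pair %in% uni$candidates, ]
      survivors <- ut$pair[order(ut$p)][seq_len(min(10L, nrow(ut)))]
      notes <- c(notes, "lasso_empty_fallback_to_top_univariate")
    }
  } else {
    las <- list(survivors = uni$candidates, lambda = NA_real_)
    survivors <- uni$candidates
    notes <- c(notes, "single_candidate_lasso_skipped")
  }

  sig <- stage("stepwise_cox",
               stepwise_cox(pm_tr, survivors, tr$times, tr$events))

  scores <- stage("risk_scores", risk_scores(sig, pm))
  sc_tr <- scores[split$train]
  cut <- stage("aic_cutoff",
               aic_cutoff(sc_tr, tr$times, tr$events,
                          horizon = cfg$horizons[1],
                          method = cfg$cutoff_method))
  groups <- assign_groups(scores, cut$cutoff)

  set_ids <- list(train = split$train, test = split$test,
                  entire = clinical$sample_id)
  auc <- do.call(rbind, lapply(names(set_ids), function(nm) {
    ids <- set_ids[[nm]]
    sv <- surv_of(ids)
    do.call(rbind, lapply(cfg$horizons, function(h) {
      roc <- tryCatch(td_roc(scores[ids], sv$times, sv$events, h),
                      error = function(e) NULL)
      data.frame(set = nm, horizon = h,
                 auc = if (is.null(roc)) NA_real_ else roc$auc)
    }))
  }))

  km <- lapply(set_ids, function(ids) {
    sv <- surv_of(ids)
    g <- droplevels(groups[ids])
    if (nlevels(g) < 2L) return(NULL)
    logrank_test(g, sv$times, sv$events)
  })

  hazard_multi <- stage("clinical_cox",
                        clinical_cox(scores[set_ids$entire], clinical,
                                     mode = "multi"))
  hazard_uni <- clinical_cox(scores[set_ids$entire], clinical,
                             mode = "uni")
  assoc_clinical <- stage("risk_group_associations",
                          risk_group_associations(groups[set_ids$entire],
                                                  clinical))
  roc_clinical <- stage("roc_vs_clinical",
                        roc_vs_clinical(scores[set_ids$entire], clinical,
                                        horizon = cfg$horizons[1]))

  lollipop <- NULL
  if (!is.null(cohort$infiltration) && nrow(cohort$infiltration)) {
    lollipop <- stage("infiltration_correlation",
                      infiltration_correlation(scores[set_ids$entire],
                                               cohort$infiltration))
  } else notes <- c(notes, "infiltration_table_absent")

  ici_tab <- NULL
  ici_genes <- cohort$truth$ici_genes %||% NULL
  if (!is.null(ici_genes)) {
    ici_tab <- stage("group_expression_tests",
                     group_expression_tests(expr, ici_genes,
                                            groups[set_ids$entire]))
  }

  drug_tab <- NULL
  if (!is.null(cohort$ic50) && nrow(cohort$ic50)) {
    drug_tab <- stage("group_ic50_tests",
                      group_ic50_tests(cohort$ic50,
                                       groups[set_ids$entire]))
  } else notes <- c(notes, "ic50_table_absent")

  clust <- NULL; clust_cmp <- NULL; pca <- NULL
  if (length(sig$pairs) >= 2L) {
    clust <- stage("consensus_cluster",
                   consensus_cluster(pm[sig$pairs, , drop = FALSE],
                                     k_range = cfg$k_range,
                                     reps = cfg$consensus_reps,
                                     item_fraction = cfg$consensus_fraction,
                                     seed = cfg$stage_seeds[["cluster"]],
                                     k = cfg$fixed_k))
    pca <- pca_embed(pm[sig$pairs, , drop = FALSE], clust$labels)
    clust_cmp <- stage("cluster_comparisons",
                       cluster_comparisons(clust$labels, clinical,
                                           estimate = cohort$estimate,
                                           expr = expr,
                                           ici_genes = ici_genes))
  } else notes <- c(notes, "too_few_signature_pairs_for_clustering")

  manifest <- list(
    n_lncrna = length(sets$lncrna), n_immune = length(sets$immune),
    n_irlncrna = nrow(ir), n_de = sum(de$direction != "ns"),
    n_de_up = sum(de$direction == "up"),
    n_de_down = sum(de$direction == "down"),
    n_pairs_total = nrow(pm_all), n_pairs_filtered = nrow(pm),
    n_train = length(split$train), n_test = length(split$test),
    k1_univariate = length(uni$candidates),
    k2_lasso = length(survivors), k_final = length(sig$pairs),
    cutoff = cut$cutoff, seed = cfg$seed, notes = notes)

  run <- structure(list(
    gene_sets = sets, irlncrna = ir, de = de, deir = deir,
    pair_matrix = pm, split = split, univariate = uni, lasso = las,
    signature = sig, scores = scores, cutoff = cut, groups = groups,
    auc = auc, km = km, hazard_uni = hazard_uni,
    hazard_multi = hazard_multi, assoc_clinical = assoc_clinical,
    roc_clinical = roc_clinical, lollipop = lollipop, ici = ici_tab,
    drugs = drug_tab, clusters = clust, cluster_comparisons = clust_cmp,
    pca = pca, manifest = manifest, config = cfg), class = "lnc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.lnc_run <- function(x, ...) {
  m <- x$manifest
  cat("pair-signature run\n")
  cat(sprintf("  IRlncRNAs %d | DE %d (%d up / %d down) | pairs %d -> %d\n",
              m$n_irlncrna, m$n_de, m$n_de_up, m$n_de_down,
              m$n_pairs_total, m$n_pairs_filtered))
  cat(sprintf("  selection: %d univariate -> %d lasso -> %d final\n",
              m$k1_univariate, m$k2_lasso, m$k_final))
  cat(sprintf("  cutoff %.4f (%s); 1-year training AUC %.3f\n",
              m$cutoff, x$cutoff$method,
              x$auc$auc[x$auc$set == "train" &
                          x$auc$horizon == x$config$horizons[1]]))
  invisible(x)
}

#' Write every stage table of a run as TSV files
#' @param run an `lnc_run`
#' @param dir output directory
#' @return invisibly, the files written
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  files <- c(
    wt(run$irlncrna, "irlncrna.tsv"),
    wt(run$de, "de_irlncrna.tsv"),
    wt(attr(run$pair_matrix, "freq_table"), "pair_freq.tsv"),
    wt(data.frame(pair = rownames(run$pair_matrix), run$pair_matrix,
                  check.names = FALSE), "pairs.tsv"),
    wt(data.frame(pair = run$signature$pairs,
                  beta = unname(run$signature$beta)), "signature.tsv"),
    wt(data.frame(sample_id = names(run$scores),
                  score = unname(run$scores),
                  group = as.character(run$groups[names(run$scores)]),
                  set = ifelse(names(run$scores) %in% run$split$train,
                               "train", "test")), "risk_scores.tsv"),
    wt(run$cutoff$table, "cutoff.tsv"),
    wt(run$auc, "auc.tsv"),
    wt(run$hazard_uni, "hazard_uni.tsv"),
    wt(run$hazard_multi, "hazard_multi.tsv"),
    wt(run$assoc_clinical, "assoc_clinical.tsv"),
    wt(run$roc_clinical, "roc_clinical.tsv"))
  if (!is.null(run$lollipop)) files <- c(files, wt(run$lollipop,
                                                   "lollipop.tsv"))
  if (!is.null(run$ici)) files <- c(files, wt(run$ici, "ici_genes.tsv"))
  if (!is.null(run$drugs)) files <- c(files, wt(run$drugs,
                                                "drug_ic50.tsv"))
  if (!is.null(run$clusters)) {
    files <- c(files, wt(data.frame(
      sample_id = names(run$clusters$labels),
      cluster = unname(run$clusters$labels)), "clusters.tsv"))
  }
  man <- run$manifest
  man$notes <- paste(man$notes, collapse = ";")
  files <- c(files, wt(data.frame(key = names(man),
                                  value = vapply(man, function(v)
                                    paste(format(v), collapse = ","),
                                    character(1))), "manifest.tsv"))
  invisible(files)
}
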