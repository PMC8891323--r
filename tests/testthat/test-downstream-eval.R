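# Most downstream checks reuse the cached strong-signal pipeline runs.

test_that("the risk score is an independent prognostic factor", {
  hits <- vapply(recovery_runs(), function(rr) {
    tab <- rr$run$hazard_multi
    row <- tab[tab$term == "risk_score", ]
    row$hr > 1 && row$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("null covariates keep hazard ratios near one", {
  set.seed(70)
  n <- 400
  score <- rnorm(n)
  tt <- rexp(n, 1e-3 * exp(score))
  cc <- runif(n, 0, 3500)
  clin <- data.frame(sample_id = sprintf("P%03d", 1:n),
                     os_days = pmax(1, ceiling(pmin(tt, cc))),
                     os_event = as.integer(tt <= cc),
                     age = round(rnorm(n, 65, 8)),
                     sex = sample(c("male", "female"), n, TRUE),
                     grade = sample(c("low", "high"), n, TRUE),
                     stage = sample(c("I", "II", "III", "IV"), n, TRUE))
  tab <- clinical_cox(setNames(score, clin$sample_id), clin)
  noise <- tab[tab$term != "risk_score", ]
  expect_true(all(noise$lower < 1 & noise$upper > 1 | noise$p > 0.01))
  expect_lt(tab$p[tab$term == "risk_score"], 1e-6)
})

test_that("risk groups associate with the planted stage structure", {
  ps <- vapply(recovery_runs(), function(rr) {
    run <- rr$run
    assoc <- run$assoc_clinical
    assoc$p[assoc$trait == "stage"]
  }, numeric(1))
  expect_gte(sum(ps < 0.05), 4)
})

test_that("single-category traits are skipped with a warning", {
  cl <- data.frame(sample_id = paste0("s", 1:40),
                   os_days = 100 + 1:40, os_event = rep(0:1, 20),
                   sex = rep("male", 40),
                   grade = rep(c("low", "high"), 20))
  g <- setNames(factor(rep(c("low", "high"), each = 20),
                       levels = c("low", "high")), cl$sample_id)
  expect_warning(out <- risk_group_associations(g, cl,
                                                traits = c("sex", "grade")),
                 "single category")
  expect_equal(out$trait, "grade")
})

test_that("ROC comparison ranks the true score above noise traits", {
  rr <- recovery_runs()[[1]]
  run <- rr$run
  ids <- run$split$train
  tab <- roc_vs_clinical(run$scores[ids], rr$cohort$clinical)
  expect_equal(tab$variable[which.max(tab$auc)], "risk_score")
  # a duplicate of the score gets the identical AUC
  cl2 <- rr$cohort$clinical
  cl2$dup <- run$scores[match(cl2$sample_id, names(run$scores))]
  tab2 <- roc_vs_clinical(run$scores[ids], cl2,
                          variables = c("age", "dup"))
  expect_equal(tab2$auc[tab2$variable == "dup"],
               tab2$auc[tab2$variable == "risk_score"])
  # constant variables are skipped
  cl2$flat <- 1
  tab3 <- roc_vs_clinical(run$scores[ids], cl2, variables = "flat")
  expect_false("flat" %in% tab3$variable)
})

test_that("planted infiltration associations are detected, nulls are not", {
  rr <- recovery_runs()[[1]]
  run <- rr$run
  lol <- run$lollipop
  truth <- rr$cohort$truth$infiltration_assoc
  planted <- names(truth)[truth >= 0.5]
  nulls <- names(truth)[truth == 0]
  agg <- aggregate(flagged ~ cell_type, lol, all)
  expect_true(all(agg$flagged[agg$cell_type %in% planted]))
  expect_true(all(lol$rho[lol$cell_type %in% planted] > 0))
  expect_lte(mean(lol$flagged[lol$cell_type %in% nulls]), 0.35)
  # a method with a single overlapping sample is skipped
  tiny <- data.frame(sample_id = "TUM0001", cell_type = "B_cell",
                     method = "ONLYONE", score = 1)
  lol2 <- infiltration_correlation(run$scores,
                                   rbind(rr$cohort$infiltration, tiny))
  expect_false("ONLYONE" %in% lol2$method)
})

test_that("checkpoint genes and drugs separate by risk group as planted", {
  rr <- recovery_runs()[[1]]
  run <- rr$run
  expect_true(mean(run$ici$flagged) > 0.5)
  expect_true(all(run$ici$direction[run$ici$flagged] > 0))
  truth <- rr$cohort$truth$drug_assoc
  sens <- names(truth)[truth < 0]
  nulls <- names(truth)[truth == 0]
  dr <- run$drugs
  hit <- dr$flagged & dr$direction == "sensitive_in_high"
  expect_gte(mean(hit[dr$drug %in% sens]), 0.8)
  expect_lte(mean(dr$flagged[dr$drug %in% nulls]), 0.3)
  # a gene absent from the matrix is skipped with a warning
  expect_warning(
    out <- group_expression_tests(rr$cohort$expr, c("NOPE", "IMM0001"),
                                  run$groups),
    "absent")
  expect_equal(out$gene, "IMM0001")
})
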