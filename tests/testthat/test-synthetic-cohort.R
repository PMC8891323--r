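test_that("identical config and seed give identical cohorts", {
  cfg <- cohort_config(n_tumour = 40, n_normal = 8, n_lncrna = 12,
                       n_immune_genes = 10, n_other_genes = 5,
                       n_coexpressed_lnc = 6, n_de_lnc_up = 4,
                       n_de_lnc_down = 2, planted_betas = c(0.8, -0.8),
                       seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$infiltration, b$infiltration)
  expect_identical(a$truth$true_risk, b$truth$true_risk)
  # and the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_cohort(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n_lncrna = 10, n_coexpressed_lnc = 5,
                             n_immune_genes = 10, n_de_lnc_up = 8,
                             n_de_lnc_down = 5), "more DE")
  expect_error(cohort_config(censoring_fraction_target = 1), "censoring")
  expect_error(cohort_config(n_coexpressed_lnc = 4,
                             planted_betas = rep(0.5, 4)),
               "not enough DE")
  expect_error(cohort_config(n_tumour = 0), "positive count")
})

test_that("censoring calibration hits the target within 5 points", {
  for (s in 1:5) {
    cfg <- cohort_config(n_tumour = 250, n_normal = 5, n_lncrna = 10,
                         n_immune_genes = 8, n_other_genes = 4,
                         n_coexpressed_lnc = 4, n_de_lnc_up = 4,
                         n_de_lnc_down = 2, planted_betas = c(0.8, -0.8),
                         n_clusters = 1,
                         censoring_fraction_target = 0.3, seed = s)
    cohort <- generate_cohort(cfg)
    expect_lt(abs(cohort$truth$realized_censoring - 0.3), 0.05)
  }
})

test_that("planted coexpression and fold changes are realized", {
  cfg <- cohort_config(n_tumour = 250, n_normal = 40, n_lncrna = 30,
                       n_immune_genes = 25, n_other_genes = 10,
                       n_coexpressed_lnc = 10, coexpression_r = 0.6,
                       n_de_lnc_up = 6, n_de_lnc_down = 3,
                       de_log2fc = 3, planted_betas = c(0.8, -0.8),
                       n_clusters = 1, seed = 5)
  cohort <- generate_cohort(cfg)
  tum <- samples_of(cohort$expr, "tumour")
  lx <- log2(cohort$expr$values + 1)
  truth <- cohort$truth
  rs <- vapply(seq_along(truth$coexpressed_lnc_ids), function(j) {
    cor(lx[truth$coexpressed_lnc_ids[j], tum],
        lx[truth$coexpression_partners[j], tum])
  }, numeric(1))
  expect_true(all(abs(rs - 0.6) < 0.1))
  nor <- samples_of(cohort$expr, "normal")
  lfc <- rowMeans(lx[truth$de_lnc_ids_up, tum]) -
    rowMeans(lx[truth$de_lnc_ids_up, nor])
  expect_true(all(abs(lfc - 3) < 0.6))
  lfc_dn <- rowMeans(lx[truth$de_lnc_ids_down, tum]) -
    rowMeans(lx[truth$de_lnc_ids_down, nor])
  expect_true(all(abs(lfc_dn + 3) < 0.6))
})

test_that("a planted pair with beta = 1 yields hazard ratio near e", {
  cfg <- cohort_config(n_tumour = 400, n_normal = 5, n_lncrna = 10,
                       n_immune_genes = 8, n_other_genes = 4,
                       n_coexpressed_lnc = 4, n_de_lnc_up = 4,
                       n_de_lnc_down = 0, planted_betas = 1.0,
                       n_clusters = 1, censoring_fraction_target = 0.3,
                       seed = 21)
  cohort <- generate_cohort(cfg)
  pr <- cohort$truth$planted_pairs
  s <- as.integer(cohort$expr$values[pr$lnc_a, cohort$clinical$sample_id] >
                    cohort$expr$values[pr$lnc_b, cohort$clinical$sample_id])
  fit <- cox_fit(data.frame(s = s), cohort$clinical$os_days,
                 cohort$clinical$os_event)
  expect_lt(abs(fit$table$coef - 1), 0.25)
})

test_that("a null cohort shows null behaviour under random splits", {
  cfg <- cohort_config(n_tumour = 120, n_normal = 5, n_lncrna = 10,
                       n_immune_genes = 8, n_other_genes = 4,
                       n_coexpressed_lnc = 4, n_de_lnc_up = 4,
                       n_de_lnc_down = 0, planted_betas = numeric(0),
                       n_clusters = 1, seed = 31)
  cohort <- generate_cohort(cfg)
  ps <- vapply(1:20, function(i) {
    set.seed(i)
    g <- sample(c(0, 1), nrow(cohort$clinical), replace = TRUE)
    logrank_test(g, cohort$clinical$os_days,
                 cohort$clinical$os_event)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.2)
})
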