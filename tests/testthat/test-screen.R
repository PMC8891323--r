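test_that("a lncRNA duplicating an immune gene is retained with r = 1", {
  set.seed(20)
  v <- rexp(30, 0.1)
  m <- rbind(LNCX = v, IMMX = v, LNCY = rexp(30, 0.1))
  colnames(m) <- paste0("S", 1:30)
  es <- expr_set(m, setNames(rep("tumour", 30), colnames(m)))
  out <- coexpression_filter(es, c("LNCX", "LNCY"), "IMMX")
  expect_true("LNCX" %in% out$lncrna)
  expect_equal(out$r[out$lncrna == "LNCX"], 1)
  expect_false("LNCY" %in% out$lncrna)
})

test_that("independent noise lncRNAs are excluded at n = 200", {
  set.seed(21)
  m <- rbind(matrix(rexp(20 * 200), 20,
                    dimnames = list(paste0("LNC", 1:20), NULL)),
             matrix(rexp(10 * 200), 10,
                    dimnames = list(paste0("IMM", 1:10), NULL)))
  colnames(m) <- paste0("S", 1:200)
  es <- expr_set(m, setNames(rep("tumour", 200), colnames(m)))
  out <- coexpression_filter(es, paste0("LNC", 1:20), paste0("IMM", 1:10))
  expect_equal(nrow(out), 0L)
})

test_that("the coexpression screen recovers the planted partners", {
  cfg <- cohort_config(n_tumour = 200, n_normal = 10, n_lncrna = 30,
                       n_immune_genes = 25, n_other_genes = 10,
                       n_coexpressed_lnc = 10, coexpression_r = 0.6,
                       n_de_lnc_up = 6, n_de_lnc_down = 2,
                       planted_betas = c(0.8, -0.8), n_clusters = 1,
                       seed = 22)
  cohort <- generate_cohort(cfg)
  sets <- classify_genes(cohort$annotation, cohort$immune_symbols)
  out <- coexpression_filter(cohort$expr, sets$lncrna, sets$immune)
  expect_true(all(cohort$truth$coexpressed_lnc_ids %in% out$lncrna))
  # false positives held near the thresholds' nominal rate
  fp <- setdiff(out$lncrna, cohort$truth$coexpressed_lnc_ids)
  expect_lte(length(fp), 2L)
})

test_that("raising the correlation threshold never grows the set", {
  cfg <- cohort_config(n_tumour = 120, n_normal = 10, n_lncrna = 20,
                       n_immune_genes = 15, n_other_genes = 5,
                       n_coexpressed_lnc = 8, coexpression_r = 0.5,
                       n_de_lnc_up = 4, n_de_lnc_down = 2,
                       planted_betas = c(0.6, -0.6), n_clusters = 1,
                       seed = 23)
  cohort <- generate_cohort(cfg)
  sets <- classify_genes(cohort$annotation, cohort$immune_symbols)
  prev <- Inf
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    n <- nrow(coexpression_filter(cohort$expr, sets$lncrna, sets$immune,
                                  r_threshold = thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("differential expression calls match the planted truth", {
  cfg <- cohort_config(n_tumour = 200, n_normal = 25, n_lncrna = 40,
                       n_immune_genes = 20, n_other_genes = 10,
                       n_coexpressed_lnc = 10, n_de_lnc_up = 12,
                       n_de_lnc_down = 5, de_log2fc = 3,
                       planted_betas = c(0.8, -0.8), n_clusters = 1,
                       seed = 24)
  cohort <- generate_cohort(cfg)
  lnc <- classify_genes(cohort$annotation, cohort$immune_symbols)$lncrna
  de <- differential_expression(cohort$expr, lnc)
  up <- de$gene[de$direction == "up"]
  dn <- de$gene[de$direction == "down"]
  expect_setequal(up, cohort$truth$de_lnc_ids_up)
  expect_setequal(dn, cohort$truth$de_lnc_ids_down)
  # calls invariant to sample column order
  perm <- sample(colnames(cohort$expr$values))
  es2 <- expr_set(cohort$expr$values[, perm],
                  cohort$expr$condition[perm])
  de2 <- differential_expression(es2, lnc)
  expect_equal(de2[order(de2$gene), ], de[order(de$gene), ],
               ignore_attr = TRUE)
})

test_that("differential expression is calibrated under the null", {
  set.seed(25)
  m <- matrix(rexp(200 * 60), 200,
              dimnames = list(paste0("G", 1:200), paste0("S", 1:60)))
  es <- expr_set(m, setNames(rep(c("tumour", "normal"), c(40, 20)),
                             colnames(m)))
  de <- differential_expression(es, rownames(m))
  expect_true(all(de$direction == "ns"))
  expect_lte(mean(de$q < 0.05), 0.05)
  expect_error(differential_expression(
    expr_set(m, setNames(rep(c("tumour", "normal"), c(59, 1)),
                         colnames(m))), rownames(m)),
    "2 samples")
})
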