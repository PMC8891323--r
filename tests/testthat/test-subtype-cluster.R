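test_that("duplicated-sample blocks give an exact 0/1 consensus", {
  block_a <- matrix(rep(c(1L, 1L, 0L, 0L, 0L), 12), 5)
  block_b <- matrix(rep(c(0L, 0L, 1L, 1L, 1L), 12), 5)
  x <- cbind(block_a, block_b)
  dimnames(x) <- list(paste0("p", 1:5), paste0("s", 1:24))
  cc <- consensus_cluster(x, k_range = 2:3, reps = 30, seed = 1, k = 2)
  cm <- cc$consensus[["2"]]
  same <- outer(rep(1:2, each = 12), rep(1:2, each = 12), "==")
  expect_true(all(cm[same] == 1))
  expect_true(all(cm[!same] == 0))
  expect_equal(length(unique(cc$labels[1:12])), 1L)
  # determinism
  cc2 <- consensus_cluster(x, k_range = 2:3, reps = 30, seed = 1, k = 2)
  expect_identical(cc$labels, cc2$labels)
})

test_that("consensus matrices are symmetric with unit diagonal", {
  set.seed(80)
  x <- matrix(rbinom(6 * 30, 1, 0.5), 6, 30,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:30)))
  cc <- consensus_cluster(x, k_range = 2:4, reps = 40, seed = 2)
  for (cm in cc$consensus) {
    expect_true(all(cm >= 0 & cm <= 1))
    expect_equal(cm, t(cm))
    expect_true(all(diag(cm) == 1))
  }
  expect_true(all(cc$pac >= 0 & cc$pac <= 1))
})

test_that("planted subtypes are recovered from pair features", {
  cohort <- generate_cohort(cluster_config(1))
  truth <- cohort$truth
  pm <- encode_pairs(cohort$expr,
                     unique(c(truth$planted_pairs$lnc_a,
                              truth$planted_pairs$lnc_b)))
  feats <- pm[truth$planted_pairs$pair, , drop = FALSE]
  cc <- consensus_cluster(feats, reps = 60, seed = 9, k = 3)
  ari <- adjusted_rand_index(cc$labels, truth$cluster_labels[colnames(feats)])
  expect_gte(ari, 0.8)
  # PCA separates the planted clusters on the top components
  emb <- pca_embed(feats, cc$labels)
  cent <- aggregate(emb$coords, list(cl = truth$cluster_labels), mean)
  d_between <- min(dist(cent[, -1]))
  within <- mean(vapply(split(as.data.frame(emb$coords),
                              truth$cluster_labels), function(d)
    mean(sqrt(rowSums(sweep(d, 2, colMeans(d))^2))), numeric(1)))
  expect_gt(d_between, within)
  expect_lte(sum(emb$var_explained), 1 + 1e-9)
})

test_that("adjusted Rand index behaves at its anchors", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  perm <- c(2, 3, 1)[a]
  expect_equal(adjusted_rand_index(a, perm), 1)
  set.seed(81)
  b <- sample(1:3, 30, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.35)
})

test_that("cluster statistics are invariant to label permutation", {
  cohort <- generate_cohort(cluster_config(2))
  labels <- cohort$truth$cluster_labels
  cmp1 <- cluster_comparisons(labels, cohort$clinical,
                              estimate = cohort$estimate)
  relab <- setNames(c(3L, 1L, 2L)[labels], names(labels))
  cmp2 <- cluster_comparisons(relab, cohort$clinical,
                              estimate = cohort$estimate)
  expect_equal(cmp1$survival$statistic, cmp2$survival$statistic)
  expect_equal(cmp1$scores$p, cmp2$scores$p)
  # planted cluster hazards separate survival
  expect_lt(cmp1$survival$p, 0.05)
  # ESTIMATE scores differ across clusters by construction
  expect_true(all(cmp1$scores$p < 0.05))
})

test_that("duplicated identical clusters give a null log-rank", {
  times <- rep(c(100, 300, 700, 1500), 5)
  events <- rep(c(1, 1, 0, 1), 5)
  labels <- setNames(rep(1:2, each = 10), paste0("s", 1:20))
  cl <- data.frame(sample_id = paste0("s", 1:20),
                   os_days = rep(times[1:10], 2)[1:20],
                   os_event = rep(events[1:10], 2)[1:20])
  cl$os_days <- c(times[1:10], times[1:10])
  cl$os_event <- c(events[1:10], events[1:10])
  cmp <- cluster_comparisons(labels, cl)
  expect_equal(cmp$survival$statistic, 0, tolerance = 1e-12)
})

test_that("degenerate inputs are handled", {
  x <- matrix(rbinom(4 * 25, 1, 0.5), 4, 25,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:25)))
  expect_error(consensus_cluster(x[, 1:10]), "20 samples")
  expect_error(consensus_cluster(x[1, , drop = FALSE]), "2 features")
  labels <- setNames(c(rep(1, 22), rep(2, 3)), colnames(x))
  cl <- data.frame(sample_id = colnames(x),
                   os_days = 100 + seq_len(25), os_event = rep(0:1, c(5, 20)))
  expect_warning(expect_error(
    cluster_comparisons(labels, cl), "2 usable"), "degenerate")
})
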