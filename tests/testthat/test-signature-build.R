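make_clin <- function(n, n_events, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("P%03d", 1:n),
             os_days = sample(50:2000, n, replace = TRUE),
             os_event = sample(rep(c(1L, 0L), c(n_events, n - n_events))))
}

test_that("the stratified split balances events and is reproducible", {
  cl <- make_clin(100, 40)
  sp <- split_cohort(cl, seed = 3)
  expect_setequal(c(sp$train, sp$test), cl$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  ev_tr <- sum(cl$os_event[cl$sample_id %in% sp$train])
  expect_true(abs(ev_tr - 20) <= 2)
  expect_identical(split_cohort(cl, seed = 3), sp)
  expect_false(identical(split_cohort(cl, seed = 4)$train, sp$train))
  cl_odd <- make_clin(101, 40)
  sp_odd <- split_cohort(cl_odd, seed = 3)
  expect_equal(abs(length(sp_odd$train) - length(sp_odd$test)), 1L)
  expect_error(split_cohort(make_clin(10, 5)), "20 samples")
})

sim_pairs <- function(n, betas, n_null, seed) {
  set.seed(seed)
  k <- length(betas)
  pm <- matrix(rbinom((k + n_null) * n, 1, 0.5), k + n_null, n,
               dimnames = list(c(sprintf("true%d", seq_len(k)),
                                 sprintf("null%02d", seq_len(n_null))),
                               sprintf("P%03d", 1:n)))
  eta <- as.numeric(crossprod(pm[seq_len(k), , drop = FALSE], betas))
  tt <- rexp(n, 1e-3 * exp(eta))
  cc <- runif(n, 0, 3500)
  list(pm = pm, times = pmax(1, ceiling(pmin(tt, cc))),
       events = as.integer(tt <= cc))
}

test_that("univariate screen finds planted pairs and skips constants", {
  d <- sim_pairs(400, c(1.0), 10, seed = 30)
  d$pm <- rbind(d$pm, const = rep(1L, 400))
  expect_warning(uni <- univariate_screen(d$pm, d$times, d$events),
                 "constant")
  expect_true("true1" %in% uni$candidates)
  expect_equal(uni$skipped, "const")
  # null pairs selected near the nominal rate
  nulls <- grep("null", uni$table$pair, value = TRUE)
  expect_lte(mean(uni$table$p[uni$table$pair %in% nulls] < 0.05), 0.3)
})

test_that("lasso keeps the strong pair and is seed-deterministic", {
  d <- sim_pairs(400, c(1.2), 20, seed = 31)
  uni <- univariate_screen(d$pm, d$times, d$events)
  las <- lasso_cox_cv(d$pm, rownames(d$pm), d$times, d$events, seed = 5)
  expect_true("true1" %in% las$survivors)
  las2 <- lasso_cox_cv(d$pm, rownames(d$pm), d$times, d$events, seed = 5)
  expect_identical(las$survivors, las2$survivors)
  expect_true(all(las$survivors %in% rownames(d$pm)))
  expect_error(lasso_cox_cv(d$pm, "true1", d$times, d$events),
               "2 candidate")
})

test_that("stepwise selection keeps planted pairs and lowers AIC", {
  d <- sim_pairs(400, c(0.9, -0.9, 0.9, -0.9), 2, seed = 32)
  sig <- stepwise_cox(d$pm, rownames(d$pm), d$times, d$events)
  expect_gte(sum(sprintf("true%d", 1:4) %in% sig$pairs), 3)
  expect_lte(sig$trace$aic_final, sig$trace$aic_initial + 1e-9)
  expect_true(all(!is.na(sig$beta)))
  # single survivor -> that pair is the signature
  sig1 <- stepwise_cox(d$pm, "true1", d$times, d$events)
  expect_equal(sig1$pairs, "true1")
})

test_that("risk scores are the exact linear combination", {
  pm <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L), 2, 3,
               dimnames = list(c("a|b", "c|d"), c("s1", "s2", "s3")))
  sig <- structure(list(pairs = c("a|b", "c|d"),
                        beta = c("a|b" = 0.5, "c|d" = -0.3)),
                   class = "pair_signature")
  expect_equal(unname(risk_scores(sig, pm)),
               c(0.5 * 1 - 0.3 * 0, 0.5 * 0 - 0.3 * 1, 0.5 * 1 - 0.3 * 0))
  expect_equal(unname(risk_scores(sig, pm * 0L)), rep(0, 3))
  set.seed(33)
  pm2 <- matrix(rbinom(20 * 8, 1, 0.5), 20, 8,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:8)))
  sig2 <- structure(list(pairs = rownames(pm2),
                         beta = setNames(rnorm(20), rownames(pm2))),
                    class = "pair_signature")
  expect_equal(unname(risk_scores(sig2, pm2)),
               as.numeric(t(pm2) %*% sig2$beta))
  expect_error(risk_scores(sig, pm[1, , drop = FALSE]), "missing")
})

test_that("the expression baseline recovers a planted prognostic gene", {
  set.seed(34)
  n <- 300
  ids <- sprintf("P%03d", 1:n)
  x <- matrix(rexp(20 * n, 0.05), 20, n,
              dimnames = list(paste0("LNC", 1:20), ids))
  risk_gene <- log2(x["LNC1", ] + 1)
  tt <- rexp(n, 1e-3 * exp(0.8 * scale(risk_gene)[, 1]))
  cc <- runif(n, 0, 3500)
  times <- pmax(1, ceiling(pmin(tt, cc)))
  events <- as.integer(tt <= cc)
  es <- expr_set(x, setNames(rep("tumour", n), ids))
  bl <- baseline_expression_signature(es, rownames(x), times, events,
                                      ids, p_threshold = 0.01)
  expect_true("LNC1" %in% bl$genes)
  expect_gt(bl$coef[["LNC1"]], 0)
  risk <- expression_risk_scores(bl, es, ids)
  grp <- assign_groups(risk, bl$cutoff)
  expect_lte(abs(sum(grp == "high") - sum(grp == "low")), 1)
  expect_error(baseline_expression_signature(es, rownames(x), times,
                                             events, ids,
                                             p_threshold = 1e-30),
               "no gene passes")
})
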