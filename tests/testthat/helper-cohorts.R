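# Shared synthetic-cohort configurations and cached heavy runs. The cache
# lives for one test session so the recovery cohorts are generated and
# analysed once and reused by every test that needs them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Strong-signal cohort: 400 tumour samples, 4 planted pairs |beta| = 0.8,
# ~30% censoring, no subtype structure.
recovery_config <- function(seed) {
  cohort_config(n_tumour = 400, n_normal = 15, n_lncrna = 40,
                n_immune_genes = 40, n_other_genes = 20,
                n_coexpressed_lnc = 16, n_de_lnc_up = 12,
                n_de_lnc_down = 4,
                planted_betas = c(0.8, -0.8, 0.8, -0.8),
                n_clusters = 1, censoring_fraction_target = 0.3,
                seed = seed)
}

# Full pipeline runs on the strong-signal cohorts, one per seed.
recovery_runs <- function(seeds = 1:5) {
  cached("recovery_runs", lapply(seeds, function(s) {
    cohort <- generate_cohort(recovery_config(s))
    run <- suppressWarnings(run_all(cohort, run_config(seed = s + 100)))
    list(cohort = cohort, run = run)
  }))
}

# Three balanced planted subtypes separated by flipped pair orderings,
# with a planted per-cluster hazard step.
cluster_config <- function(seed) {
  cohort_config(n_tumour = 240, n_normal = 10, n_lncrna = 60,
                n_immune_genes = 40, n_other_genes = 20,
                n_coexpressed_lnc = 30, n_de_lnc_up = 24,
                n_de_lnc_down = 6, planted_betas = rep(0.2, 12),
                n_clusters = 3, cluster_sep = 2, cluster_hazard = 0.6,
                censoring_fraction_target = 0.3, seed = seed)
}

# Fully null cohort: no planted pairs, no subtypes, enough DE lncRNAs for
# several hundred balanced null pairs.
null_config <- function(seed) {
  cohort_config(n_tumour = 200, n_normal = 10, n_lncrna = 90,
                n_immune_genes = 90, n_other_genes = 10,
                n_coexpressed_lnc = 85, n_de_lnc_up = 65,
                n_de_lnc_down = 20, planted_betas = numeric(0),
                n_clusters = 1, censoring_fraction_target = 0.3,
                seed = seed)
}

# A small expression set built by hand for definition-level tests.
toy_expr_set <- function() {
  m <- rbind(
    LNC01 = c(5, 3, 7, 2, 6, 1),
    LNC02 = c(3, 5, 2, 7, 1, 6),
    IMM01 = c(4, 4, 4, 4, 4, 4),
    IMM02 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("S", 1:6)
  expr_set(m, setNames(rep(c("tumour", "normal"), c(4, 2)),
                       colnames(m)))
}
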