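#' Configuration for a synthetic bladder-cancer-like cohort
#'
#' Defines the generative model used to emulate the structure the analysis
#' assumes: log-normal expression (log2 values Gaussian per gene), planted
#' lncRNA-immune-gene coexpression via a shared latent factor, planted
#' tumour/normal differential expression, exponential survival whose hazard
#' is `h0 * exp(sum(beta_i * S_i) + cluster_hazard * (cluster - 1))` where
#' `S_i` is the 0/1 ordering of planted lncRNA pair i, independent uniform
#' censoring calibrated to a target fraction, clinical covariates with a
#' mild planted stage-risk dependence, and infiltration / checkpoint / IC50
#' tables monotone in the true linear predictor.
#'
#' Default sizes mirror a TCGA-BLCA-like cohort (394 tumour, 18 normal
#' samples; 96 differentially expressed lncRNAs, 81 up and 15 down).
#'
#' @param n_tumour,n_normal sample counts.
#' @param n_lncrna,n_immune_genes,n_other_genes gene counts by class.
#' @param n_coexpressed_lnc number of lncRNAs given an immune-gene partner.
#' @param coexpression_r target Pearson correlation with the partner.
#' @param n_de_lnc_up,n_de_lnc_down counts of up/down differentially
#'   expressed lncRNAs (tumour vs normal).
#' @param de_log2fc magnitude of the planted log2 fold change.
#' @param planted_pairs optional data.frame `(lnc_a, lnc_b, beta)` naming
#'   the prognostic pairs explicitly (canonical orientation, `lnc_a` <
#'   `lnc_b`); default `NULL` auto-assigns pairs among the first
#'   differentially expressed, coexpressed lncRNAs using `planted_betas`.
#' @param planted_betas Cox log-hazard coefficients of the auto-assigned
#'   pairs (may be empty for a null cohort).
#' @param baseline_hazard events per day at linear predictor 0.
#' @param censoring_fraction_target fraction of samples censored, in
#'   \[0, 1).
#' @param n_clusters number of planted tumour subtypes (1 = none).
#' @param cluster_sep log2 mean shift used to flip pair orderings between
#'   clusters.
#' @param cluster_hazard additive log-hazard per cluster index step.
#' @param stage_assoc strength of the stage / risk association.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration including this seed.
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_tumour = 394, n_normal = 18,
                          n_lncrna = 200, n_immune_genes = 150,
                          n_other_genes = 150,
                          n_coexpressed_lnc = 60, coexpression_r = 0.6,
                          n_de_lnc_up = 81, n_de_lnc_down = 15,
                          de_log2fc = 3,
                          planted_pairs = NULL,
                          planted_betas = c(0.8, -0.8, 0.8, -0.8),
                          baseline_hazard = 1e-3,
                          censoring_fraction_target = 0.3,
                          n_clusters = 3, cluster_sep = 2,
                          cluster_hazard = 0.5,
                          stage_assoc = 0.8,
                          seed = 1L) {
  cfg <- list(n_tumour = n_tumour, n_normal = n_normal,
              n_lncrna = n_lncrna, n_immune_genes = n_immune_genes,
              n_other_genes = n_other_genes,
              n_coexpressed_lnc = n_coexpressed_lnc,
              coexpression_r = coexpression_r,
              n_de_lnc_up = n_de_lnc_up, n_de_lnc_down = n_de_lnc_down,
              de_log2fc = de_log2fc,
              planted_pairs = planted_pairs,
              planted_betas = planted_betas,
              baseline_hazard = baseline_hazard,
              censoring_fraction_target = censoring_fraction_target,
              n_clusters = n_clusters, cluster_sep = cluster_sep,
              cluster_hazard = cluster_hazard,
              stage_assoc = stage_assoc,
              seed = as.integer(seed))
  counts <- c("n_tumour", "n_normal", "n_lncrna", "n_immune_genes",
              "n_other_genes", "n_clusters")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || cfg[[f]] < 1) {
      stop_input(f, " must be a positive count")
    }
  }
  if (n_coexpressed_lnc < 0 || n_coexpressed_lnc > n_lncrna) {
    stop_input("n_coexpressed_lnc out of range")
  }
  if (n_coexpressed_lnc > n_immune_genes) {
    stop_input("need an immune partner per coexpressed lncRNA")
  }
  if (n_de_lnc_up + n_de_lnc_down > n_lncrna) {
    stop_input("more DE lncRNAs than lncRNAs")
  }
  if (coexpression_r < 0 || coexpression_r > 1) {
    stop_input("coexpression_r must be in [0, 1]")
  }
  if (censoring_fraction_target < 0 || censoring_fraction_target >= 1) {
    stop_input("censoring_fraction_target must be in [0, 1)")
  }
  if (baseline_hazard <= 0) stop_input("baseline_hazard must be > 0")
  n_pairs <- if (is.null(planted_pairs)) length(planted_betas)
             else nrow(planted_pairs)
  if (is.null(planted_pairs) && n_pairs > 0) {
    # auto-assignment draws members from the DE-up, coexpressed lncRNAs
    if (2 * n_pairs > min(n_de_lnc_up, n_coexpressed_lnc)) {
      stop_input("not enough DE, coexpressed lncRNAs for ", n_pairs,
                 " planted pairs")
    }
  }
  structure(cfg, class = "cohort_config")
}

lnc_id <- function(i) sprintf("LNC%04d", i)
imm_id <- function(i) sprintf("IMM%04d", i)
oth_id <- function(i) sprintf("PCG%04d", i)

# Calibrate the upper bound of Uniform(0, m) censoring so the expected
# censored fraction matches the target: P(C < T) for T ~ Exp(lambda) is
# (1 - exp(-lambda m)) / (lambda m), averaged over samples.
calibrate_censoring <- function(lambda, target) {
  if (target <= 0) return(Inf)
  f <- function(m) mean((1 - exp(-lambda * m)) / (lambda * m)) - target
  stats::uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-8)$root
}

#' Generate a fully labelled synthetic cohort
#'
#' Draws one cohort from the generative model described in
#' [cohort_config()] and returns every table the analysis pipeline consumes
#' plus the ground truth it was generated from. The output is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config a [cohort_config()]
#' @return list of class `lnc_cohort` with elements `expr` ([expr_set()]),
#'   `clinical`, `annotation`, `immune_symbols`, `infiltration`,
#'   `estimate`, `ic50`, `truth` (ground-truth list) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_t <- cfg$n_tumour; n_n <- cfg$n_normal
    tum <- sprintf("TUM%04d", seq_len(n_t))
    nor <- sprintf("NOR%04d", seq_len(n_n))
    samples <- c(tum, nor)
    condition <- stats::setNames(rep(c("tumour", "normal"), c(n_t, n_n)),
                                 samples)

    lnc <- lnc_id(seq_len(cfg$n_lncrna))
    imm <- imm_id(seq_len(cfg$n_immune_genes))
    oth <- oth_id(seq_len(cfg$n_other_genes))
    genes <- c(lnc, imm, oth)
    G <- length(genes)

    de_up <- lnc[seq_len(cfg$n_de_lnc_up)]
    de_down <- if (cfg$n_de_lnc_down > 0) {
      lnc[cfg$n_de_lnc_up + seq_len(cfg$n_de_lnc_down)]
    } else character()
    coexpressed <- lnc[seq_len(cfg$n_coexpressed_lnc)]
    partners <- stats::setNames(imm[seq_len(cfg$n_coexpressed_lnc)],
                                coexpressed)

    pairs <- cfg$planted_pairs
    if (is.null(pairs)) {
      nb <- length(cfg$planted_betas)
      pairs <- if (nb > 0) {
        data.frame(lnc_a = lnc_id(2 * seq_len(nb) - 1),
                   lnc_b = lnc_id(2 * seq_len(nb)),
                   beta = cfg$planted_betas,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(lnc_a = character(), lnc_b = character(),
                   beta = numeric())
      }
    }
    if (nrow(pairs)) {
      memb <- c(pairs$lnc_a, pairs$lnc_b)
      if (anyDuplicated(memb)) stop_input("planted pair members overlap")
      if (!all(memb %in% c(de_up, de_down))) {
        stop_input("planted pair members must be DE lncRNAs")
      }
      if (any(pairs$lnc_a >= pairs$lnc_b)) {
        stop_input("planted pairs must be canonically oriented (lnc_a < lnc_b)")
      }
      pairs$pair <- paste(pairs$lnc_a, pairs$lnc_b, sep = "|")
    } else {
      pairs$pair <- character()
    }

    mu <- stats::setNames(stats::rnorm(G, 5, 1.5), genes)
    sd_g <- stats::setNames(stats::runif(G, 0.4, 0.8), genes)
    # planted pair members share mean and sd so their ordering is balanced
    mu[pairs$lnc_b] <- mu[pairs$lnc_a]
    sd_g[pairs$lnc_b] <- sd_g[pairs$lnc_a]

    eps <- matrix(stats::rnorm(G * length(samples)), G, length(samples),
                  dimnames = list(genes, samples))
    # coexpression through a shared latent factor: loading sqrt(r) on both
    # partners yields Pearson correlation r in closed form
    r <- cfg$coexpression_r
    if (r > 0 && cfg$n_coexpressed_lnc > 0) {
      for (j in seq_len(cfg$n_coexpressed_lnc)) {
        z <- stats::rnorm(length(samples))
        eps[coexpressed[j], ] <- sqrt(r) * z +
          sqrt(1 - r) * eps[coexpressed[j], ]
        eps[partners[j], ] <- sqrt(r) * z +
          sqrt(1 - r) * eps[partners[j], ]
      }
    }
    log2x <- mu + sd_g * eps  # recycles by row

    log2x[de_up, tum] <- log2x[de_up, tum] + cfg$de_log2fc
    if (length(de_down)) {
      log2x[de_down, tum] <- log2x[de_down, tum] - cfg$de_log2fc
    }

    # clusters flip the expected ordering of their home pairs
    K <- cfg$n_clusters
    cl <- NULL
    if (K > 1) {
      # balanced planted subtypes: equal sizes, random membership
      cl <- stats::setNames(sample(rep(seq_len(K), length.out = n_t)), tum)
      if (cfg$cluster_sep > 0 && nrow(pairs)) {
        home <- ((seq_len(nrow(pairs)) - 1L) %% K) + 1L
        for (j in seq_len(nrow(pairs))) {
          own <- tum[cl == home[j]]
          oth_s <- setdiff(tum, own)
          s <- cfg$cluster_sep
          log2x[pairs$lnc_a[j], own] <- log2x[pairs$lnc_a[j], own] + s
          log2x[pairs$lnc_b[j], own] <- log2x[pairs$lnc_b[j], own] - s
          log2x[pairs$lnc_a[j], oth_s] <- log2x[pairs$lnc_a[j], oth_s] - s
          log2x[pairs$lnc_b[j], oth_s] <- log2x[pairs$lnc_b[j], oth_s] + s
        }
      }
    }

    # immune-checkpoint panel: last immune genes, expression monotone in
    # the true risk (null when the linear predictor is constant)
    ici <- imm[seq.int(cfg$n_immune_genes - min(7, cfg$n_immune_genes - 1),
                       cfg$n_immune_genes)]

    # true linear predictor over tumour samples
    S <- if (nrow(pairs)) {
      (log2x[pairs$lnc_a, tum, drop = FALSE] >
         log2x[pairs$lnc_b, tum, drop = FALSE]) + 0
    } else {
      matrix(0, 0, n_t)
    }
    eta <- as.numeric(if (nrow(pairs)) crossprod(S, pairs$beta) else
                        rep(0, n_t))
    if (!is.null(cl)) eta <- eta + cfg$cluster_hazard * (cl - 1)
    eta <- stats::setNames(eta, tum)
    eta_std <- if (stats::sd(eta) > 0) as.numeric(scale(eta)) else
      rep(0, n_t)

    log2x[ici, tum] <- log2x[ici, tum] +
      rep(0.5 * eta_std, each = length(ici))

    expr <- expr_set(2^log2x, condition)

    # exponential survival, uniform censoring calibrated to the target
    lambda <- cfg$baseline_hazard * exp(eta)
    t_event <- stats::rexp(n_t, rate = lambda)
    cmax <- calibrate_censoring(lambda, cfg$censoring_fraction_target)
    c_time <- if (is.finite(cmax)) stats::runif(n_t, 0, cmax) else
      rep(Inf, n_t)
    os_days <- pmax(1, ceiling(pmin(t_event, c_time)))
    os_event <- as.integer(t_event <= c_time)

    age <- pmin(90, pmax(30, round(stats::rnorm(n_t, 68, 10))))
    sex <- sample(c("male", "female"), n_t, replace = TRUE,
                  prob = c(0.75, 0.25))
    grade <- ifelse(0.5 * eta_std + stats::rnorm(n_t) > 0, "high", "low")
    stage_lat <- cfg$stage_assoc * eta_std + stats::rnorm(n_t)
    stage_num <- as.integer(cut(stage_lat,
                                stats::quantile(stage_lat,
                                                c(0, .2, .45, .75, 1)),
                                include.lowest = TRUE))
    stage <- c("I", "II", "III", "IV")[stage_num]
    t_num <- pmin(4L, pmax(1L, stage_num +
                             sample(c(-1L, 0L, 1L), n_t, TRUE,
                                    prob = c(.2, .6, .2))))
    clinical <- data.frame(
      sample_id = tum, os_days = os_days, os_event = os_event,
      age = age, sex = sex, grade = grade, stage = stage,
      t_stage = paste0("T", t_num),
      n_stage = ifelse(stats::runif(n_t) <
                         stats::plogis(-1 + 0.5 * eta_std), "N1", "N0"),
      m_stage = ifelse(stats::runif(n_t) < 0.1, "M1", "M0"),
      stringsAsFactors = FALSE)

    annotation <- data.frame(
      gene_id = genes,
      symbol = c(sprintf("LINC%04d", seq_along(lnc)),
                 sprintf("IMMG%04d", seq_along(imm)),
                 sprintf("GENE%04d", seq_along(oth))),
      biotype = rep(c("lncRNA", "protein_coding", "protein_coding"),
                    c(length(lnc), length(imm), length(oth))),
      stringsAsFactors = FALSE)
    immune_symbols <- annotation$symbol[match(imm, annotation$gene_id)]

    cell_types <- c("B_cell", "CD4_T", "CD8_T", "Macrophage", "NK",
                    "Neutrophil", "DC", "CAF")
    ct_assoc <- stats::setNames(c(0.5, 0.4, 0.6, 0.7, 0, 0.3, 0, 0.6),
                                cell_types)
    methods <- c("XCELL", "TIMER", "QUANTISEQ")
    infiltration <- do.call(rbind, lapply(methods, function(m) {
      do.call(rbind, lapply(cell_types, function(ct) {
        data.frame(sample_id = tum, cell_type = ct, method = m,
                   score = ct_assoc[ct] * eta_std + stats::rnorm(n_t),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(infiltration) <- NULL

    cl_shift <- if (!is.null(cl) && cfg$cluster_sep > 0) 0.8 * (cl - 1) else
      rep(0, n_t)
    immune_sc <- stats::rnorm(n_t) + cl_shift + 0.4 * eta_std
    stromal_sc <- stats::rnorm(n_t) + 0.8 * cl_shift
    estimate <- data.frame(sample_id = tum,
                           StromalScore = stromal_sc,
                           ImmuneScore = immune_sc,
                           ESTIMATEScore = immune_sc + stromal_sc,
                           stringsAsFactors = FALSE)

    drugs <- sprintf("Drug%02d", 1:20)
    drug_assoc <- stats::setNames(rep(c(-0.6, 0), c(10, 10)), drugs)
    ic50 <- do.call(rbind, lapply(drugs, function(d) {
      data.frame(sample_id = tum, drug = d,
                 ic50 = drug_assoc[d] * eta_std + stats::rnorm(n_t),
                 stringsAsFactors = FALSE)
    }))
    rownames(ic50) <- NULL

    truth <- list(
      de_lnc_ids_up = de_up, de_lnc_ids_down = de_down,
      coexpressed_lnc_ids = coexpressed, coexpression_partners = partners,
      planted_pairs = pairs[, c("pair", "lnc_a", "lnc_b", "beta")],
      cluster_labels = cl, true_risk = eta,
      realized_censoring = 1 - mean(os_event),
      censor_max = cmax, ici_genes = ici,
      infiltration_assoc = ct_assoc, drug_assoc = drug_assoc)

    structure(list(expr = expr, clinical = clinical,
                   annotation = annotation,
                   immune_symbols = immune_symbols,
                   infiltration = infiltration, estimate = estimate,
                   ic50 = ic50, truth = truth, config = cfg),
              class = "lnc_cohort")
  })
}

#' @export
print.lnc_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d tumour + %d normal samples, ",
                     "%d genes, %d planted pair(s)\n"),
              x$config$n_tumour, x$config$n_normal, nrow(x$expr$values),
              nrow(x$truth$planted_pairs)))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits every external-interface file (`expression.tsv`, `samples.tsv`,
#' `clinical.tsv`, `annotation.tsv`, `immune_genes.txt`,
#' `infiltration.tsv`, `estimate.tsv`, `ic50.tsv`), a ground-truth pair
#' table, a config echo and a `manifest.tsv`; empty optional tables are
#' omitted and noted in the manifest. Files round-trip through the
#' `read_*` functions.
#'
#' @param cohort an `lnc_cohort`
#' @param dir target directory (created if needed)
#' @return invisibly, the manifest data.frame
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lnc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file
  }
  files <- character()
  em <- data.frame(gene_id = rownames(cohort$expr$values),
                   cohort$expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  files <- c(files, wt(em, "expression.tsv"))
  files <- c(files, wt(data.frame(
    sample_id = names(cohort$expr$condition),
    condition = as.character(cohort$expr$condition)), "samples.tsv"))
  clin <- cohort$clinical
  names(clin)[match(c("t_stage", "n_stage", "m_stage"), names(clin))] <-
    c("T", "N", "M")
  files <- c(files, wt(clin, "clinical.tsv"))
  files <- c(files, wt(cohort$annotation, "annotation.tsv"))
  writeLines(c("# immune gene symbols", cohort$immune_symbols),
             file.path(dir, "immune_genes.txt"))
  files <- c(files, "immune_genes.txt")
  omitted <- character()
  for (nm in c("infiltration", "estimate", "ic50")) {
    tb <- cohort[[nm]]
    if (is.null(tb) || nrow(tb) == 0L) {
      omitted <- c(omitted, nm)
    } else {
      files <- c(files, wt(tb, paste0(nm, ".tsv")))
    }
  }
  if (nrow(cohort$truth$planted_pairs)) {
    files <- c(files, wt(cohort$truth$planted_pairs,
                         "ground_truth_pairs.tsv"))
  }
  cfg <- cohort$config
  scalars <- vapply(cfg, function(v)
    if (is.null(v) || is.data.frame(v)) NA_character_ else
      paste(v, collapse = ","), character(1))
  files <- c(files, wt(data.frame(key = names(scalars)[!is.na(scalars)],
                                  value = scalars[!is.na(scalars)]),
                       "config.tsv"))
  manifest <- rbind(
    data.frame(file = files, status = "written"),
    if (length(omitted)) data.frame(file = paste0(omitted, ".tsv"),
                                    status = "omitted_empty"))
  wt(manifest, "manifest.tsv")
  invisible(manifest)
}

#' Read a cohort fixture directory back into memory
#'
#' @param dir directory written by [write_fixture()]
#' @return list with the same table elements as [generate_cohort()]
#'   (ground truth restricted to what the fixture stores)
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  opt <- function(f, reader) if (file.exists(p(f))) reader(p(f)) else NULL
  list(expr = read_expression(p("expression.tsv"), p("samples.tsv")),
       clinical = read_clinical(p("clinical.tsv")),
       annotation = read_annotation(p("annotation.tsv")),
       immune_symbols = read_gene_list(p("immune_genes.txt")),
       infiltration = opt("infiltration.tsv", read_infiltration),
       estimate = opt("estimate.tsv", function(f)
         utils::read.delim(f, stringsAsFactors = FALSE)),
       ic50 = opt("ic50.tsv", read_ic50),
       planted_pairs = opt("ground_truth_pairs.tsv", function(f)
         utils::read.delim(f, stringsAsFactors = FALSE)))
}
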