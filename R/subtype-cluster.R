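#' Monti consensus clustering of tumour samples on binary pair features
#'
#' Resampling consensus: in each repetition a fraction of the samples is
#' drawn without replacement, clustered by average-linkage hierarchical
#' agglomeration on Hamming distance of the 0/1 features, and cut into k
#' groups; `consensus(i, j)` is the number of times i and j co-clustered
#' divided by the number of times both were sampled. Final labels at each
#' k come from hierarchical clustering of `1 - consensus`. The number of
#' clusters is chosen by the maximum of the relative delta-area of the
#' consensus CDF (with the k = 2 entry equal to its absolute area, the
#' usual convention) unless `k` is fixed by the caller; the proportion of
#' ambiguous clustering (PAC) is also reported as a diagnostic.
#'
#' @param features binary matrix, features x samples (e.g. the final
#'   signature's pair rows)
#' @param k_range candidate cluster numbers (default 2:6)
#' @param reps resampling repetitions (default 100)
#' @param item_fraction fraction of samples per repetition (default 0.8)
#' @param seed RNG seed
#' @param k fix the number of clusters instead of selecting it (the
#'   replication profile fixes k = 3)
#' @return object of class `consensus_result`: list with `k_range`,
#'   `consensus` (one matrix per k), `labels_by_k`, `area`, `delta_area`,
#'   `pac`, `k_selected`, `k_used`, `labels`
#' @export
consensus_cluster <- function(features, k_range = 2:6, reps = 100,
                              item_fraction = 0.8, seed = 1L, k = NULL) {
  if (ncol(features) < 20L) stop_input("need at least 20 samples")
  if (nrow(features) < 2L) stop_input("need at least 2 features")
  if (!all(features %in% c(0, 1))) stop_input("features must be 0/1")
  n <- ncol(features)
  ids <- colnames(features)
  kmax <- max(k_range)
  conn <- lapply(k_range, function(kk) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  nboth <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, floor(item_fraction * n)))
      # Hamming distance = Manhattan on 0/1 rows
      d <- stats::dist(t(features[, idx, drop = FALSE]),
                       method = "manhattan")
      hc <- stats::hclust(d, method = "average")
      nboth[idx, idx] <- nboth[idx, idx] + 1
      for (kk in k_range) {
        labs <- stats::cutree(hc, kk)
        conn[[as.character(kk)]][idx, idx] <-
          conn[[as.character(kk)]][idx, idx] + outer(labs, labs, "==")
      }
    }
  })
  off <- nboth[upper.tri(nboth)]
  if (any(off == 0)) {
    stop_input("some sample pairs were never co-sampled; increase reps")
  }
  consensus <- lapply(conn, function(m) {
    cm <- m / nboth
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  })
  grid <- seq(0, 1, by = 0.01)
  area <- vapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    cdf <- vapply(grid, function(c0) mean(v <= c0), numeric(1))
    sum(cdf) * 0.01
  }, numeric(1))
  delta <- numeric(length(k_range))
  delta[1] <- area[1]
  if (length(k_range) > 1) {
    delta[-1] <- diff(area) / utils::head(area, -1)
  }
  names(delta) <- names(area)
  pac <- vapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    mean(v <= 0.9) - mean(v <= 0.1)
  }, numeric(1))
  k_selected <- k_range[which.max(delta)]
  k_used <- k %||% k_selected
  labels_by_k <- lapply(seq_along(k_range), function(i) {
    cm <- consensus[[i]]
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    stats::setNames(stats::cutree(hc, k_range[i]), ids)
  })
  names(labels_by_k) <- as.character(k_range)
  structure(list(k_range = k_range, consensus = consensus,
                 labels_by_k = labels_by_k, area = area,
                 delta_area = delta, pac = pac,
                 k_selected = k_selected, k_used = k_used,
                 labels = labels_by_k[[as.character(k_used)]]),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering: k selected %d (used %d) over k in %s\n",
              x$k_selected, x$k_used,
              paste(range(x$k_range), collapse = "-")))
  print(data.frame(k = x$k_range, area = unname(x$area),
                   delta_area = unname(x$delta_area),
                   pac = unname(x$pac)), digits = 3)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), about 0 for independent ones.
#'
#' @param a,b cluster label vectors over the same items
#' @return numeric scalar
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("partitions differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

#' PCA embedding of samples on pair features
#'
#' Centered (unscaled) principal components of the samples; zero-variance
#' features are dropped. Returns the top-2 coordinates and the fraction of
#' variance each explains.
#'
#' @param features numeric matrix, features x samples
#' @param labels optional cluster labels carried through for plotting
#' @return list with `coords` (samples x 2), `var_explained` (length 2),
#'   `labels`
#' @export
pca_embed <- function(features, labels = NULL) {
  if (nrow(features) < 2L) stop_input("need at least 2 features")
  keep <- apply(features, 1, stats::sd) > 0
  x <- t(features[keep, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  list(coords = coords, var_explained = ve[seq_len(k)], labels = labels)
}

#' Survival, microenvironment and checkpoint comparisons across clusters
#'
#' Multi-group log-rank over the clusters; Kruskal-Wallis per
#' tumour-microenvironment score (Stromal/Immune/ESTIMATE) with pairwise
#' rank-sum follow-ups; Kruskal-Wallis per immune-checkpoint gene across
#' clusters. Clusters with fewer than `min_size` samples are dropped with
#' a warning.
#'
#' @param labels named cluster labels
#' @param clinical clinical data.frame
#' @param estimate optional ESTIMATE score data.frame (`sample_id`,
#'   `StromalScore`, `ImmuneScore`, `ESTIMATEScore`)
#' @param expr optional [expr_set()] for checkpoint genes
#' @param ici_genes gene ids tested across clusters
#' @param min_size minimum cluster size (default 5)
#' @return list with `survival` (statistic, df, p), `scores`,
#'   `score_pairwise`, `ici`
#' @export
cluster_comparisons <- function(labels, clinical, estimate = NULL,
                                expr = NULL, ici_genes = NULL,
                                min_size = 5L) {
  tab <- table(labels)
  small <- names(tab)[tab < min_size]
  if (length(small)) {
    warning("dropping degenerate cluster(s): ",
            paste(small, collapse = ", "), call. = FALSE)
    labels <- labels[!labels %in% small]
  }
  if (length(unique(labels)) < 2L) stop_input("need >= 2 usable clusters")
  cl <- clinical[match(names(labels), clinical$sample_id), ]
  surv <- logrank_test(labels, cl$os_days, cl$os_event)

  scores <- NULL; pairwise <- NULL
  if (!is.null(estimate)) {
    es <- estimate[match(names(labels), estimate$sample_id), ]
    types <- intersect(c("StromalScore", "ImmuneScore", "ESTIMATEScore"),
                       names(es))
    scores <- do.call(rbind, lapply(types, function(ty) {
      kt <- kruskal_test(es[[ty]], labels)
      data.frame(score = ty, statistic = kt$statistic, df = kt$df,
                 p = kt$p)
    }))
    lv <- sort(unique(labels))
    cmb <- utils::combn(lv, 2)
    pairwise <- do.call(rbind, lapply(types, function(ty) {
      do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
        a <- es[[ty]][labels == cmb[1, i]]
        b <- es[[ty]][labels == cmb[2, i]]
        rt <- ranksum_test(a, b)
        data.frame(score = ty, group_a = cmb[1, i], group_b = cmb[2, i],
                   p = rt$p)
      }))
    }))
    rownames(scores) <- rownames(pairwise) <- NULL
  }

  ici <- NULL
  if (!is.null(expr) && length(ici_genes)) {
    genes <- intersect(ici_genes, rownames(expr$values))
    ici <- do.call(rbind, lapply(genes, function(g) {
      v <- log2p1(expr$values[g, names(labels)])
      kt <- kruskal_test(v, labels)
      data.frame(gene = g, statistic = kt$statistic, df = kt$df, p = kt$p)
    }))
    if (!is.null(ici)) {
      ici$q <- bh_fdr(ici$p)
      rownames(ici) <- NULL
    }
  }
  list(survival = surv, scores = scores, score_pairwise = pairwise,
       ici = ici)
}
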