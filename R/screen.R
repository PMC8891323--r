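#' Immune coexpression filter for lncRNAs
#'
#' A lncRNA is called immune-related (IRlncRNA) when at least one immune
#' gene correlates with it beyond the thresholds (default Pearson
#' |r| > 0.4 and p < 0.001), computed on `log2(x + 1)` values over tumour
#' samples. The default is two-sided in r since negatively regulated
#' partners are biologically relevant; set `signed = TRUE` for the
#' one-sided `r > r_threshold` reading.
#'
#' @param expr an [expr_set()]
#' @param lnc_ids,immune_ids gene id sets to correlate
#' @param r_threshold,p_threshold retention thresholds
#' @param signed require positive r rather than |r|
#' @param tumour_only correlate over tumour samples only (default)
#' @return data.frame `(lncrna, partner, r, p)` with one row per retained
#'   lncRNA and its best (largest |r|) qualifying immune partner
#' @export
coexpression_filter <- function(expr, lnc_ids, immune_ids,
                                r_threshold = 0.4, p_threshold = 0.001,
                                signed = FALSE, tumour_only = TRUE) {
  if (length(lnc_ids) == 0L || length(immune_ids) == 0L) {
    stop_input("empty gene id set")
  }
  cols <- if (tumour_only) samples_of(expr, "tumour") else
    colnames(expr$values)
  if (length(cols) < 3L) stop_input("need at least 3 samples")
  lm <- log2p1(expr$values[lnc_ids, cols, drop = FALSE])
  im <- log2p1(expr$values[immune_ids, cols, drop = FALSE])
  vl <- apply(lm, 1, stats::sd) > 0
  vi <- apply(im, 1, stats::sd) > 0
  if (!all(vl) || !all(vi)) {
    warning(sum(!vl) + sum(!vi), " zero-variance gene(s) skipped",
            call. = FALSE)
  }
  lm <- lm[vl, , drop = FALSE]; im <- im[vi, , drop = FALSE]
  if (nrow(lm) == 0L || nrow(im) == 0L) {
    return(data.frame(lncrna = character(), partner = character(),
                      r = numeric(), p = numeric()))
  }
  n <- length(cols)
  r <- stats::cor(t(lm), t(im))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pass <- (if (signed) r > r_threshold else abs(r) > r_threshold) &
    p < p_threshold
  hit <- which(rowSums(pass) > 0)
  out <- lapply(hit, function(i) {
    j <- which(pass[i, ])
    j <- j[which.max(abs(r[i, j]))]
    data.frame(lncrna = rownames(r)[i], partner = colnames(r)[j],
               r = r[i, j], p = p[i, j], stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(lncrna = character(), partner = character(),
               r = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Tumour vs normal differential expression of lncRNAs
#'
#' Welch two-sample t test per gene on `log2(x + 1)` values;
#' `log2FC = mean(tumour) - mean(normal)`. BH adjustment is applied over
#' the tested genes only. A gene is called `up` when `q < fdr_threshold`
#' and `log2FC > lfc_threshold`, `down` symmetrically, otherwise `ns`.
#'
#' @param expr an [expr_set()]
#' @param ids genes to test (e.g. the IRlncRNA set)
#' @param lfc_threshold log2 fold-change magnitude threshold (default 2)
#' @param fdr_threshold BH q threshold (default 0.05)
#' @return data.frame `(gene, log2fc, stat, p, q, direction)`
#' @export
differential_expression <- function(expr, ids, lfc_threshold = 2,
                                    fdr_threshold = 0.05) {
  tum <- samples_of(expr, "tumour")
  nor <- samples_of(expr, "normal")
  if (length(tum) < 2L || length(nor) < 2L) {
    stop_input("need at least 2 samples per condition")
  }
  x <- log2p1(expr$values[ids, , drop = FALSE])
  xt <- x[, tum, drop = FALSE]; xn <- x[, nor, drop = FALSE]
  n1 <- length(tum); n0 <- length(nor)
  m1 <- rowMeans(xt); m0 <- rowMeans(xn)
  v1 <- apply(xt, 1, stats::var); v0 <- apply(xn, 1, stats::var)
  se2 <- v1 / n1 + v0 / n0
  stat <- (m1 - m0) / sqrt(pmax(se2, .Machine$double.eps))
  df <- se2^2 / pmax((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1),
                     .Machine$double.eps)
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[se2 == 0 & m1 == m0] <- 1
  q <- bh_fdr(p)
  lfc <- m1 - m0
  direction <- rep("ns", length(ids))
  direction[q < fdr_threshold & lfc > lfc_threshold] <- "up"
  direction[q < fdr_threshold & lfc < -lfc_threshold] <- "down"
  data.frame(gene = ids, log2fc = lfc, stat = stat, p = p, q = q,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}
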