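# Independent brute-force oracles used to pin down expected values.

# Pair encoding by an explicit double loop over genes and samples.
brute_encode_pairs <- function(x, gene_ids) {
  g <- sort(unique(gene_ids))
  out <- NULL
  nm <- character()
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (j <= i) next
      row <- integer(ncol(x))
      for (s in seq_len(ncol(x))) {
        row[s] <- if (x[g[i], s] > x[g[j], s]) 1L else 0L
      }
      out <- rbind(out, row)
      nm <- c(nm, paste(g[i], g[j], sep = "|"))
    }
  }
  rownames(out) <- nm
  colnames(out) <- colnames(x)
  out
}

# Cox partial log-likelihood for one covariate without ties (Breslow =
# Efron in that case), maximized by golden-section search.
grid_cox_coef <- function(x, times, events) {
  logpl <- function(b) {
    s <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      s <- s + x[i] * b - log(sum(exp(x[risk] * b)))
    }
    s
  }
  stats::optimize(logpl, c(-8, 8), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)$maximum
}

# Empirical (Mann-Whitney) AUC of score for binary status.
empirical_auc <- function(score, status) {
  pos <- score[status == 1]
  neg <- score[status == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# BH step-up written independently of stats::p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
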