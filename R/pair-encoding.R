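#' Encode lncRNA pairs as a 0/1 relative-ordering matrix
#'
#' The central feature construction: every unordered pair of genes becomes a
#' binary feature whose value in a sample is 1 when the first gene of the
#' pair is expressed more highly than the second, and 0 otherwise (ties
#' score 0). Because only the within-sample ordering is used, the encoding
#' is invariant to any strictly monotone per-sample transform of
#' expression — no cross-sample normalization is required.
#'
#' Pairs are oriented canonically: gene ids are sorted lexicographically and
#' the pair is named `"A|B"` with A before B, so pair naming is
#' deterministic across runs and `"B|A"` never occurs.
#'
#' @param x genes-by-samples numeric matrix, or an [expr_set()] (in which
#'   case tumour samples only are encoded).
#' @param gene_ids genes to pair (at least 2); default all rows of `x`.
#' @return integer matrix with `choose(m, 2)` rows named `"A|B"` and one
#'   column per sample, values in `{0, 1}`.
#' @export
encode_pairs <- function(x, gene_ids = NULL) {
  if (inherits(x, "expr_set")) {
    x <- x$values[, samples_of(x, "tumour"), drop = FALSE]
  }
  gene_ids <- gene_ids %||% rownames(x)
  missing <- setdiff(gene_ids, rownames(x))
  if (length(missing)) stop_input("genes absent from matrix: ", missing[1])
  g <- sort(unique(gene_ids))
  if (length(g) < 2L) stop_input("need at least 2 genes to form pairs")
  idx <- utils::combn(length(g), 2L)
  a <- g[idx[1L, ]]
  b <- g[idx[2L, ]]
  pm <- (x[a, , drop = FALSE] > x[b, , drop = FALSE]) + 0L
  storage.mode(pm) <- "integer"
  rownames(pm) <- paste(a, b, sep = "|")
  pm
}

#' Per-pair frequency of the value 1
#' @param pm pair matrix from [encode_pairs()]
#' @return named numeric vector in \[0, 1\]
#' @export
pair_frequencies <- function(pm) rowMeans(pm)

#' Remove near-constant pairs (the 80 percent constancy filter)
#'
#' A pair whose majority value (either 0 or 1) occurs in more than
#' `high` of the samples carries almost no discriminative information and
#' is deleted. Equivalently a pair is kept iff
#' `low <= freq(1) <= high`; both boundaries are inclusive and
#' configurable.
#'
#' @param pm pair matrix
#' @param low,high inclusive bounds on the frequency of 1 (defaults 0.2
#'   and 0.8)
#' @return the filtered pair matrix, with the full frequency table in
#'   attribute `"freq_table"` (pair, one_freq, kept)
#' @export
filter_pairs <- function(pm, low = 0.2, high = 0.8) {
  if (nrow(pm) == 0L) stop_input("empty pair matrix")
  if (low > high) stop_input("low must be <= high")
  f <- rowMeans(pm)
  keep <- f >= low & f <= high
  out <- pm[keep, , drop = FALSE]
  attr(out, "freq_table") <- data.frame(pair = rownames(pm), one_freq = f,
                                        kept = keep, row.names = NULL)
  out
}
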