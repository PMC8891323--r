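#' Expression set container
#'
#' A minimal genes-by-samples expression container: a non-negative numeric
#' matrix plus a per-sample condition label (`normal` or `tumour`). Values
#' are linear scale on disk and in memory; `log2(x + 1)` is applied
#' internally wherever a log-scale statistic is computed.
#'
#' @param values numeric matrix, genes as rows, samples as columns; both
#'   dimensions must be named and free of duplicates.
#' @param condition character or factor of `"normal"`/`"tumour"`, named by
#'   sample id (or in column order).
#' @return An object of class `expr_set`: a list with elements `values`
#'   and `condition` (a named factor).
#' @export
expr_set <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("expression matrix must have gene and sample names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_input("duplicate gene id: ",
               rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stop_input("duplicate sample id: ",
               colnames(values)[duplicated(colnames(values))][1])
  }
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_input("negative expression at gene ", rownames(values)[bad[1]],
               ", sample ", colnames(values)[bad[2]])
  }
  cn <- names(condition) %||% colnames(values)
  condition <- factor(as.character(condition), levels = c("normal", "tumour"))
  names(condition) <- cn
  if (any(is.na(condition))) stop_input("condition must be normal/tumour")
  miss <- setdiff(colnames(values), names(condition))
  if (length(miss)) stop_input("samples without condition: ", miss[1])
  structure(list(values = values,
                 condition = condition[colnames(values)]),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d normal, %d tumour)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "normal"), sum(x$condition == "tumour")))
  invisible(x)
}

#' Sample ids of one condition
#' @param es an [expr_set()]
#' @param condition `"tumour"` or `"normal"`
#' @return character vector of sample ids
#' @export
samples_of <- function(es, condition = "tumour") {
  names(es$condition)[es$condition == condition]
}

#' Read an expression matrix and its sample-condition table
#'
#' The expression file is a TSV whose first column is `gene_id` and whose
#' remaining columns are sample ids; the companion file maps
#' `sample_id` to `condition` (`normal`/`tumour`).
#'
#' @param path expression TSV.
#' @param condition_path sample condition TSV.
#' @return an [expr_set()]
#' @export
read_expression <- function(path, condition_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") {
    stop_input("expression file must start with a gene_id column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric expression values")
  rownames(m) <- df$gene_id
  cond <- utils::read.delim(condition_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(cond))) {
    stop_input("condition file needs sample_id and condition columns")
  }
  expr_set(m, stats::setNames(cond$condition, cond$sample_id))
}

#' Read a clinical table
#'
#' Expects header
#' `sample_id os_days os_event age sex grade stage T N M` (`NA` allowed in
#' covariates only). Rows with non-positive follow-up are removed — samples
#' with zero follow-up days carry no survival information — and the number
#' removed is reported via `message()` and stored in the
#' `n_dropped_zero_followup` attribute.
#'
#' @param path clinical TSV.
#' @return data.frame with columns `sample_id, os_days, os_event, age, sex,
#'   grade, stage, t_stage, n_stage, m_stage`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "os_days", "os_event", "age", "sex", "grade",
            "stage", "T", "N", "M")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("clinical file missing column(s): ",
                               paste(miss, collapse = ", "))
  names(df)[match(c("T", "N", "M"), names(df))] <-
    c("t_stage", "n_stage", "m_stage")
  if (anyDuplicated(df$sample_id)) {
    stop_input("duplicate sample id in clinical table: ",
               df$sample_id[duplicated(df$sample_id)][1])
  }
  if (any(is.na(df$os_days)) || any(is.na(df$os_event))) {
    stop_input("os_days/os_event must not be missing")
  }
  if (!all(df$os_event %in% c(0, 1))) {
    bad <- which(!df$os_event %in% c(0, 1))[1]
    stop_input("non-binary os_event in row ", bad)
  }
  drop <- df$os_days <= 0
  if (any(drop)) {
    message(sum(drop), " sample(s) with zero follow-up days excluded")
  }
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_zero_followup") <- sum(drop)
  out
}

#' Read a gene symbol list (one symbol per line, `#` comments allowed)
#' @param path text file
#' @return character vector of unique symbols
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' Read a gene annotation table (`gene_id symbol biotype`)
#' @param path TSV file
#' @return data.frame with columns gene_id, symbol, biotype
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "biotype")
  if (!all(need %in% names(df))) {
    stop_input("annotation file needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop_input("duplicate gene id in annotation: ",
               df$gene_id[duplicated(df$gene_id)][1])
  }
  df[, need]
}

#' Read an immune-infiltration table (`sample_id cell_type method score`)
#' @param path TSV file
#' @return data.frame
#' @export
read_infiltration <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "method", "score")
  if (!all(need %in% names(df))) {
    stop_input("infiltration file needs columns ",
               paste(need, collapse = ", "))
  }
  key <- paste(df$sample_id, df$cell_type, df$method)
  if (anyDuplicated(key)) {
    stop_input("duplicate (sample, cell type, method) row: ",
               key[duplicated(key)][1])
  }
  df[, need]
}

#' Read a per-sample per-drug IC50 table (`sample_id drug ic50`)
#' @param path TSV file
#' @return data.frame
#' @export
read_ic50 <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "drug", "ic50")
  if (!all(need %in% names(df))) {
    stop_input("ic50 file needs columns ", paste(need, collapse = ", "))
  }
  key <- paste(df$sample_id, df$drug)
  if (anyDuplicated(key)) {
    stop_input("duplicate (sample, drug) row: ", key[duplicated(key)][1])
  }
  df[, need]
}

#' Partition annotated genes into lncRNA / immune mRNA / other
#'
#' lncRNAs are genes annotated with biotype `lncRNA`; immune mRNAs are
#' protein-coding genes whose symbol appears in the immune list
#' (ImmPort-style). Biotype takes precedence: a gene annotated as lncRNA is
#' never classified as immune mRNA even if its symbol is listed. The three
#' sets are disjoint and jointly exhaustive.
#'
#' @param annotation data.frame from [read_annotation()]
#' @param immune_symbols character vector of immune gene symbols
#' @return list with character elements `lncrna`, `immune`, `other`
#' @export
classify_genes <- function(annotation, immune_symbols) {
  if (length(immune_symbols) == 0L) stop_input("empty immune gene list")
  absent <- setdiff(immune_symbols, annotation$symbol)
  if (length(absent)) {
    warning(length(absent), " immune symbol(s) absent from annotation",
            call. = FALSE)
  }
  is_lnc <- annotation$biotype == "lncRNA"
  is_imm <- !is_lnc & annotation$biotype == "protein_coding" &
    annotation$symbol %in% immune_symbols
  list(lncrna = annotation$gene_id[is_lnc],
       immune = annotation$gene_id[is_imm],
       other  = annotation$gene_id[!is_lnc & !is_imm])
}
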