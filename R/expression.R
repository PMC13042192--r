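#' Expression matrix container
#'
#' Genes-in-rows expression values (assumed already on a correlation-ready
#' scale, e.g. log-normalized counts) with unique gene and sample
#' identifiers and an optional sample-to-condition map.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. All
#'   values must be finite.
#' @param gene_ids,sample_ids Character vectors of unique identifiers; taken
#'   from the dimnames of `values` when omitted.
#' @param condition_of Optional named character vector mapping every sample
#'   id to a condition label.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              condition_of = NULL) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite (drop or impute missing rows first)")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(condition_of)) {
    condition_of <- condition_of[sample_ids]
    if (anyNA(condition_of)) {
      stop("condition_of must cover every sample id")
    }
    names(condition_of) <- sample_ids
  }
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 values = values, condition_of = condition_of),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples%s\n",
              length(x$gene_ids), length(x$sample_ids),
              if (is.null(x$condition_of)) "" else
                sprintf(", %d conditions", length(unique(x$condition_of)))))
  invisible(x)
}

#' Restrict an expression matrix to a subset of samples
#' @param expr An [expression_matrix()].
#' @param sample_ids Character vector of sample ids to keep (order kept as
#'   given).
#' @return An [expression_matrix()].
#' @export
subset_samples <- function(expr, sample_ids) {
  missing <- setdiff(sample_ids, expr$sample_ids)
  if (length(missing)) {
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  }
  expression_matrix(expr$values[, sample_ids, drop = FALSE],
                    condition_of = expr$condition_of[sample_ids])
}

#' Attach condition labels to an expression matrix
#' @param expr An [expression_matrix()].
#' @param condition_of Named character vector, sample id -> condition.
#' @return An [expression_matrix()] with conditions set.
#' @export
set_conditions <- function(expr, condition_of) {
  expression_matrix(expr$values, condition_of = condition_of)
}
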