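#' Build the complete co-expression graph for a gene set
#'
#' Edge weights are absolute pairwise correlations of expression across
#' samples, `w_ij = |cor(x_i, x_j)|`, so both strong positive and strong
#' negative co-expression produce heavy edges ("guilt by association").
#' The result is the complete all-to-all graph over the gene-set members
#' present in the matrix; pairs with exactly zero correlation carry weight
#' zero and are treated as absent edges (a zero-conductance resistor is no
#' edge at all).
#'
#' Spearman correlation (average ranks for ties) is the rank-robust choice
#' recommended when few samples are available; Pearson is the default.
#'
#' @param expr An [expression_matrix()].
#' @param genes A [gene_set()] or character vector of gene ids; node order
#'   follows this order restricted to genes present in `expr`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [weighted_graph()].
#' @export
build_complete_graph <- function(expr, genes,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- if (inherits(genes, "gene_set")) genes$genes else as.character(genes)
  present <- ids[ids %in% expr$gene_ids]
  absent <- setdiff(ids, present)
  if (length(absent)) {
    nse_log("gene-set members absent from matrix: %s",
            paste(absent, collapse = ", "))
  }
  if (ncol(expr$values) < 3) stop("need at least 3 samples to correlate")
  x <- expr$values[present, , drop = FALSE]
  zero_var <- apply(x, 1L, stats::sd) == 0
  if (any(zero_var)) {
    warning("dropping zero-variance gene(s): ",
            paste(present[zero_var], collapse = ", "), call. = FALSE)
    present <- present[!zero_var]
    x <- x[!zero_var, , drop = FALSE]
  }
  if (length(present) < 2) {
    stop("fewer than 2 usable gene-set members present in the matrix")
  }
  w <- abs(stats::cor(t(x), method = method))
  diag(w) <- 0
  w <- (w + t(w)) / 2
  weighted_graph(present, w)
}

#' Gene-set members absent from an expression matrix
#'
#' Matching between gene-set and matrix identifiers is exact and
#' case-sensitive; this report makes silently missing members visible.
#'
#' @param expr An [expression_matrix()].
#' @param sets List of [gene_set()] objects (or a single one).
#' @return Data frame with columns `set_id`, `gene` (one row per missing
#'   member; zero rows when all are present).
#' @export
missing_genes_report <- function(expr, sets) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    absent <- setdiff(s$genes, expr$gene_ids)
    if (!length(absent)) return(NULL)
    data.frame(set_id = s$set_id, gene = absent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_id = character(), gene = character())
  }
  rownames(out) <- NULL
  out
}

#' Drop one random replicate per condition
#'
#' Emulates mild replicate subsampling: from every condition group, exactly
#' one randomly chosen sample is removed (e.g. 24 conditions x 4 replicates
#' -> 72 of 96 samples remain). Deterministic under `seed`.
#'
#' @param expr An [expression_matrix()] with condition labels.
#' @param seed Integer seed.
#' @return An [expression_matrix()] with the surviving samples, original
#'   order preserved.
#' @export
subsample_one_per_condition <- function(expr, seed) {
  if (is.null(expr$condition_of)) stop("expression matrix has no condition labels")
  groups <- split(expr$sample_ids, expr$condition_of[expr$sample_ids])
  singletons <- names(groups)[lengths(groups) < 2]
  if (length(singletons)) {
    stop("condition(s) with a single sample cannot lose a replicate: ",
         paste(singletons, collapse = ", "))
  }
  dropped <- withr::with_seed(seed, {
    vapply(groups, function(g) g[sample.int(length(g), 1L)], character(1))
  })
  keep <- setdiff(expr$sample_ids, dropped)
  subset_samples(expr, keep)
}

#' Keep a random fraction of samples
#'
#' Keeps `round(fraction * n_samples)` samples uniformly at random without
#' replacement (aggressive subsampling, e.g. 20% of samples). Deterministic
#' under `seed`.
#'
#' @param expr An [expression_matrix()].
#' @param fraction Fraction in (0, 1]; the resulting count must be >= 3.
#' @param seed Integer seed.
#' @return An [expression_matrix()], original sample order preserved.
#' @export
subsample_fraction <- function(expr, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]")
  }
  n <- length(expr$sample_ids)
  k <- round(fraction * n)
  if (k < 3) {
    stop("subsampling to ", k, " samples (< 3) cannot support correlations")
  }
  if (k == n) return(expr)
  keep_idx <- withr::with_seed(seed, sort(sample.int(n, k)))
  subset_samples(expr, expr$sample_ids[keep_idx])
}
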