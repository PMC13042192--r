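check_same_nodes <- function(a, b) {
  a <- as_weighted_graph(a)
  b <- as_weighted_graph(b)
  if (!identical(a$nodes, b$nodes)) {
    stop("graphs must share an identical node set in identical order")
  }
  list(a = a, b = b)
}

#' Normalized Hamming distance between two skeletons
#'
#' Both adjacency matrices are binarized (edge present iff weight > 0) and
#' the fraction of node pairs whose presence/absence differs is returned:
#' `sum_{i<j} |A_ij - B_ij| / (N(N-1)/2)`. 0 means identical edge sets; 1
#' means complementary. Unlike the Jaccard index, the normalization by all
#' node pairs makes this metric insensitive to the average sparsity level.
#'
#' @param a,b [skeleton()]s or [weighted_graph()]s on the same ordered node
#'   set.
#' @return Scalar in `[0, 1]`.
#' @export
hamming_distance <- function(a, b) {
  g <- check_same_nodes(a, b)
  A <- g$a$weights > 0
  B <- g$b$weights > 0
  n <- length(g$a$nodes)
  ut <- upper.tri(A)
  sum(A[ut] != B[ut]) / (n * (n - 1) / 2)
}

#' Jaccard index between two skeletons' edge sets
#'
#' `|E_A intersect E_B| / |E_A union E_B|`: 1 when the edge sets coincide,
#' 0 when disjoint. Two empty edge sets are defined as identical (index 1);
#' the raw ratio is 0/0 there. Sensitive to sparsity: for very sparse
#' graphs a small change in the intersection moves the index a lot.
#'
#' @inheritParams hamming_distance
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  g <- check_same_nodes(a, b)
  A <- g$a$weights > 0
  B <- g$b$weights > 0
  ut <- upper.tri(A)
  union <- sum(A[ut] | B[ut])
  if (union == 0) return(1)
  sum(A[ut] & B[ut]) / union
}

#' Spectral distance between two skeletons
#'
#' Absolute difference of algebraic connectivities,
#' `|lambda_2(A) - lambda_2(B)|` on the unnormalized Laplacians: a global
#' measure of how differently cohesive the two graphs are, blind to which
#' particular edges differ. A fragmented graph contributes `lambda_2 = 0`.
#'
#' @param a,b [skeleton()]s or [weighted_graph()]s (node sets need not
#'   match; only connectivities are compared).
#' @return Non-negative scalar.
#' @export
spectral_distance <- function(a, b) {
  abs(fiedler_value(as_weighted_graph(a)) - fiedler_value(as_weighted_graph(b)))
}

#' Mean-center each gene within each condition
#'
#' Subtracts, per gene, its mean across the samples of every condition
#' group. Applied before label permutation so that between-condition mean
#' shifts (differential expression) cannot masquerade as co-expression in
#' the permuted data.
#'
#' @param expr An [expression_matrix()] with condition labels.
#' @return An [expression_matrix()] of centered values.
#' @export
center_within_condition <- function(expr) {
  if (is.null(expr$condition_of)) stop("expression matrix has no condition labels")
  vals <- expr$values
  for (cond in unique(expr$condition_of)) {
    cols <- names(expr$condition_of)[expr$condition_of == cond]
    vals[, cols] <- vals[, cols, drop = FALSE] - rowMeans(vals[, cols, drop = FALSE])
  }
  expression_matrix(vals, condition_of = expr$condition_of)
}

#' Spectrally-matched permutation null ensemble
#'
#' Builds `n` random graphs matched to a reference skeleton's density and
#' approximate spectral profile under the no-condition-effect null. Per
#' replicate: (1) each gene is mean-centered within each condition; (2) the
#' pooled samples are randomly reassigned to pseudo-conditions preserving
#' the original group sizes; (3) the complete |correlation| graph is
#' rebuilt from the pseudo-condition-A samples; (4) it is probabilistically
#' sparsified (importance-proportional sampling) down to the reference
#' skeleton's edge count. All randomness derives from `seed`.
#'
#' When `reference_b` is supplied, each permutation additionally yields a
#' second graph built from the complementary pseudo-condition-B samples and
#' sparsified to `reference_b`'s edge count (`graphs_b`). Pairing each
#' `graphs[[r]]` with `graphs_b[[r]]` gives null statistics whose sampling
#' structure mirrors the observed A-vs-B comparison (both sides resampled,
#' per-side density preserved).
#'
#' @param expr_a,expr_b [expression_matrix()]s for the two conditions, with
#'   identical gene rows.
#' @param reference The observed condition-A [skeleton()] whose edge count
#'   (and node set) the nulls match.
#' @param n Number of null graphs.
#' @param seed Integer master seed.
#' @param method Correlation method used when rebuilding the graphs.
#' @param reference_b Optional condition-B [skeleton()]; when given, paired
#'   pseudo-B graphs matched to its edge count are returned as `graphs_b`.
#' @return A `null_ensemble`: list with `graphs`, `n`, `seed`,
#'   `reference_edges` (and `graphs_b` when `reference_b` is given).
#' @export
build_null_ensemble <- function(expr_a, expr_b, reference, n, seed,
                                method = c("pearson", "spearman"),
                                reference_b = NULL) {
  method <- match.arg(method)
  if (!identical(expr_a$gene_ids, expr_b$gene_ids)) {
    stop("both expression matrices must share identical gene rows")
  }
  if (n < 1) stop("need at least one permutation")
  ref_graph <- as_weighted_graph(reference)
  m_ref <- n_edges(ref_graph)
  na <- length(expr_a$sample_ids)
  nb <- length(expr_b$sample_ids)
  pooled_vals <- cbind(expr_a$values, expr_b$values)
  colnames(pooled_vals) <- make.unique(c(expr_a$sample_ids, expr_b$sample_ids))
  cond <- stats::setNames(rep(c("A", "B"), c(na, nb)), colnames(pooled_vals))
  pooled <- center_within_condition(
    expression_matrix(pooled_vals, condition_of = cond))
  make_graph_from <- function(ids, target, draw_seed) {
    g <- build_complete_graph(subset_samples(pooled, ids), ref_graph$nodes,
                              method)
    if (!identical(g$nodes, ref_graph$nodes)) {
      stop("null replicate lost gene(s); cannot match the reference node set")
    }
    probabilistic_sparsify(g, target, seed = draw_seed)
  }
  graphs <- vector("list", n)
  graphs_b <- if (is.null(reference_b)) NULL else vector("list", n)
  m_ref_b <- if (is.null(reference_b)) NULL else
    n_edges(as_weighted_graph(reference_b))
  for (r in seq_len(n)) {
    perm <- withr::with_seed(derive_seed(seed, 101L, r), {
      sample.int(na + nb)
    })
    graphs[[r]] <- make_graph_from(pooled$sample_ids[perm[seq_len(na)]],
                                   m_ref, derive_seed(seed, 202L, r))
    if (!is.null(reference_b)) {
      graphs_b[[r]] <- make_graph_from(
        pooled$sample_ids[perm[seq(na + 1L, na + nb)]],
        m_ref_b, derive_seed(seed, 203L, r))
    }
  }
  structure(list(graphs = graphs, graphs_b = graphs_b, n = n, seed = seed,
                 reference_edges = m_ref, reference_edges_b = m_ref_b),
            class = "null_ensemble")
}

#' Empirical permutation p-value (add-one convention)
#'
#' `p = (1 + #{null in tail, ties included}) / (1 + n_null)`. The add-one
#' convention counts the observed statistic as one more draw from the null,
#' so p is never 0 and the test is valid at finite permutation counts.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics (non-empty).
#' @param tail `"high"` (null >= observed) or `"low"` (null <= observed).
#' @return Scalar in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_values, tail = c("high", "low")) {
  tail <- match.arg(tail)
  if (!length(null_values)) stop("empty null distribution")
  r <- if (tail == "high") sum(null_values >= observed)
       else sum(null_values <= observed)
  (1 + r) / (1 + length(null_values))
}

comparison_result <- function(metric, observed, null_values, metadata = list()) {
  structure(list(metric = metric, observed = observed,
                 null_values = null_values,
                 p_high = empirical_pvalue(observed, null_values, "high"),
                 p_low = empirical_pvalue(observed, null_values, "low"),
                 n_null = length(null_values), metadata = metadata),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: observed=%.4g, p_high=%.4g, p_low=%.4g (n_null=%d)\n",
              x$metric, x$observed, x$p_high, x$p_low, x$n_null))
  invisible(x)
}

#' Compare two conditions over one gene set
#'
#' Extracts a deterministic skeleton for each condition, computes the
#' requested similarity metrics between them, and situates each against a
#' spectrally-matched permutation null: per permutation, the condition
#' labels are reassigned (after within-condition mean-centering) and a
#' pseudo-A and a pseudo-B graph are probabilistically sparsified to the
#' respective observed skeleton densities; the null statistic is the metric
#' between the two members of each pair. Both sides of the null thus vary
#' the way both observed skeletons do, which keeps the high-tail
#' (difference) test calibrated. For each metric both tail p-values are
#' reported;
#' `p_difference` is the tail indicating more difference than chance (high
#' for Hamming and spectral distance, low for Jaccard) and
#' `p_conservation` the opposite tail.
#'
#' @param expr_a,expr_b [expression_matrix()]s for conditions A and B with
#'   identical gene rows.
#' @param genes A [gene_set()] or character vector.
#' @param n_null Number of permutations (default 99).
#' @param seed Integer master seed.
#' @param method Correlation method.
#' @param metrics Subset of `c("hamming", "jaccard", "spectral")`.
#' @param stride MSE checkpoint stride for skeleton extraction.
#' @return List of class `condition_comparison`: per-metric
#'   `comparison_result`s (with `p_difference`/`p_conservation` added),
#'   plus `skeleton_a`, `skeleton_b`.
#' @export
compare_conditions <- function(expr_a, expr_b, genes, n_null = 99L, seed = 1L,
                               method = c("pearson", "spearman"),
                               metrics = c("hamming", "jaccard", "spectral"),
                               stride = 1L) {
  method <- match.arg(method)
  metrics <- match.arg(metrics, several.ok = TRUE)
  skel_a <- extract_skeleton(expr_a, genes, method, stride)$skeleton
  skel_b <- extract_skeleton(expr_b, genes, method, stride)$skeleton
  if (!identical(skel_a$graph$nodes, skel_b$graph$nodes)) {
    stop("conditions yield different usable gene sets; ",
         "restrict the gene set to genes usable in both")
  }
  ens <- build_null_ensemble(expr_a, expr_b, skel_a, n_null, seed, method,
                             reference_b = skel_b)
  metric_fun <- list(hamming = hamming_distance, jaccard = jaccard_index,
                     spectral = spectral_distance)
  difference_tail <- c(hamming = "high", jaccard = "low", spectral = "high")
  out <- list()
  for (mname in metrics) {
    f <- metric_fun[[mname]]
    observed <- f(skel_a, skel_b)
    null_values <- vapply(seq_len(n_null),
                          function(r) f(ens$graphs[[r]], ens$graphs_b[[r]]),
                          numeric(1))
    res <- comparison_result(mname, observed, null_values,
                             metadata = list(set_id = skel_a$set_id,
                                             n_null = n_null, seed = seed))
    tail <- difference_tail[[mname]]
    res$p_difference <- if (tail == "high") res$p_high else res$p_low
    res$p_conservation <- if (tail == "high") res$p_low else res$p_high
    out[[mname]] <- res
  }
  structure(list(results = out, skeleton_a = skel_a, skeleton_b = skel_b,
                 n_null = n_null, seed = seed),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> set %s, n_null=%d\n",
              x$skeleton_a$set_id %||% "?", x$n_null))
  for (r in x$results) {
    cat(sprintf("  %-8s observed=%.4g p_difference=%.4g\n",
                r$metric, r$observed, r$p_difference))
  }
  invisible(x)
}
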