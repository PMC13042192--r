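#' In-sample MSE of predicting one gene from its graph neighbors
#'
#' Ordinary least squares with intercept, regressing the gene's expression
#' on the expression of its current neighbors in `graph`; returns the mean
#' of squared residuals (divide-by-n). When the design is underdetermined
#' (neighbors >= samples - 1) the rank-revealing QR fit attains the minimal
#' residual sum of squares, so the MSE is well defined for all inputs and
#' is 0 in the saturated regime. A gene with no neighbors is fitted by its
#' intercept alone, giving the population variance (divide-by-n) of the
#' gene.
#'
#' @param expr An [expression_matrix()] covering the graph's nodes.
#' @param graph A [weighted_graph()].
#' @param gene Gene id, must be a node of `graph`.
#' @return Non-negative scalar MSE.
#' @export
gene_mse <- function(expr, graph, gene) {
  if (!gene %in% graph$nodes) stop("gene '", gene, "' is not in the graph")
  if (!gene %in% expr$gene_ids) stop("gene '", gene, "' is not in the matrix")
  nb <- graph$nodes[graph$weights[gene, ] > 0]
  y <- expr$values[gene, ]
  n <- length(y)
  if (!length(nb)) return(sum((y - mean(y))^2) / n)
  X <- cbind(1, t(expr$values[nb, , drop = FALSE]))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2) / n
}

# MSE for every gene in the graph; vectorized driver used by the trajectory.
all_gene_mse <- function(expr, graph) {
  vapply(graph$nodes, function(g) gene_mse(expr, graph, g), numeric(1))
}

#' Median-MSE curve along a sparsification trace
#'
#' Replays the removal order and, at step 0 and every `stride`-th removal
#' (plus the final traced step), records the median across genes of the
#' per-gene neighbor-regression MSE. Only the two endpoint genes of a
#' removed edge change their neighborhoods, so per-gene MSEs are cached and
#' updated incrementally; the curve is exactly what a full recomputation
#' would produce.
#'
#' @param expr An [expression_matrix()] covering the trace's nodes.
#' @param trace A [greedy_sparsify()] trace.
#' @param stride Checkpoint spacing in removal steps (default 1 = every
#'   removal, per-step resolution).
#' @return An `mse_curve`: data frame (`step`, `fraction_removed`,
#'   `median_mse`) with attributes `per_gene` (genes x checkpoints matrix),
#'   `fragmentation_step`, `n_edges0`.
#' @export
mse_trajectory <- function(expr, trace, stride = 1L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be a positive integer")
  g <- attr(trace, "initial_graph")
  missing <- setdiff(g$nodes, expr$gene_ids)
  if (length(missing)) {
    stop("expression matrix lacks graph node(s): ",
         paste(missing, collapse = ", "))
  }
  m0 <- attr(trace, "n_edges0")
  at_stride <- seq_len(nrow(trace))
  at_stride <- at_stride[at_stride %% stride == 0L]
  steps <- unique(c(0L, at_stride, nrow(trace)))
  mse <- all_gene_mse(expr, g)
  per_gene <- matrix(NA_real_, length(g$nodes), length(steps),
                     dimnames = list(g$nodes, steps))
  rows <- vector("list", length(steps))
  ck <- 1L
  for (s in seq(0L, nrow(trace))) {
    if (s > 0L) {
      g <- drop_edge(g, trace$i[s], trace$j[s])
      for (gene in c(trace$from[s], trace$to[s])) {
        mse[[gene]] <- gene_mse(expr, g, gene)
      }
    }
    if (s == steps[ck]) {
      per_gene[, ck] <- mse
      rows[[ck]] <- data.frame(step = s, fraction_removed = s / m0,
                               median_mse = stats::median(mse))
      ck <- ck + 1L
      if (ck > length(steps)) break
    }
  }
  curve <- do.call(rbind, rows)
  structure(curve, per_gene = per_gene,
            fragmentation_step = attr(trace, "fragmentation_step"),
            n_edges0 = m0,
            class = c("mse_curve", "data.frame"))
}

#' Locate the elbow of a median-MSE curve
#'
#' Fits a continuous two-segment (broken-stick) least-squares line to the
#' checkpoints strictly before the fragmentation step: for each candidate
#' junction checkpoint k (both segments at least 3 points, sharing the
#' junction), the model `y = a + b1 (x - x_k)^- + b2 (x - x_k)^+` is fitted
#' and the junction minimizing the total SSE wins (ties: the smaller k,
#' i.e. less sparsification). The two fitted lines meet at the junction by
#' construction; that junction checkpoint is the elbow.
#'
#' An unconstrained variant (two independent lines whose crossing defines
#' the elbow) is simpler but degenerates when the best-fit lines intersect
#' outside the fitted range, which happens routinely on curves with a
#' saturated (flat-zero) start; the constrained fit has no such failure
#' mode.
#'
#' @param curve An [mse_trajectory()] result (>= 6 usable checkpoints; with
#'   fewer, the last pre-fragmentation step is returned with a warning).
#' @return Integer removal-step index of the elbow.
#' @export
find_elbow <- function(curve) {
  frag <- attr(curve, "fragmentation_step")
  keep <- if (is.na(frag %||% NA)) rep(TRUE, nrow(curve)) else curve$step < frag
  pts <- curve[keep, , drop = FALSE]
  m <- nrow(pts)
  if (m < 6) {
    warning("fewer than 6 pre-fragmentation checkpoints; ",
            "falling back to the last safe step", call. = FALSE)
    return(as.integer(max(pts$step)))
  }
  x <- pts$fraction_removed
  y <- pts$median_mse
  best <- NULL
  for (k in 3:(m - 2)) {
    X <- cbind(1, pmin(x - x[k], 0), pmax(x - x[k], 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(k = k, sse = sse)
    }
  }
  as.integer(pts$step[best$k])
}

#' Network skeleton
#'
#' The sparsified, still-connected co-expression graph retained at the
#' elbow of the median-MSE curve, with surviving edges keeping their
#' original weights.
#'
#' @param graph A connected [weighted_graph()] with positive spectral gap.
#' @param elbow_step Removal step at which sparsification stopped.
#' @param n_edges0 Edge count of the originating complete graph.
#' @param set_id,method Provenance strings.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(graph, elbow_step = 0L, n_edges0 = n_edges(graph),
                     set_id = NA_character_, method = NA_character_) {
  if (!is_connected(graph)) stop("a skeleton must be a single component")
  gap <- fiedler_value(graph)
  if (n_nodes(graph) >= 2 && gap <= 0) {
    stop("a skeleton must have a positive spectral gap")
  }
  structure(list(graph = graph,
                 elbow_step = as.integer(elbow_step),
                 n_edges0 = as.integer(n_edges0),
                 sparsification_fraction = elbow_step / max(1L, n_edges0),
                 spectral_gap = gap,
                 set_id = set_id, method = method),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf(paste0("<skeleton> %s: %d nodes, %d/%d edges kept ",
                     "(%.1f%% removed), gap=%.4g\n"),
              x$set_id %||% "?", n_nodes(x$graph), n_edges(x$graph),
              x$n_edges0, 100 * x$sparsification_fraction, x$spectral_gap))
  invisible(x)
}

#' End-to-end skeleton extraction
#'
#' The full pipeline for one gene set: build the complete |correlation|
#' graph, greedily remove least-important edges until just before
#' fragmentation, trace the median neighbor-regression MSE, locate its
#' elbow, and return the graph as it stood at the elbow step. The skeleton
#' is guaranteed connected with a positive spectral gap; a star-like graph
#' where any removal fragments yields the complete graph back (0% removed).
#'
#' @param expr An [expression_matrix()].
#' @param genes A [gene_set()] or character vector of gene ids.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param stride MSE checkpoint stride (default 1, every removal).
#' @return List with elements `skeleton`, `trace`, and `curve`.
#' @export
extract_skeleton <- function(expr, genes,
                             method = c("pearson", "spearman"),
                             stride = 1L) {
  method <- match.arg(method)
  set_id <- if (inherits(genes, "gene_set")) genes$set_id else NA_character_
  complete <- build_complete_graph(expr, genes, method)
  if (!is_connected(complete)) {
    stop("complete co-expression graph is disconnected ",
         "(exact zero correlations isolate part of the gene set)")
  }
  trace <- greedy_sparsify(complete, stop = "fragmentation")
  if (nrow(trace) == 0) {
    skel <- skeleton(complete, 0L, n_edges(complete), set_id, method)
    curve <- mse_trajectory(expr, trace, stride = 1L)
    return(list(skeleton = skel, trace = trace, curve = curve))
  }
  curve <- mse_trajectory(expr, trace, stride = stride)
  elbow <- find_elbow(curve)
  skel_graph <- graph_at_step(trace, elbow)
  nse_log("extract[%s]: %d edges, elbow step %d (%.1f%%), Foster residual %.2e",
          set_id, attr(trace, "n_edges0"), elbow,
          100 * elbow / attr(trace, "n_edges0"), foster_residual(complete))
  list(skeleton = skeleton(skel_graph, elbow, attr(trace, "n_edges0"),
                           set_id, method),
       trace = trace, curve = curve)
}
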