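#' Deterministic greedy spectral sparsification
#'
#' Iteratively removes the edge with the lowest current importance
#' `I_ij = w_ij * R_ij`, recomputing every effective resistance (and hence
#' every importance) on the reduced graph before each selection. Removal
#' raises the effective resistance of the surviving alternatives, so the
#' ranking genuinely changes step to step; the full recomputation is the
#' reference semantics (O(steps x N^3), fine for gene sets up to a few
#' hundred nodes). Equal minimal importances are broken by the smallest
#' `(i, j)` pair in node order, making the procedure fully deterministic.
#'
#' With `stop = "fragmentation"` the trace halts at the last step before
#' the graph would split into two components and records that would-be
#' step; with `stop = "all_edges"` removal continues to the empty graph
#' and the first fragmenting step is recorded.
#'
#' @param graph A connected [weighted_graph()] with at least one edge.
#' @param stop `"fragmentation"` (default) or `"all_edges"`.
#' @return A `sparsification_trace`: data frame with one row per removal
#'   (`step`, `i`, `j`, `from`, `to`, `weight`, `importance`, `lambda2`,
#'   `n_components`, `fraction_removed`) carrying attributes
#'   `initial_graph`, `fragmentation_step` (NA if never observed),
#'   `n_edges0`, and `stop`.
#' @export
greedy_sparsify <- function(graph, stop = c("fragmentation", "all_edges")) {
  stop <- match.arg(stop)
  if (!is_connected(graph)) {
    base::stop("greedy sparsification requires a connected input graph")
  }
  m0 <- n_edges(graph)
  if (m0 < 1) base::stop("graph has no edges")
  records <- vector("list", m0)
  current <- graph
  step <- 0L
  fragmentation_step <- NA_integer_
  while (n_edges(current) > 0) {
    tab <- edge_importance(current)
    # finite within components; canonical order makes which.min the tie-break
    pick <- tab[which.min(tab$importance), ]
    after <- drop_edge(current, pick$i, pick$j)
    ncomp <- graph_components(after)$n_components
    fragments <- ncomp > graph_components(current)$n_components
    if (fragments && is.na(fragmentation_step)) {
      fragmentation_step <- step + 1L
    }
    if (stop == "fragmentation" && fragments) break
    step <- step + 1L
    records[[step]] <- data.frame(
      step = step, i = pick$i, j = pick$j, from = pick$from, to = pick$to,
      weight = pick$weight, importance = pick$importance,
      lambda2 = fiedler_value(after), n_components = ncomp,
      fraction_removed = step / m0, stringsAsFactors = FALSE)
    current <- after
  }
  trace <- do.call(rbind, records[seq_len(step)])
  if (is.null(trace)) {
    trace <- data.frame(step = integer(), i = integer(), j = integer(),
                        from = character(), to = character(),
                        weight = numeric(), importance = numeric(),
                        lambda2 = numeric(), n_components = integer(),
                        fraction_removed = numeric())
  }
  structure(trace,
            initial_graph = graph, fragmentation_step = fragmentation_step,
            n_edges0 = m0, stop = stop,
            class = c("sparsification_trace", "data.frame"))
}

#' First fragmenting removal step of a trace
#' @param trace A `sparsification_trace`.
#' @return Integer step index, or `NA` if fragmentation was never reached.
#' @export
fragmentation_step <- function(trace) attr(trace, "fragmentation_step")

#' Reconstruct the graph after the first `step` removals of a trace
#' @param trace A `sparsification_trace`.
#' @param step Number of removals to apply (0 = initial graph).
#' @return A [weighted_graph()].
#' @export
graph_at_step <- function(trace, step) {
  g <- attr(trace, "initial_graph")
  if (step < 0 || step > nrow(trace)) {
    stop("step must lie in [0, ", nrow(trace), "]")
  }
  if (step > 0) {
    idx <- seq_len(step)
    g$weights[cbind(trace$i[idx], trace$j[idx])] <- 0
    g$weights[cbind(trace$j[idx], trace$i[idx])] <- 0
  }
  g
}

#' Probabilistic (importance-sampled) sparsification
#'
#' The Spielman-Srivastava-style randomized counterpart used for
#' spectrally-matched null graphs: edge importances are computed once on
#' the input graph and normalized to probabilities
#' `p_ij = I_ij / sum(I)`; distinct edges are then drawn sequentially with
#' probability proportional to importance among the not-yet-drawn edges
#' until exactly `target_edge_count` are kept. Kept edges retain their
#' original weights. Because sampling favours high-importance edges, the
#' result approximately preserves the Laplacian spectrum at the target
#' density while varying which edges survive.
#'
#' @param graph A [weighted_graph()] with at least one edge.
#' @param target_edge_count Number of edges to keep, in `[1, n_edges]`.
#' @param seed Integer seed (the draw is random by design).
#' @return A [weighted_graph()] with exactly `target_edge_count` edges.
#' @export
probabilistic_sparsify <- function(graph, target_edge_count, seed) {
  m <- n_edges(graph)
  if (m < 1) stop("graph has no edges")
  if (target_edge_count < 1 || target_edge_count > m) {
    stop("target_edge_count must lie in [1, ", m, "]")
  }
  if (target_edge_count == m) return(graph)
  tab <- edge_importance(graph)
  kept <- withr::with_seed(seed, {
    sample.int(m, target_edge_count, replace = FALSE, prob = tab$importance)
  })
  w <- matrix(0, n_nodes(graph), n_nodes(graph))
  ki <- tab$i[kept]; kj <- tab$j[kept]
  w[cbind(ki, kj)] <- tab$weight[kept]
  w[cbind(kj, ki)] <- tab$weight[kept]
  weighted_graph(graph$nodes, w)
}

#' Threshold sparsification (diagnostic baseline)
#'
#' The conventional alternative to importance-based removal: delete every
#' edge whose weight falls below `threshold`. Used only to contrast
#' fragmentation behaviour with the greedy method (thresholding severs
#' weak bridges early and fragments at lower removal fractions).
#'
#' @param graph A [weighted_graph()].
#' @param threshold Weight cutoff; edges with `w < threshold` are removed.
#' @return A [weighted_graph()].
#' @export
threshold_sparsify <- function(graph, threshold) {
  w <- graph$weights
  w[w < threshold] <- 0
  weighted_graph(graph$nodes, w)
}

#' Fragmentation point of a threshold sweep
#'
#' Sweeps weight thresholds (default 0 to 1 by 0.01) and reports, for each,
#' the fraction of edges removed and the resulting component count; also
#' returns the smallest removal fraction at which the graph fragments.
#'
#' @param graph A connected [weighted_graph()].
#' @param thresholds Numeric vector of cutoffs to sweep.
#' @return List with `sweep` (data frame: `threshold`, `fraction_removed`,
#'   `n_components`, `spectral_gap`) and `fragmentation_fraction` (NA if the
#'   sweep never fragments the graph).
#' @export
threshold_sweep <- function(graph, thresholds = seq(0, 1, by = 0.01)) {
  m0 <- n_edges(graph)
  rows <- lapply(thresholds, function(th) {
    g <- threshold_sparsify(graph, th)
    data.frame(threshold = th,
               fraction_removed = (m0 - n_edges(g)) / m0,
               n_components = graph_components(g)$n_components,
               spectral_gap = fiedler_value(g))
  })
  sweep <- do.call(rbind, rows)
  frag <- sweep$fraction_removed[sweep$n_components > 1]
  list(sweep = sweep,
       fragmentation_fraction = if (length(frag)) min(frag) else NA_real_)
}
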