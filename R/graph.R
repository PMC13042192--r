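#' Weighted co-expression graph
#'
#' A `weighted_graph` is the package's central container: an undirected graph
#' over an ordered set of gene identifiers with a symmetric, non-negative
#' weight matrix and a zero diagonal. When built from expression data
#' (see [build_complete_graph()]) the weights are absolute correlations, so
#' `0 <= w_ij <= 1`. Pairs with weight exactly zero are treated as absent
#' edges throughout the package.
#'
#' @param nodes Character vector of unique node (gene) identifiers; defines
#'   the node order used everywhere downstream (tie-breaking, output order).
#' @param weights Numeric symmetric matrix, `length(nodes)` on each side,
#'   non-negative with zero diagonal. Dimnames are set from `nodes`.
#' @return An object of class `weighted_graph` with elements `nodes` and
#'   `weights`.
#' @examples
#' g <- weighted_graph(c("a", "b", "c"),
#'                     matrix(c(0, 1, 0.5, 1, 0, 0, 0.5, 0, 0), 3, 3))
#' graph_degrees(g)
#' @export
weighted_graph <- function(nodes, weights) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  n <- length(nodes)
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n) {
    stop("`weights` must be a numeric ", n, "x", n, " matrix")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("weights must be finite and non-missing")
  }
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 0,
                        check.attributes = FALSE))) {
    stop("weight matrix must be exactly symmetric")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("diagonal of the weight matrix must be zero")
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  el <- graph_edges(x)
  cat(sprintf("<weighted_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(el)))
  invisible(x)
}

#' Number of nodes in a graph
#' @param graph A `weighted_graph`.
#' @return Integer node count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' Weighted node degrees
#' @param graph A `weighted_graph`.
#' @return Named numeric vector `d_i = sum_j w_ij`.
#' @export
graph_degrees <- function(graph) rowSums(graph$weights)

#' Edge list of a weighted graph
#'
#' Enumerates unordered pairs with positive weight, ordered by node index
#' `(i, j)` with `i < j` (the package's canonical edge order, also used as
#' the deterministic tie-break in sparsification).
#'
#' @param graph A `weighted_graph`.
#' @return Data frame with integer columns `i`, `j` (node indices), character
#'   `from`, `to` (node ids) and numeric `weight`.
#' @export
graph_edges <- function(graph) {
  w <- graph$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  # which() on upper.tri returns column-major order: ordered by j then i.
  # Reorder to (i, j) lexicographic in node order.
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  data.frame(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]),
             from = graph$nodes[idx[, 1L]], to = graph$nodes[idx[, 2L]],
             weight = w[idx], stringsAsFactors = FALSE)
}

#' Number of edges in a graph
#' @param graph A `weighted_graph`.
#' @return Integer count of unordered pairs with positive weight.
#' @export
n_edges <- function(graph) {
  w <- graph$weights
  sum(w[upper.tri(w)] > 0)
}

#' Remove one edge (set its weight to zero)
#' @param graph A `weighted_graph`.
#' @param i,j Node indices of the edge to remove.
#' @return A new `weighted_graph` without the edge.
#' @export
drop_edge <- function(graph, i, j) {
  if (graph$weights[i, j] <= 0) stop("no edge between nodes ", i, " and ", j)
  graph$weights[i, j] <- 0
  graph$weights[j, i] <- 0
  graph
}

#' Connected components by edge traversal
#'
#' Component structure is always determined combinatorially (breadth-first
#' search over positive-weight edges), never from near-zero eigenvalues,
#' so the count is exact.
#'
#' @param graph A `weighted_graph`.
#' @return List with `membership` (integer vector, components numbered by
#'   first-seen node) and `n_components`.
#' @export
graph_components <- function(graph) {
  w <- graph$weights
  n <- nrow(w)
  membership <- integer(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (membership[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    membership[start] <- comp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(w[v, ] > 0 & membership == 0L)
      membership[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  list(membership = membership, n_components = comp)
}

#' Is the graph a single connected component?
#' @param graph A `weighted_graph`.
#' @return Logical.
#' @export
is_connected <- function(graph) graph_components(graph)$n_components == 1L

#' Coerce to a weighted graph
#'
#' Accepts a `weighted_graph` (returned as-is) or a [skeleton()] (its graph
#' is extracted), so comparison metrics work on either.
#'
#' @param x Object to coerce.
#' @return A `weighted_graph`.
#' @export
as_weighted_graph <- function(x) UseMethod("as_weighted_graph")

#' @export
as_weighted_graph.weighted_graph <- function(x) x

#' @export
as_weighted_graph.skeleton <- function(x) x$graph

#' @export
as_weighted_graph.default <- function(x) {
  stop("cannot interpret object of class '", class(x)[1], "' as a graph")
}
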