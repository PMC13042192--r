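#' Unnormalized graph Laplacian
#'
#' `L = D - W` with `D` the diagonal matrix of weighted degrees. `L` is
#' positive semi-definite; the multiplicity of its zero eigenvalue equals
#' the number of connected components, and its second-smallest eigenvalue
#' (the Fiedler value) measures algebraic connectivity.
#'
#' @param graph A [weighted_graph()].
#' @return Symmetric numeric matrix with zero row sums.
#' @export
laplacian <- function(graph) {
  w <- graph$weights
  diag(rowSums(w)) - w
}

# Relative tolerance for calling an eigenvalue zero. Component counting never
# relies on this (it is combinatorial); the tolerance only guards the
# pseudoinverse and diagnostic multiplicity checks.
zero_eig_tol <- function(eigenvalues) 1e-9 * max(1, max(eigenvalues))

#' Moore-Penrose pseudoinverse of a graph Laplacian
#'
#' Computed by eigendecomposition of the symmetric Laplacian with eigenvalues
#' below `1e-9 * max(1, lambda_max)` clipped to zero. For a disconnected
#' graph the Laplacian is block diagonal, so the pseudoinverse is the direct
#' sum of the per-component pseudoinverses: within-component effective
#' resistances read off the global pseudoinverse are still exact.
#'
#' @param L Symmetric Laplacian matrix.
#' @return List with `pinv` (matrix) and `eigenvalues` (ascending).
#' @export
laplacian_pinv <- function(L) {
  es <- eigen(L, symmetric = TRUE)
  lambda <- rev(es$values)            # ascending
  tol <- zero_eig_tol(pmax(es$values, 0))
  inv <- ifelse(es$values > tol, 1 / es$values, 0)
  pinv <- es$vectors %*% (inv * t(es$vectors))
  list(pinv = (pinv + t(pinv)) / 2, eigenvalues = lambda)
}

#' Effective resistance between all node pairs
#'
#' The two-point resistance when every edge is a resistor of conductance
#' `w_ij`: `R_ij = (e_i - e_j)' L^+ (e_i - e_j)`. Pairs lying in different
#' connected components are assigned `Inf` (the pseudoinverse formula does
#' not apply across components; electrically there is no path).
#'
#' @param graph A [weighted_graph()].
#' @return Symmetric numeric matrix of resistances with zero diagonal;
#'   `Inf` across components.
#' @export
resistance_matrix <- function(graph) {
  P <- laplacian_pinv(laplacian(graph))$pinv
  d <- diag(P)
  R <- outer(d, d, "+") - 2 * P
  diag(R) <- 0
  comp <- graph_components(graph)$membership
  cross <- outer(comp, comp, "!=")
  R[cross] <- Inf
  dimnames(R) <- dimnames(graph$weights)
  R
}

#' Effective resistance of each edge
#'
#' @param graph A [weighted_graph()].
#' @return Data frame as [graph_edges()] plus column `resistance`.
#' @export
effective_resistance <- function(graph) {
  el <- graph_edges(graph)
  R <- resistance_matrix(graph)
  el$resistance <- R[cbind(el$i, el$j)]
  el
}

#' Edge importance table
#'
#' Importance of an edge is the product of its weight and its effective
#' resistance, `I_ij = w_ij * R_ij`. A bridge (sole path between its
#' endpoints) has `R = 1/w` and hence importance exactly 1; on a connected
#' graph the importances sum to `N - 1` (Foster's theorem). Low-importance
#' edges are weak links with many alternative paths and are the first
#' candidates for removal.
#'
#' @param graph A [weighted_graph()].
#' @return Data frame with columns `i`, `j`, `from`, `to`, `weight`,
#'   `resistance`, `importance`, one row per edge in canonical order.
#' @export
edge_importance <- function(graph) {
  el <- effective_resistance(graph)
  el$importance <- el$weight * el$resistance
  el
}

#' Laplacian spectral summary
#'
#' @param graph A [weighted_graph()].
#' @return List of class `spectral_summary`: `eigenvalues` (ascending),
#'   `spectral_gap` (`lambda_2`, zero by convention for graphs with a single
#'   node), and `n_components` (combinatorial count, not spectral).
#' @export
spectral_summary <- function(graph) {
  lambda <- sort(eigen(laplacian(graph), symmetric = TRUE,
                       only.values = TRUE)$values)
  structure(list(
    eigenvalues = lambda,
    spectral_gap = if (length(lambda) >= 2) lambda[[2L]] else 0,
    n_components = graph_components(graph)$n_components
  ), class = "spectral_summary")
}

#' Algebraic connectivity (Fiedler value)
#'
#' Second-smallest Laplacian eigenvalue; zero iff the graph is disconnected.
#'
#' @param graph A [weighted_graph()].
#' @return Non-negative scalar.
#' @export
fiedler_value <- function(graph) spectral_summary(graph)$spectral_gap

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> N=%d, gap=%.6g, components=%d\n",
              length(x$eigenvalues), x$spectral_gap, x$n_components))
  invisible(x)
}

#' Normalized Laplacian (utility)
#'
#' `D^{-1/2} L D^{-1/2}`, with zero-degree nodes left as isolated zero
#' rows/columns. Exposed as a diagnostic utility only; no pipeline path
#' uses it.
#'
#' @param graph A [weighted_graph()].
#' @return Symmetric matrix.
#' @export
normalized_laplacian <- function(graph) {
  d <- graph_degrees(graph)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- laplacian(graph)
  outer(s, s) * L
}

#' Foster residual diagnostic
#'
#' On a connected graph the edge importances sum to `N - 1`; the relative
#' residual `|sum(I) - (N-1)| / (N-1)` is a cheap numerical health check
#' logged by the pipeline drivers.
#'
#' @param graph A connected [weighted_graph()].
#' @return Non-negative scalar.
#' @export
foster_residual <- function(graph) {
  n <- n_nodes(graph)
  if (n < 2) return(0)
  abs(sum(edge_importance(graph)$importance) - (n - 1)) / (n - 1)
}
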