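# Independent oracles. These deliberately avoid the package's
# eigendecomposition/pseudoinverse route: resistances come from per-pair
# grounded linear solves, and the greedy oracle re-implements the removal
# loop on top of them.

# Effective resistance between nodes i and j by solving the grounded
# Laplacian system L x = e_i - e_j with the last node of the component
# removed (the circuit solved directly).
oracle_resistance <- function(graph, i, j) {
  comp <- graph_components(graph)$membership
  if (comp[i] != comp[j]) return(Inf)
  members <- which(comp == comp[i])
  L <- laplacian(graph)[members, members, drop = FALSE]
  ii <- match(i, members)
  jj <- match(j, members)
  ground <- length(members)
  if (ground == ii || ground == jj) ground <- 1L
  keep <- setdiff(seq_along(members), ground)
  b <- numeric(length(members))
  b[ii] <- 1
  b[jj] <- -1
  x <- numeric(length(members))
  x[keep] <- solve(L[keep, keep, drop = FALSE], b[keep])
  x[ii] - x[jj]
}

oracle_resistance_all <- function(graph) {
  el <- graph_edges(graph)
  vapply(seq_len(nrow(el)),
         function(k) oracle_resistance(graph, el$i[k], el$j[k]),
         numeric(1))
}

# Brute-force greedy removal: recompute all resistances with the grounded
# solver at every step, pick minimal w*R with the (i, j) tie-break.
# Returns the removal order as a data frame, stopping before fragmentation.
oracle_greedy_order <- function(graph) {
  out <- list()
  current <- graph
  repeat {
    el <- graph_edges(current)
    if (!nrow(el)) break
    imp <- el$weight * oracle_resistance_all(current)
    k <- which.min(imp)  # rows already in (i, j) lexicographic order
    after <- drop_edge(current, el$i[k], el$j[k])
    if (!is_connected(after)) break
    out[[length(out) + 1L]] <- data.frame(i = el$i[k], j = el$j[k],
                                          importance = imp[k])
    current <- after
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Exact inclusion probability of each edge when `target` distinct edges are
# drawn sequentially with probability proportional to `imp` among the
# remaining edges: enumeration over all ordered draw sequences.
oracle_inclusion_prob <- function(imp, target) {
  m <- length(imp)
  incl <- numeric(m)
  recurse <- function(remaining, prob, depth) {
    if (depth == target) return()
    for (e in remaining) {
      p_e <- prob * imp[e] / sum(imp[remaining])
      incl[e] <<- incl[e] + p_e
      recurse(setdiff(remaining, e), p_e, depth + 1L)
    }
  }
  recurse(seq_len(m), 1, 0L)
  incl
}

# Random connected weighted graph: Erdos-Renyi edges on top of a random
# spanning tree (guarantees connectivity), uniform weights in (0.05, 1].
random_connected_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    for (v in 2:n) {
      u <- sample.int(v - 1L, 1L)
      w[u, v] <- w[v, u] <- stats::runif(1, 0.05, 1)
    }
    extra <- which(upper.tri(w) & w == 0)
    extra <- extra[stats::runif(length(extra)) < p]
    w[extra] <- stats::runif(length(extra), 0.05, 1)
    w <- pmax(w, t(w))
    weighted_graph(paste0("n", seq_len(n)), w)
  })
}
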