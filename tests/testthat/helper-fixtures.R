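# Shared fixtures built in code.

# Graph from an edge table: make_graph(c("a","b","c"), "a","b",1, "b","c",2)
make_graph <- function(nodes, ...) {
  args <- list(...)
  stopifnot(length(args) %% 3 == 0)
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq(1, length(args), by = 3)) {
    a <- args[[k]]; b <- args[[k + 1]]; wt <- args[[k + 2]]
    w[a, b] <- w[b, a] <- wt
  }
  weighted_graph(nodes, w)
}

unit_triangle <- function() make_graph(c("a", "b", "c"),
                                       "a", "b", 1, "b", "c", 1, "a", "c", 1)

unit_path3 <- function() make_graph(c("a", "b", "c"),
                                    "a", "b", 1, "b", "c", 1)

star_graph <- function(k = 5) {
  leaves <- paste0("l", seq_len(k))
  args <- unlist(lapply(leaves, function(l) list("hub", l, 1)),
                 recursive = FALSE)
  do.call(make_graph, c(list(c("hub", leaves)), args))
}

complete_graph <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  weighted_graph(paste0("v", seq_len(n)), w)
}

# The canonical two-block + single-bridge world: two tight 10-gene modules
# joined by one weak tie (infeasible as literal entries, hence the nearest-
# correlation projection; realized bridge correlation ~0.245).
two_block_bridge_spec <- function(n_samples = 200) {
  sim_spec(blocks = c(10, 10), rho = 0.8, n_samples = n_samples,
           bridges = data.frame(gene_a = "g1", gene_b = "g11", rho = 0.3),
           psd = "nearest")
}

# Two-condition world for the null-model tests: two 6-gene blocks at
# rho 0.7; condition B rewires 4 disjoint cross-block pairs from 0 to 0.3
# (the largest strength for which the 4-pair template is still PSD, and the
# same weak-tie scale as the bridge fixture).
rewired_pairs_fixture <- function() {
  data.frame(gene_a = c("g1", "g2", "g3", "g4"),
             gene_b = c("g7", "g8", "g9", "g10"),
             rho = 0.3)
}

two_condition_spec <- function(n_samples = 40, rewire = rewired_pairs_fixture()) {
  sim_spec(blocks = c(6, 6), rho = 0.7, n_samples = n_samples,
           rewire = rewire, psd = "nearest")
}

# Multi-condition world for the reproducibility experiment: 24 condition
# groups (4 lineages x 6 stages) x 4 replicates = 96 samples, the design
# of the study data, on a 20-gene two-block set. Condition means follow a
# developmental trajectory (block 1 genes ramp up over stages, block 2
# down, gene amplitudes 0.8-1.6 residual-sd units), so that - as in the
# real data, where stage and lineage dominate the variance - pooled-sample
# correlations are driven by condition structure that any balanced
# subsample retains. Residual within-block correlation 0.5.
repro_fixture_spec <- function() {
  stages <- rep(1:6, times = 4)               # conditions c1..c24
  t_stage <- (stages - 3.5) / 2.5             # trajectory in [-1, 1]
  amp <- rep(seq(0.8, 1.6, length.out = 10), 2) *
    rep(c(1, -1), each = 10)                  # block sign
  sim_spec(blocks = c(10, 10), rho = 0.5, n_samples = 4,
           bridges = data.frame(gene_a = "g1", gene_b = "g11", rho = 0.2),
           conditions = paste0("c", 1:24),
           condition_means = outer(amp, t_stage))
}

expr_from_matrix <- function(vals, conditions = NULL) {
  expression_matrix(vals, condition_of = conditions)
}
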