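#' Replicate-subsampling reproducibility experiment
#'
#' Quantifies how stable extracted skeletons are under data subsampling,
#' against the yardstick of spectrally-matched random graphs. For each
#' gene set:
#'
#' * a reference skeleton is extracted from all samples;
#' * `n_repeats` subsampled skeletons are extracted, either dropping one
#'   random replicate per condition (`mode = "drop_one_per_condition"`,
#'   mild) or keeping a random fraction of samples (`mode = "fraction"`,
#'   aggressive; default 20%);
#' * `n_repeats` density-matched probabilistic sparsifications of the
#'   reference complete graph serve as the random-graph yardstick
#'   ("null" group).
#'
#' Each subsampled/null graph is compared to the reference (Hamming,
#' Jaccard, spectral distance), and all within-group pairs are compared to
#' each other. Mild subsampling is expected to sit closest to the
#' reference, aggressive subsampling further, and the density-matched
#' random graphs furthest.
#'
#' @param expr An [expression_matrix()] (with condition labels when
#'   `mode = "drop_one_per_condition"`).
#' @param sets List of [gene_set()]s (or a single one).
#' @param mode `"drop_one_per_condition"` or `"fraction"`.
#' @param n_repeats Subsampling repetitions per gene set (default 8).
#' @param fraction Fraction kept when `mode = "fraction"` (default 0.2).
#' @param seed Integer master seed; every repetition uses a derived seed.
#' @param method Correlation method.
#' @param stride MSE checkpoint stride.
#' @return Data frame with columns `set_id`, `group` (`subsample` or
#'   `null`), `comparison` (`vs_reference` or `within`), `rep_a`, `rep_b`,
#'   `hamming`, `jaccard`, `spectral`, `n_edges_a`, `n_edges_b`.
#' @export
run_reproducibility_experiment <- function(expr, sets,
                                           mode = c("drop_one_per_condition",
                                                    "fraction"),
                                           n_repeats = 8L, fraction = 0.2,
                                           seed = 1L,
                                           method = c("pearson", "spearman"),
                                           stride = 1L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (inherits(sets, "gene_set")) sets <- list(sets)
  rows <- list()
  add_row <- function(set_id, group, comparison, rep_a, rep_b, ga, gb) {
    rows[[length(rows) + 1L]] <<- data.frame(
      set_id = set_id, group = group, comparison = comparison,
      rep_a = rep_a, rep_b = rep_b,
      hamming = hamming_distance(ga, gb),
      jaccard = jaccard_index(ga, gb),
      spectral = spectral_distance(ga, gb),
      n_edges_a = n_edges(as_weighted_graph(ga)),
      n_edges_b = n_edges(as_weighted_graph(gb)),
      stringsAsFactors = FALSE)
  }
  for (s in sets) {
    ref <- extract_skeleton(expr, s, method, stride)$skeleton
    complete <- build_complete_graph(expr, s, method)
    subs <- lapply(seq_len(n_repeats), function(r) {
      sub_expr <- switch(mode,
        drop_one_per_condition =
          subsample_one_per_condition(expr, derive_seed(seed, 301L, r)),
        fraction =
          subsample_fraction(expr, fraction, derive_seed(seed, 302L, r)))
      extract_skeleton(sub_expr, s, method, stride)$skeleton
    })
    nulls <- lapply(seq_len(n_repeats), function(r) {
      probabilistic_sparsify(complete, n_edges(ref$graph),
                             seed = derive_seed(seed, 303L, r))
    })
    groups <- list(subsample = subs, null = nulls)
    for (gname in names(groups)) {
      members <- groups[[gname]]
      for (r in seq_along(members)) {
        add_row(s$set_id, gname, "vs_reference", 0L, r, ref, members[[r]])
      }
      if (length(members) >= 2) {
        for (a in seq_len(length(members) - 1L)) {
          for (b in seq(a + 1L, length(members))) {
            add_row(s$set_id, gname, "within", a, b,
                    members[[a]], members[[b]])
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
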