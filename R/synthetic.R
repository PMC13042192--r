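#' Specification of a synthetic block-correlated expression dataset
#'
#' Describes a Gaussian expression model with block-diagonal correlation
#' structure plus optional cross-block "bridge" pairs and optional
#' condition-specific rewiring: the stylized world in which two tight
#' co-expression modules are joined by a single weak tie, the regime the
#' sparsifier is designed to respect. Genes are `g1..gN` in block order;
#' samples per condition are drawn i.i.d. from `N(0, C)` with `C` the
#' implied correlation matrix (optionally plus mean shifts and independent
#' noise).
#'
#' @param blocks Integer vector of block sizes (sums to the gene count).
#' @param rho Within-block correlation, scalar or one value per block, in
#'   `[0, 1)`.
#' @param n_samples Samples per condition.
#' @param bridges Optional data frame with columns `gene_a`, `gene_b`
#'   (gene ids or 1-based indices) and `rho`: cross-block correlated pairs.
#' @param rewire Optional data frame with the same columns: pairs whose
#'   correlation in condition B replaces the condition-A value.
#' @param conditions Character vector of condition labels (replicated
#'   structure; default a single condition `"A"`).
#' @param mean_shift Optional per-condition mean offsets (named numeric,
#'   one value per condition, added to every gene) to exercise the
#'   mean-centering step of the null model.
#' @param condition_means Optional genes x conditions matrix of mean
#'   offsets (columns named by condition), emulating condition-driven
#'   expression programs such as developmental trajectories; added on top
#'   of `mean_shift`.
#' @param noise_sd Standard deviation of independent Gaussian noise added
#'   on top of the correlated draws (default 0; the correlation matrix
#'   itself already encodes the residual variance).
#' @param psd What to do when the entry-template correlation matrix is not
#'   positive semi-definite: `"error"` (default) rejects it naming the
#'   offending pairs; `"nearest"` projects to the nearest correlation
#'   matrix (Higham), slightly shrinking the stated entries (a strong
#'   cross-block bridge between tight blocks is often infeasible as a
#'   literal entry).
#' @return A validated object of class `sim_spec`.
#' @export
sim_spec <- function(blocks, rho, n_samples, bridges = NULL, rewire = NULL,
                     conditions = "A", mean_shift = NULL, noise_sd = 0,
                     psd = c("error", "nearest"), condition_means = NULL) {
  psd <- match.arg(psd)
  if (!is.null(condition_means)) {
    condition_means <- as.matrix(condition_means)
    if (nrow(condition_means) != sum(blocks) ||
        ncol(condition_means) != length(conditions)) {
      stop("condition_means must be a genes x conditions matrix")
    }
    colnames(condition_means) <- conditions
  }
  blocks <- as.integer(blocks)
  if (any(blocks < 1)) stop("block sizes must be positive")
  n_genes <- sum(blocks)
  rho <- rep_len(rho, length(blocks))
  if (any(rho < 0 | rho >= 1)) stop("within-block rho must lie in [0, 1)")
  genes <- paste0("g", seq_len(n_genes))
  block_of <- rep(seq_along(blocks), blocks)
  norm_pairs <- function(df, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(c("gene_a", "gene_b", "rho") %in% names(df))) {
      stop(what, " needs columns gene_a, gene_b, rho")
    }
    to_id <- function(x) if (is.numeric(x)) genes[x] else as.character(x)
    df$gene_a <- to_id(df$gene_a)
    df$gene_b <- to_id(df$gene_b)
    bad <- !(df$gene_a %in% genes) | !(df$gene_b %in% genes)
    if (any(bad)) stop(what, " references unknown genes")
    if (any(abs(df$rho) >= 1)) stop(what, " correlations must lie in (-1, 1)")
    df
  }
  bridges <- norm_pairs(bridges, "bridges")
  rewire <- norm_pairs(rewire, "rewire")
  spec <- structure(list(blocks = blocks, rho = rho, n_samples = n_samples,
                         n_genes = n_genes, genes = genes,
                         block_of = block_of, bridges = bridges,
                         rewire = rewire, conditions = conditions,
                         mean_shift = mean_shift, noise_sd = noise_sd,
                         psd = psd, condition_means = condition_means),
                    class = "sim_spec")
  # fail fast on a non-PSD construction
  sim_correlation(spec)
  if (!is.null(rewire)) sim_correlation(spec, condition_b = TRUE)
  spec
}

#' Implied correlation matrix of a simulation spec
#'
#' @param spec A [sim_spec()].
#' @param condition_b If `TRUE`, apply the rewiring instructions (the
#'   condition-B covariance).
#' @return Correlation matrix with gene ids as dimnames; errors if the
#'   construction is not positive semi-definite, naming the offending
#'   bridge/rewire pairs.
#' @export
sim_correlation <- function(spec, condition_b = FALSE) {
  n <- spec$n_genes
  C <- matrix(0, n, n, dimnames = list(spec$genes, spec$genes))
  same_block <- outer(spec$block_of, spec$block_of, "==")
  C[same_block] <- spec$rho[spec$block_of[row(C)[same_block]]]
  diag(C) <- 1
  apply_pairs <- function(C, df) {
    for (r in seq_len(NROW(df))) {
      ia <- match(df$gene_a[r], spec$genes)
      ib <- match(df$gene_b[r], spec$genes)
      C[ia, ib] <- C[ib, ia] <- df$rho[r]
    }
    C
  }
  C <- apply_pairs(C, spec$bridges)
  if (condition_b) C <- apply_pairs(C, spec$rewire)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    if (identical(spec$psd %||% "error", "nearest")) {
      C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
      dimnames(C) <- list(spec$genes, spec$genes)
    } else {
      culprits <- rbind(spec$bridges, if (condition_b) spec$rewire)
      stop("implied correlation matrix is not positive semi-definite ",
           "(min eigenvalue ", signif(min(ev), 3), "); check pairs: ",
           paste(paste0(culprits$gene_a, "-", culprits$gene_b),
                 collapse = ", "))
    }
  }
  C
}

# Draw genes x samples from N(0, C) via symmetric square root (tolerates
# semi-definite C, unlike plain Cholesky).
draw_mvn <- function(C, n_samples) {
  es <- eigen(C, symmetric = TRUE)
  root <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  z <- matrix(stats::rnorm(nrow(C) * n_samples), nrow(C), n_samples)
  root %*% z
}

#' Simulate a block-correlated expression matrix
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed (deterministic output).
#' @param condition_b Draw from the rewired (condition-B) covariance.
#' @return List with `expr` (an [expression_matrix()] with condition
#'   labels) and `truth`: a data frame of generating pair annotations
#'   (`gene_a`, `gene_b`, `rho`, `kind` in within_block/bridge/rewired).
#' @export
simulate_expression <- function(spec, seed = 1L, condition_b = FALSE) {
  C <- sim_correlation(spec, condition_b)
  n_cond <- length(spec$conditions)
  total <- spec$n_samples * n_cond
  vals <- withr::with_seed(seed, {
    x <- draw_mvn(C, total)
    if (spec$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sd),
                      nrow(x), ncol(x))
    }
    x
  })
  cond_vec <- rep(spec$conditions, each = spec$n_samples)
  if (!is.null(spec$mean_shift)) {
    vals <- vals + rep(spec$mean_shift[cond_vec], each = spec$n_genes)
  }
  if (!is.null(spec$condition_means)) {
    vals <- vals + spec$condition_means[, cond_vec, drop = FALSE]
  }
  sample_ids <- paste0("s", seq_len(total), "_", cond_vec)
  dimnames(vals) <- list(spec$genes, sample_ids)
  expr <- expression_matrix(vals,
                            condition_of = stats::setNames(cond_vec, sample_ids))
  list(expr = expr, truth = sim_truth(spec, condition_b))
}

# Pair-level ground truth of the generating covariance (annotations, not a
# graph, to avoid circularity with the method under test).
sim_truth <- function(spec, condition_b = FALSE) {
  rows <- list()
  for (b in seq_along(spec$blocks)) {
    members <- spec$genes[spec$block_of == b]
    if (length(members) >= 2) {
      pairs <- utils::combn(members, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = pairs[1L, ], gene_b = pairs[2L, ], rho = spec$rho[b],
        kind = "within_block", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(spec$bridges)) {
    rows[[length(rows) + 1L]] <- cbind(spec$bridges[c("gene_a", "gene_b", "rho")],
                                       kind = "bridge")
  }
  truth <- do.call(rbind, rows)
  if (condition_b && !is.null(spec$rewire)) {
    for (r in seq_len(nrow(spec$rewire))) {
      hit <- (truth$gene_a == spec$rewire$gene_a[r] &
                truth$gene_b == spec$rewire$gene_b[r]) |
             (truth$gene_a == spec$rewire$gene_b[r] &
                truth$gene_b == spec$rewire$gene_a[r])
      if (any(hit)) {
        truth$rho[hit] <- spec$rewire$rho[r]
        truth$kind[hit] <- "rewired"
      } else {
        truth <- rbind(truth, data.frame(gene_a = spec$rewire$gene_a[r],
                                         gene_b = spec$rewire$gene_b[r],
                                         rho = spec$rewire$rho[r],
                                         kind = "rewired"))
      }
    }
  }
  rownames(truth) <- NULL
  truth
}

#' Simulate paired condition-A / condition-B datasets
#'
#' Condition B is drawn from a covariance differing from A's only at the
#' spec's `rewire` pairs (empty rewiring: both conditions share one
#' covariance). Group sizes are equal (`spec$n_samples` each).
#'
#' @param spec A [sim_spec()] (its `conditions` field is ignored here; the
#'   two matrices are labeled A and B).
#' @param seed Integer master seed; A and B use derived sub-seeds.
#' @return List with `expr_a`, `expr_b` ([expression_matrix()]s),
#'   `rewired_pairs` (data frame, possibly empty) and `truth_a`/`truth_b`.
#' @export
simulate_two_conditions <- function(spec, seed = 1L) {
  spec_one <- spec
  spec_one$conditions <- "A"
  a <- simulate_expression(spec_one, seed = derive_seed(seed, 11L))
  spec_one$conditions <- "B"
  b <- simulate_expression(spec_one, seed = derive_seed(seed, 22L),
                           condition_b = TRUE)
  rewired <- spec$rewire
  if (is.null(rewired)) {
    rewired <- data.frame(gene_a = character(), gene_b = character(),
                          rho = numeric())
  }
  list(expr_a = a$expr, expr_b = b$expr, rewired_pairs = rewired,
       truth_a = a$truth, truth_b = b$truth)
}
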