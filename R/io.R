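#' Gene set container
#'
#' @param set_id Identifier (e.g. a KEGG pathway id).
#' @param genes Character vector of at least two unique gene ids; order is
#'   preserved and defines downstream node order.
#' @param description Free-text description.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(set_id, genes, description = "") {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in set '", set_id, "'")
  if (length(genes) < 2) stop("gene set '", set_id, "' needs at least 2 genes")
  structure(list(set_id = as.character(set_id),
                 description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$set_id, length(x$genes)))
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Expects gene ids in the first column and sample ids in the header row
#' (use `transpose = TRUE` for samples-in-rows files). Values must be
#' numeric; rows containing missing values are dropped with a message by
#' default or rejected with `strict = TRUE`.
#'
#' @param path File path.
#' @param delimiter Field separator (default tab).
#' @param transpose Set `TRUE` when the file stores samples in rows.
#' @param strict If `TRUE`, any missing/non-finite value is an error instead
#'   of a dropped row.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t", transpose = FALSE,
                            strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2) stop("malformed header: expected id column plus values")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw) &
                 !(toupper(raw) %in% c("NA", "NAN", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %s (id '%s'), column %s ('%s')",
                 raw[bad[1L, , drop = FALSE]], bad[1L, 1L], ids[bad[1L, 1L]],
                 bad[1L, 2L], colnames(raw)[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(ids, colnames(raw))
  if (transpose) vals <- t(vals)
  incomplete <- !apply(is.finite(vals), 1L, all)
  if (any(incomplete)) {
    if (strict) {
      stop(sum(incomplete), " gene row(s) contain missing/non-finite values")
    }
    message("dropping ", sum(incomplete),
            " gene row(s) with missing/non-finite values")
    vals <- vals[!incomplete, , drop = FALSE]
  }
  expression_matrix(vals)
}

#' Read sample condition labels
#'
#' Two-column delimited file (sample id, condition label), with or without a
#' header line named `sample`/`condition`.
#'
#' @param path File path.
#' @param delimiter Field separator.
#' @return Named character vector, sample id -> condition.
#' @export
read_condition_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = delimiter,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("expected two columns: sample id, condition")
  if (tolower(tab[1L, 1L]) %in% c("sample", "sample_id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Gene order is
#' preserved; duplicate genes within a line are dropped with a warning;
#' lines with fewer than two unique genes are skipped with a warning.
#'
#' @param path File path.
#' @return Named list of [gene_set()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    id <- fields[[1L]]
    desc <- if (length(fields) >= 2) fields[[2L]] else ""
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", id, "' dropped: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "),
              call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    if (length(genes) < 2) {
      warning("skipping set '", id, "': fewer than 2 genes", call. = FALSE)
      next
    }
    sets[[id]] <- gene_set(id, genes, desc)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotated edge list
#'
#' One row per edge of `graph` (canonical order, `gene_a < gene_b`
#' lexicographically), with the edge's weight, effective resistance,
#' importance, and a kept-flag marking membership in `kept` (a sparsified
#' graph or skeleton over the same nodes). Numbers are written with 12
#' significant digits so a round-trip via [read_edge_list()] reproduces
#' weights to that precision.
#'
#' @param graph A [weighted_graph()] (typically the complete graph).
#' @param path Output path.
#' @param kept Optional [weighted_graph()] or [skeleton()] whose edges are
#'   flagged `TRUE`; default flags every edge.
#' @return The edge table, invisibly.
#' @export
write_edge_list <- function(graph, path, kept = NULL) {
  if (n_edges(graph) == 0) stop("graph has no edges to write")
  tab <- edge_importance(graph)
  keep_w <- if (is.null(kept)) graph$weights else as_weighted_graph(kept)$weights
  if (!is.null(kept) &&
      !identical(as_weighted_graph(kept)$nodes, graph$nodes)) {
    stop("`kept` must share the graph's node set and order")
  }
  swap <- tab$from > tab$to
  tmp <- tab$from[swap]; tab$from[swap] <- tab$to[swap]; tab$to[swap] <- tmp
  out <- data.frame(
    gene_a = tab$from, gene_b = tab$to,
    weight = sprintf("%.12g", tab$weight),
    effective_resistance = sprintf("%.12g", tab$resistance),
    importance = sprintf("%.12g", tab$importance),
    kept = keep_w[cbind(tab$i, tab$j)] > 0,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a weighted graph from an edge-list TSV
#'
#' Inverse of [write_edge_list()]. Node order defaults to first appearance;
#' pass `nodes` to fix it (required to reproduce canonical ordering).
#'
#' @param path File path.
#' @param nodes Optional character vector fixing node order.
#' @param kept_only If `TRUE`, only rows flagged kept become edges.
#' @return A [weighted_graph()].
#' @export
read_edge_list <- function(path, nodes = NULL, kept_only = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(tab))) {
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  }
  if (kept_only && "kept" %in% names(tab)) tab <- tab[tab$kept, , drop = FALSE]
  if (is.null(nodes)) nodes <- unique(c(rbind(tab$gene_a, tab$gene_b)))
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(tab$gene_a, nodes)
  ib <- match(tab$gene_b, nodes)
  if (anyNA(ia) || anyNA(ib)) stop("edge references a gene missing from `nodes`")
  w[cbind(ia, ib)] <- tab$weight
  w[cbind(ib, ia)] <- tab$weight
  weighted_graph(nodes, w)
}
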