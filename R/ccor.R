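#' Copula-correlation (Ccor) matrix between cells
#'
#' Pairwise dependence between cells over the sampled genes. The default
#' `empirical_tau` mode is the tie-corrected Kendall tau-b between the two
#' cells' expression profiles across the selected genes; because tau depends
#' on the data only through ranks it equals the tau of the underlying copula
#' (scale invariance). The `clayton` mode additionally round-trips each
#' pairwise tau through the Clayton parameter (theta = 2*tau/(1-tau), tau =
#' theta/(theta+2)), a diagnostic parity check of the copula model; values
#' outside the Clayton-attainable range (-1/3, 1) are clipped.
#'
#' @param m a `norm_matrix`.
#' @param genes a `gene_subset` from [sample_features()], or an integer
#'   vector of gene indices; `NULL` uses all genes.
#' @param mode `"empirical_tau"` (default) or `"clayton"`.
#' @return An object of class `ccor_matrix`: symmetric `values` matrix with
#'   unit diagonal, entries in `[-1, 1]`, plus `cell_ids` and `mode`.
#'   Undefined pairs (constant profiles) score 0 with a warning.
#' @export
ccor_matrix <- function(m, genes = NULL,
                        mode = c("empirical_tau", "clayton")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "norm_matrix"))
  idx <- if (is.null(genes)) seq_len(ncol(m$values))
         else if (inherits(genes, "gene_subset")) genes$selected
         else as.integer(genes)
  if (length(idx) < 2) stop("need at least 2 selected genes")
  if (nrow(m$values) < 2) stop("need at least 2 cells")
  v <- m$values[, idx, drop = FALSE]
  tau <- .kendall_tau_rows_cpp(v)
  if (anyNA(tau)) {
    warning(sum(is.na(tau)) / 2, " cell pair(s) with constant profiles; ",
            "Ccor set to 0")
    tau[is.na(tau)] <- 0
  }
  if (mode == "clayton") {
    off <- row(tau) != col(tau)
    th <- suppressWarnings(theta_from_tau(tau[off]))
    tau[off] <- vapply(th, tau_from_theta, numeric(1))
  }
  structure(list(values = tau, cell_ids = m$cell_ids, mode = mode),
            class = "ccor_matrix")
}

#' @export
print.ccor_matrix <- function(x, ...) {
  cat("ccor_matrix:", nrow(x$values), "cells, mode =", x$mode, "\n")
  invisible(x)
}

# union-of-directed-kNN edges from a score matrix.
# decreasing = TRUE ranks by descending score (similarities),
# FALSE by ascending (distances). Ties break by ascending index.
.knn_union <- function(score, k, decreasing = TRUE) {
  n <- nrow(score)
  ranked <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    s <- score[i, ]
    ord <- order(if (decreasing) -s else s, seq_len(n))
    ord <- ord[ord != i]
    ranked[i, ] <- ord[seq_len(k)]
  }
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(ranked))
  e <- cbind(pmin(from, to), pmax(from, to))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  list(edges = e, ranked = ranked)
}

#' k-nearest-neighbour cell graph from a Ccor matrix
#'
#' Each cell ranks all others by descending Ccor (ties by ascending index)
#' and keeps the top `k`; the undirected union of the directed top-k choices
#' is the edge set. Every node therefore has degree >= k when `k < n`, and
#' the edge count lies between `k*n/2` (fully mutual lists) and `k*n`.
#'
#' @param c a [ccor_matrix()].
#' @param k neighbours per cell (default 5); must be `< n`.
#' @return An object of class `cell_graph`: `n_nodes`, `edges` (m x 2
#'   integer matrix, `i < j`, lexicographic order), `ranked_lists` (n x k,
#'   the directed choices), `cell_ids`, `weights` (Ccor per edge).
#' @export
build_knn_graph <- function(c, k = 5) {
  stopifnot(inherits(c, "ccor_matrix"))
  n <- nrow(c$values)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  res <- .knn_union(c$values, k, decreasing = TRUE)
  structure(list(n_nodes = n, edges = res$edges, ranked_lists = res$ranked,
                 cell_ids = c$cell_ids,
                 weights = c$values[res$edges]),
            class = "cell_graph")
}

#' Construct a cell graph from an explicit edge list
#'
#' Mostly for tests and for loading a saved graph: validates, deduplicates
#' and canonically orders an undirected edge list.
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix of node pairs (1-based, no self-loops).
#' @param cell_ids optional node identifiers.
#' @return A `cell_graph` (without ranked lists).
#' @export
cell_graph <- function(n_nodes, edges, cell_ids = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges < 1 | edges > n_nodes)) stop("edge endpoint out of range")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n_nodes))
  structure(list(n_nodes = as.integer(n_nodes), edges = e,
                 ranked_lists = NULL, cell_ids = cell_ids, weights = NULL),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat("cell_graph:", x$n_nodes, "nodes,", nrow(x$edges), "undirected edges",
      sprintf("(%.2f edges/node)\n", nrow(x$edges) / x$n_nodes))
  invisible(x)
}

#' Write a cell graph as an edge list
#'
#' Two id columns plus an optional `weight` column (the Ccor of the edge),
#' tab-separated.
#'
#' @param g a `cell_graph`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  stopifnot(inherits(g, "cell_graph"))
  tab <- data.frame(from = g$cell_ids[g$edges[, 1]],
                    to = g$cell_ids[g$edges[, 2]])
  if (!is.null(g$weights)) tab$weight <- g$weights
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# dense adjacency (0/1) of a cell_graph
.adjacency <- function(g) {
  a <- matrix(0, g$n_nodes, g$n_nodes)
  a[g$edges] <- 1
  a[g$edges[, c(2, 1), drop = FALSE]] <- 1
  a
}
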