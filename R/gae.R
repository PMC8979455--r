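#' GCN autoencoder hyperparameters
#'
#' A three-layer graph-convolutional encoder (hidden dims 256 and 128, final
#' embedding 128 by default) with ReLU after layers 1-2, trained as a graph
#' autoencoder: the inner-product decoder reconstructs the adjacency and the
#' model is fitted by full-graph weighted binary cross-entropy with Adam.
#'
#' @param layer_dims three output dimensions, one per layer
#'   (default `c(256, 128, 128)`; the last is the embedding dimension).
#' @param dropout dropout fraction on hidden activations during training
#'   (default 0.1).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 50; no early stopping).
#' @param seed RNG seed governing initialization and dropout.
#' @return An object of class `gcn_params`.
#' @export
gcn_params <- function(layer_dims = c(256, 128, 128), dropout = 0.1,
                       learning_rate = 0.001, epochs = 50, seed = 1) {
  if (length(layer_dims) != 3) stop("exactly 3 layers are supported")
  stopifnot(all(layer_dims >= 1), dropout >= 0, dropout < 1,
            learning_rate > 0, epochs >= 0)
  structure(list(layer_dims = as.integer(layer_dims), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 activation = "relu", seed = as.integer(seed)),
            class = "gcn_params")
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Returns \eqn{\hat{D}^{-1/2} \hat{A} \hat{D}^{-1/2}} where
#' \eqn{\hat{A} = A + I} and \eqn{\hat{D}} is its diagonal degree matrix.
#' The self-loop guarantees degree >= 1 for isolated nodes; the symmetric
#' normalization keeps all eigenvalues in `[-1, 1]`.
#'
#' @param g a `cell_graph`, or a square symmetric 0/1 adjacency matrix.
#' @return Dense symmetric numeric matrix.
#' @export
normalize_adjacency <- function(g) {
  a <- if (inherits(g, "cell_graph")) .adjacency(g) else as.matrix(g)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  diag(a) <- diag(a) + 1
  dinv <- 1 / sqrt(rowSums(a))
  a * outer(dinv, dinv)
}

#' Split graph edges for link-prediction training
#'
#' Uniform random partition of the undirected edges into train / validation
#' / test sets in the given proportions (default 8:1:1). Validation and test
#' edges are only drawn where removal leaves both endpoints with at least
#' one remaining edge, so every node of the graph stays in the training
#' graph. Negative (non-edge) pairs of matching sizes are sampled uniformly,
#' disjointly for validation and test, excluding self-loops.
#'
#' @param g a `cell_graph` with at least 10 edges.
#' @param ratios train/val/test proportions summing to 1.
#' @param seed RNG seed.
#' @return An object of class `edge_split` with `train_edges`, `val_edges`,
#'   `test_edges`, `val_neg`, `test_neg` (two-column matrices) and `seed`.
#' @export
split_edges <- function(g, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(inherits(g, "cell_graph"), length(ratios) == 3,
            abs(sum(ratios) - 1) < 1e-8)
  e <- g$edges
  ne <- nrow(e)
  if (ne < 10) stop("graph has fewer than 10 edges; split degenerate")
  n <- g$n_nodes
  set.seed(seed)
  n_val <- floor(ne * ratios[2])
  n_test <- floor(ne * ratios[3])
  ord <- sample.int(ne)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)  # degree among unassigned
  take <- integer(0)                             # indices going to val/test
  for (i in ord) {
    if (length(take) >= n_val + n_test) break
    a <- e[i, 1]; b <- e[i, 2]
    if (deg[a] > 1 && deg[b] > 1) {
      take <- c(take, i)
      deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
    }
  }
  if (length(take) < n_val + n_test)
    warning("could not hold out the full validation/test quota without ",
            "orphaning nodes; using ", length(take), " held-out edges")
  n_val <- min(n_val, length(take))
  val_idx <- take[seq_len(n_val)]
  test_idx <- setdiff(take, val_idx)
  train_idx <- setdiff(seq_len(ne), take)

  # negative sampling: uniform non-edges, i < j, disjoint val/test
  edge_key <- (e[, 1] - 1) * n + e[, 2]
  need <- n_val + length(test_idx)
  neg <- integer(0)
  while (length(neg) < need) {
    i <- sample.int(n, 2 * need, replace = TRUE)
    j <- sample.int(n, 2 * need, replace = TRUE)
    lo <- pmin(i, j); hi <- pmax(i, j)
    ok <- lo != hi
    key <- (lo[ok] - 1) * n + hi[ok]
    key <- key[!(key %in% edge_key)]
    neg <- unique(c(neg, key))
  }
  neg <- neg[seq_len(need)]
  unkey <- function(k) cbind(((k - 1) %/% n) + 1, ((k - 1) %% n) + 1)
  structure(list(train_edges = e[train_idx, , drop = FALSE],
                 val_edges = e[val_idx, , drop = FALSE],
                 test_edges = e[test_idx, , drop = FALSE],
                 val_neg = unkey(neg[seq_len(n_val)]),
                 test_neg = unkey(neg[seq(n_val + 1, need)]),
                 n_nodes = n, seed = as.integer(seed)),
            class = "edge_split")
}

# Glorot-uniform weight initialization for the three layers
.init_gcn_weights <- function(n_nodes, layer_dims) {
  dims_in <- c(n_nodes, layer_dims[1], layer_dims[2])
  lapply(seq_len(3), function(l) {
    fin <- dims_in[l]; fout <- layer_dims[l]
    lim <- sqrt(6 / (fin + fout))
    matrix(runif(fin * fout, -lim, lim), fin, fout)
  })
}

# forward pass; returns intermediates for backprop.
# X = NULL means identity node features (the first weight then acts as a
# free per-node embedding and the n x n input is never materialized).
.gcn_forward <- function(An, weights, X = NULL, dropout = 0,
                         training = FALSE) {
  XW <- if (is.null(X)) weights[[1]] else X %*% weights[[1]]
  Z1 <- An %*% XW
  H1 <- pmax(Z1, 0)
  M1 <- M2 <- NULL
  H1d <- H1
  if (training && dropout > 0) {
    M1 <- matrix(rbinom(length(H1), 1, 1 - dropout), nrow(H1)) / (1 - dropout)
    H1d <- H1 * M1
  }
  Z2 <- An %*% (H1d %*% weights[[2]])
  H2 <- pmax(Z2, 0)
  H2d <- H2
  if (training && dropout > 0) {
    M2 <- matrix(rbinom(length(H2), 1, 1 - dropout), nrow(H2)) / (1 - dropout)
    H2d <- H2 * M2
  }
  Z <- An %*% (H2d %*% weights[[3]])
  list(Z1 = Z1, H1d = H1d, M1 = M1, Z2 = Z2, H2d = H2d, M2 = M2, Z = Z)
}

#' Encode a graph with a 3-layer GCN
#'
#' Three propagation steps \eqn{H^{(l+1)} = \sigma(\hat{D}^{-1/2}\hat{A}
#' \hat{D}^{-1/2} H^{(l)} W^{(l)})} (ReLU after layers 1-2, linear output),
#' convolving each node's third-order neighbourhood. With identity node
#' features (the default), nodes with identical neighbourhoods receive
#' identical embeddings. Evaluation mode: no dropout.
#'
#' @param A_norm normalized adjacency from [normalize_adjacency()].
#' @param params a [gcn_params()].
#' @param weights list of three weight matrices shaped
#'   `n x d1`, `d1 x d2`, `d2 x d3` (from [train_gae()] or
#'   random initialization).
#' @param X optional node feature matrix (`NULL` = identity).
#' @return `embedding` object: `Z` (n x d matrix) and `cell_ids` (NULL here;
#'   filled by [train_gae()]).
#' @export
gcn_encode <- function(A_norm, params, weights, X = NULL) {
  stopifnot(inherits(params, "gcn_params"), length(weights) == 3)
  n <- nrow(A_norm)
  fin <- if (is.null(X)) n else ncol(X)
  if (nrow(weights[[1]]) != fin)
    stop("weight/feature shape mismatch: first layer expects input dim ",
         nrow(weights[[1]]), ", got ", fin)
  fw <- .gcn_forward(A_norm, weights, X = X, training = FALSE)
  structure(list(Z = fw$Z, cell_ids = rownames(A_norm)), class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", nrow(x$Z), "cells x", ncol(x$Z), "dims\n")
  invisible(x)
}

#' Inner-product edge decoder
#'
#' \eqn{\hat{A}_{ij} = \mathrm{sigmoid}(z_i^\top z_j)}: the probability of
#' an edge between nodes i and j under the autoencoder model. Symmetric in
#' (i, j), always in (0, 1).
#'
#' @param Z an `embedding` or a numeric matrix of embeddings (rows = nodes).
#' @param i,j node indices (vectorized). If both `NULL`, the full n x n
#'   probability matrix is returned.
#' @return Edge probabilities.
#' @export
inner_product_decode <- function(Z, i = NULL, j = NULL) {
  z <- if (inherits(Z, "embedding")) Z$Z else as.matrix(Z)
  if (is.null(i) && is.null(j)) return(.sigmoid(tcrossprod(z)))
  .sigmoid(rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable softplus log(1 + e^x)
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Area under the ROC curve from positive/negative scores
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for ties.
#'
#' @param pos,neg numeric score vectors for positive and negative pairs.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision from positive/negative scores
#'
#' Step-wise average precision: mean of the precision at each positive,
#' taken in descending score order.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  sc <- c(pos, neg)
  y <- rep(c(1, 0), c(length(pos), length(neg)))
  ord <- order(-sc, y)  # ties: negatives first (conservative)
  y <- y[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec * y) / sum(y)
}

#' Train a graph autoencoder by link prediction
#'
#' Builds the training graph from the split's training edges, encodes it
#' with the 3-layer GCN and trains encoder weights so that the
#' inner-product decoder reconstructs the training adjacency (plus
#' self-loops). The loss is full-adjacency binary cross-entropy with the
#' positive class reweighted by `(n^2 - 2|E|) / (2|E|)`, optimized with
#' Adam for a fixed number of epochs (no early stopping). Validation and
#' test ROC/AP are computed from the final evaluation-mode embedding on the
#' held-out positive edges and the sampled non-edges.
#'
#' All randomness (initialization, dropout) is governed by `params$seed`;
#' identical inputs give a bitwise-identical loss trajectory.
#'
#' @param g the full `cell_graph` (used for ids/node count).
#' @param params a [gcn_params()].
#' @param split an [split_edges()] result derived from `g`.
#' @return List with `embedding` (evaluation-mode, class `embedding`),
#'   `report` (val/test ROC and AP), `weights`, `loss` (per-epoch
#'   trajectory), `params`.
#' @export
train_gae <- function(g, params, split) {
  stopifnot(inherits(g, "cell_graph"), inherits(params, "gcn_params"),
            inherits(split, "edge_split"))
  if (split$n_nodes != g$n_nodes) stop("split does not match graph")
  n <- g$n_nodes
  gt <- cell_graph(n, split$train_edges, cell_ids = g$cell_ids)
  An <- normalize_adjacency(gt)
  rownames(An) <- g$cell_ids
  Y <- .adjacency(gt)
  diag(Y) <- 1
  m2 <- 2 * nrow(split$train_edges)
  pw <- (n^2 - m2) / m2
  norm_f <- n^2 / (2 * (n^2 - m2))

  set.seed(params$seed)
  W <- .init_gcn_weights(n, params$layer_dims)
  mom <- lapply(W, function(w) w * 0)
  vel <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- params$learning_rate
  loss_hist <- numeric(params$epochs)

  for (ep in seq_len(params$epochs)) {
    fw <- .gcn_forward(An, W, dropout = params$dropout, training = TRUE)
    S <- tcrossprod(fw$Z)
    loss <- norm_f * mean(pw * Y * .softplus(-S) + (1 - Y) * .softplus(S))
    if (!is.finite(loss))
      stop("non-finite loss at epoch ", ep, " (lr = ", lr,
           "); try a smaller learning rate")
    loss_hist[ep] <- loss

    sg <- .sigmoid(S)
    G <- (norm_f / n^2) * ((1 - Y) * sg - pw * Y * (1 - sg))
    dZ <- (G + t(G)) %*% fw$Z
    gW3 <- crossprod(An %*% fw$H2d, dZ)
    dH2d <- An %*% dZ %*% t(W[[3]])
    if (!is.null(fw$M2)) dH2d <- dH2d * fw$M2
    dZ2 <- dH2d * (fw$Z2 > 0)
    gW2 <- crossprod(An %*% fw$H1d, dZ2)
    dH1d <- An %*% dZ2 %*% t(W[[2]])
    if (!is.null(fw$M1)) dH1d <- dH1d * fw$M1
    dZ1 <- dH1d * (fw$Z1 > 0)
    gW1 <- An %*% dZ1                      # identity features: d/dW0 = A' dZ1
    grads <- list(gW1, gW2, gW3)
    for (l in seq_len(3)) {
      mom[[l]] <- b1 * mom[[l]] + (1 - b1) * grads[[l]]
      vel[[l]] <- b2 * vel[[l]] + (1 - b2) * grads[[l]]^2
      mhat <- mom[[l]] / (1 - b1^ep)
      vhat <- vel[[l]] / (1 - b2^ep)
      W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  emb <- gcn_encode(An, params, W)
  emb$cell_ids <- g$cell_ids
  score <- function(pairs) inner_product_decode(emb$Z, pairs[, 1], pairs[, 2])
  report <- list(
    val_roc = roc_auc(score(split$val_edges), score(split$val_neg)),
    val_ap = average_precision(score(split$val_edges), score(split$val_neg)),
    test_roc = roc_auc(score(split$test_edges), score(split$test_neg)),
    test_ap = average_precision(score(split$test_edges), score(split$test_neg)))
  list(embedding = emb, report = report, weights = W, loss = loss_hist,
       params = params)
}

#' Write an embedding as TSV
#'
#' One row per cell: `cell_id` column followed by the d embedding columns.
#'
#' @param emb an `embedding`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding"))
  z <- emb$Z
  colnames(z) <- paste0("dim", seq_len(ncol(z)))
  ids <- if (is.null(emb$cell_ids)) paste0("cell", seq_len(nrow(z)))
         else emb$cell_ids
  tab <- data.frame(cell_id = ids, z, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
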