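#' LSH sampling configuration
#'
#' Settings for structure-aware gene sub-sampling with random-hyperplane
#' (cosine) locality-sensitive hashing: genes are hashed into at most
#' `2^n_bits` buckets, a cosine-distance `n_neighbors`-NN graph is built
#' within each bucket, and a greedy sweep in original gene order keeps a
#' gene while discarding its near neighbours. The whole procedure can be
#' applied recursively (`iterations`) to down-sample further.
#'
#' @param n_bits hash length in bits (default 10, i.e. up to 1024 buckets).
#' @param n_neighbors within-bucket nearest neighbours to discard per kept
#'   gene (default 5).
#' @param iterations number of recursive sampling passes (default 1).
#' @param seed RNG seed for the hyperplanes.
#' @return An object of class `lsh_config`.
#' @export
lsh_config <- function(n_bits = 10, n_neighbors = 5, iterations = 1,
                       seed = 1) {
  stopifnot(n_bits >= 1, n_neighbors >= 1, iterations >= 1)
  structure(list(n_bits = as.integer(n_bits),
                 n_neighbors = as.integer(n_neighbors),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "lsh_config")
}

#' Hash genes into buckets with random hyperplanes
#'
#' Each gene (a column of the normalized matrix, i.e. its profile across
#' cells) gets an `n_bits`-bit code from the signs of its dot products with
#' `n_bits` seeded standard-normal hyperplanes. Genes sharing a code land in
#' the same bucket; the buckets partition the gene set. Colliding genes are
#' close in cosine distance with high probability.
#'
#' @param m a `norm_matrix`.
#' @param cfg an [lsh_config()].
#' @param gene_idx optional subset of gene indices to hash (used by the
#'   recursive passes); defaults to all genes.
#' @return Named list mapping hash code (bit string) to integer vector of
#'   gene indices (into the full matrix).
#' @export
hash_genes <- function(m, cfg, gene_idx = NULL) {
  stopifnot(inherits(m, "norm_matrix"), inherits(cfg, "lsh_config"))
  if (is.null(gene_idx)) gene_idx <- seq_len(ncol(m$values))
  g <- length(gene_idx)
  if (g <= 2^cfg$n_bits)
    stop("number of genes (", g, ") must exceed 2^n_bits = ", 2^cfg$n_bits,
         "; lower n_bits")
  n_cells <- nrow(m$values)
  hyper <- matrix(rnorm(n_cells * cfg$n_bits), n_cells, cfg$n_bits)
  proj <- crossprod(m$values[, gene_idx, drop = FALSE], hyper)  # g x bits
  bits <- proj >= 0
  codes <- apply(bits, 1L, function(b) paste(as.integer(b), collapse = ""))
  split(gene_idx, codes)
}

#' Within-bucket nearest neighbours by cosine distance
#'
#' For each gene of a bucket, the up-to-`n_neighbors` nearest co-members by
#' cosine distance (1 - cosine similarity). Buckets smaller than
#' `n_neighbors + 1` return all co-members. All-zero gene profiles have
#' undefined cosine distance and are treated as maximally distant
#' (distance 1). Ties break by ascending gene index.
#'
#' @param bucket integer vector of gene indices.
#' @param m a `norm_matrix`.
#' @param n_neighbors neighbours per gene.
#' @return Named list (by gene index) of integer neighbour vectors.
#' @export
bucket_knn <- function(bucket, m, n_neighbors = 5) {
  stopifnot(length(bucket) >= 1)
  nb <- setNames(vector("list", length(bucket)), as.character(bucket))
  if (length(bucket) == 1L) { nb[[1]] <- integer(0); return(nb) }
  v <- m$values[, bucket, drop = FALSE]
  nrm <- sqrt(colSums(v^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  vn <- sweep(v, 2L, nrm, "/")
  d <- 1 - crossprod(vn)                 # cosine distance, genes x genes
  d[zero, ] <- 1; d[, zero] <- 1         # zero vectors: maximally distant
  if (any(zero))
    message(sum(zero), " all-zero gene profile(s) in bucket treated as ",
            "maximally distant")
  k <- min(n_neighbors, length(bucket) - 1L)
  for (i in seq_along(bucket)) {
    ord <- order(d[i, ], seq_along(bucket))  # ties by ascending position
    ord <- ord[ord != i][seq_len(k)]
    nb[[i]] <- bucket[ord]
  }
  nb
}

#' Greedy neighbour-discarding gene selection
#'
#' Genes are visited sequentially in the order they appear in the original
#' dataset. A visited gene that has not been discarded is added to the
#' selected list and its nearest neighbours are discarded; a visited gene
#' that was already discarded is skipped, but its neighbours are discarded
#' too. Deterministic given the neighbour lists and visit order.
#'
#' @param knn named list mapping gene index (as character) to integer
#'   neighbour vector, as from [bucket_knn()].
#' @param visit_order integer vector: genes in original dataset order.
#' @return Integer vector of selected gene indices, in visit order.
#' @export
greedy_select <- function(knn, visit_order) {
  discarded <- logical(max(visit_order))
  selected <- logical(max(visit_order))
  for (g in visit_order) {
    nbrs <- knn[[as.character(g)]]
    if (discarded[g]) {
      if (length(nbrs)) discarded[nbrs] <- TRUE
    } else {
      selected[g] <- TRUE
      if (length(nbrs)) discarded[nbrs[!selected[nbrs]]] <- TRUE
    }
  }
  visit_order[selected[visit_order]]
}

#' Structure-preserving gene sub-sampling
#'
#' Composes [hash_genes()], [bucket_knn()] and [greedy_select()];
#' `cfg$iterations` applies the whole procedure recursively to the surviving
#' set (each pass draws fresh hyperplanes from the seeded stream). If
#' `target_genes` is given, passes repeat until the selection is no larger
#' than the target or stops shrinking, then the list is truncated in visit
#' order. A pass whose surviving set no longer exceeds `2^n_bits` stops the
#' recursion with a message rather than failing.
#'
#' @param m a `norm_matrix`.
#' @param cfg an [lsh_config()].
#' @param target_genes optional cap on the number of selected genes.
#' @return An object of class `gene_subset`: `selected` (ordered integer
#'   indices into `m`), `buckets` (first-pass partition, diagnostic),
#'   `n_iterations` actually run.
#' @export
sample_features <- function(m, cfg, target_genes = NULL) {
  stopifnot(inherits(m, "norm_matrix"), inherits(cfg, "lsh_config"))
  set.seed(cfg$seed)
  current <- seq_len(ncol(m$values))
  buckets1 <- NULL
  iters_done <- 0L
  max_pass <- if (is.null(target_genes)) cfg$iterations else 100L
  repeat {
    if (iters_done >= max_pass) break
    if (!is.null(target_genes) && length(current) <= target_genes &&
        iters_done >= cfg$iterations) break
    if (length(current) <= 2^cfg$n_bits) {
      if (iters_done == 0L)
        stop("number of genes (", length(current), ") must exceed 2^n_bits = ",
             2^cfg$n_bits, "; lower n_bits")
      message("surviving gene set (", length(current),
              ") no longer exceeds 2^n_bits; stopping after ", iters_done,
              " pass(es)")
      break
    }
    buckets <- hash_genes(m, cfg, gene_idx = current)
    if (is.null(buckets1)) buckets1 <- buckets
    knn <- list()
    for (b in buckets)
      knn <- c(knn, bucket_knn(b, m, cfg$n_neighbors))
    sel <- greedy_select(knn, sort(current))
    iters_done <- iters_done + 1L
    if (length(sel) == length(current)) { current <- sel; break }
    current <- sel
  }
  if (!is.null(target_genes) && length(current) > target_genes)
    current <- sort(current)[seq_len(target_genes)]
  structure(list(selected = sort(current), buckets = buckets1,
                 n_iterations = iters_done),
            class = "gene_subset")
}

#' @export
print.gene_subset <- function(x, ...) {
  cat("gene_subset:", length(x$selected), "genes selected after",
      x$n_iterations, "LSH pass(es);", length(x$buckets),
      "first-pass buckets\n")
  invisible(x)
}
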