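#' k-means clustering of a cell embedding
#'
#' k-means++ seeding followed by Lloyd iterations (via [stats::kmeans()]),
#' repeated `restarts` times; the labeling with the best (lowest) total
#' within-cluster sum of squares wins. Deterministic given `seed`.
#'
#' @param Z an `embedding` or numeric matrix (cells x dims).
#' @param K number of clusters, `2 <= K <= n`.
#' @param seed RNG seed.
#' @param restarts independent initializations (default 10).
#' @return Integer vector of cluster labels in `1..K` (named by cell id when
#'   available).
#' @export
kmeans_cluster <- function(Z, K, seed = 1, restarts = 10) {
  z <- if (inherits(Z, "embedding")) Z$Z else as.matrix(Z)
  n <- nrow(z)
  if (K > n) stop("K (", K, ") exceeds the number of cells (", n, ")")
  if (K < 1) stop("K must be >= 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_init(z, K)
    km <- suppressWarnings(
      kmeans(z, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- best$cluster
  ids <- if (inherits(Z, "embedding") && !is.null(Z$cell_ids)) Z$cell_ids
         else rownames(z)
  if (!is.null(ids)) names(labels) <- ids
  labels
}

# k-means++ center selection: first uniform, then proportional to squared
# distance to the nearest chosen center
.kmeanspp_init <- function(z, K) {
  n <- nrow(z)
  centers <- matrix(NA_real_, K, ncol(z))
  idx <- sample.int(n, 1)
  centers[1, ] <- z[idx, ]
  if (K == 1) return(centers)
  d2 <- rowSums((z - matrix(centers[1, ], n, ncol(z), byrow = TRUE))^2)
  for (k in 2:K) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[k, ] <- z[idx, ]
    d2k <- rowSums((z - matrix(centers[k, ], n, ncol(z), byrow = TRUE))^2)
    d2 <- pmin(d2, d2k)
  }
  centers
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting formula on the contingency table.
#' Equals 1 iff the partitions are identical (up to label names), has
#' expectation ~0 for independent random labelings, and can be negative.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI, a single number `<= 1`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Average silhouette width of a clustering
#'
#' Mean over cells of \eqn{(b - a)/\max(a, b)} where a is the mean
#' within-cluster distance and b the smallest mean distance to another
#' cluster (Euclidean). Cells in singleton clusters score 0. Delegates to
#' [cluster::silhouette()].
#'
#' @param Z an `embedding` or numeric matrix.
#' @param labels cluster labels (>= 2 distinct values).
#' @return Average silhouette width in `[-1, 1]`.
#' @export
silhouette_width <- function(Z, labels) {
  z <- if (inherits(Z, "embedding")) Z$Z else as.matrix(Z)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  sil <- cluster::silhouette(labels, dist(z))
  mean(sil[, "sil_width"])
}

#' Topology-preservation score of an embedding
#'
#' Treats the k-NN graph of the high-dimensional data as the ground-truth
#' edge labeling over all node pairs and the k-NN graph of the embedding as
#' the prediction; the score is the KL divergence KL(P, Q) of the predicted
#' edge distribution from the reference. With binary P and the exact-match
#' convention (pairs where the two graphs agree contribute zero), each
#' mismatched pair contributes `log(1/epsilon)`, so `kl = 0` iff the two
#' graphs coincide and the score grows with the number of disagreements.
#'
#' For large n the non-edges may be uniformly subsampled
#' (`negative_subsample`); the negative term is then rescaled by
#' `n_nonedges / subsample`.
#'
#' @param X_highdim numeric matrix, cells x features (reference space).
#' @param Z an `embedding` or numeric matrix with the same rows.
#' @param k_ref neighbours for both k-NN graphs (default 5).
#' @param epsilon smoothing probability in (0, 0.5) for mismatched pairs
#'   (default 1e-4).
#' @param negative_subsample `"all"` (default) or an integer count of
#'   non-edges to sample.
#' @param seed RNG seed for the subsample.
#' @return An object of class `topology_report`: `kl`, `n_ref_edges`,
#'   `k_ref`, `epsilon`, `negative_subsample`, `n_mismatch`.
#' @export
topology_kl <- function(X_highdim, Z, k_ref = 5, epsilon = 1e-4,
                        negative_subsample = "all", seed = 1) {
  z <- if (inherits(Z, "embedding")) Z$Z else as.matrix(Z)
  x <- as.matrix(X_highdim)
  if (nrow(x) != nrow(z)) stop("X_highdim and Z must have the same cells")
  if (!(epsilon > 0 && epsilon < 0.5)) stop("epsilon must lie in (0, 0.5)")
  n <- nrow(x)
  if (k_ref >= n) stop("k_ref must be smaller than the number of cells")
  ex <- .knn_union(as.matrix(dist(x)), k_ref, decreasing = FALSE)$edges
  ez <- .knn_union(as.matrix(dist(z)), k_ref, decreasing = FALSE)$edges
  key <- function(e) (e[, 1] - 1) * n + e[, 2]
  kx <- key(ex); kz <- key(ez)
  pos_miss <- sum(!(kx %in% kz))            # reference edges not predicted
  penalty <- log(1 / epsilon)
  n_pairs <- n * (n - 1) / 2
  n_neg <- n_pairs - length(kx)
  if (identical(negative_subsample, "all")) {
    neg_miss <- sum(!(kz %in% kx))          # predicted edges not in reference
    kl <- (pos_miss + neg_miss) * penalty
    n_mismatch <- pos_miss + neg_miss
  } else {
    m <- as.integer(negative_subsample)
    stopifnot(m >= 1)
    set.seed(seed)
    samp <- integer(0)                      # sample non-edges of reference
    while (length(samp) < m) {
      i <- sample.int(n, 2 * m, replace = TRUE)
      j <- sample.int(n, 2 * m, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      k2 <- (lo[lo != hi] - 1) * n + hi[lo != hi]
      samp <- unique(c(samp, k2[!(k2 %in% kx)]))
    }
    samp <- samp[seq_len(m)]
    neg_rate <- sum(samp %in% kz) / m
    kl <- pos_miss * penalty + neg_rate * n_neg * penalty
    n_mismatch <- pos_miss + neg_rate * n_neg
  }
  structure(list(kl = kl, n_ref_edges = length(kx), k_ref = k_ref,
                 epsilon = epsilon, negative_subsample = negative_subsample,
                 n_mismatch = n_mismatch),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("topology_report: KL = %.4g (%g mismatched pairs, k = %d, eps = %g)\n",
              x$kl, x$n_mismatch, x$k_ref, x$epsilon))
  invisible(x)
}

#' Kendall correlation between high- and low-dimensional cell distances
#'
#' Computes the Euclidean distance between every pair of cells in the
#' original space and in the embedding, and returns the Kendall tau between
#' the two distance vectors. Equals 1 for any embedding that is a rigid
#' transform (rotation/reflection/translation) plus uniform scaling of the
#' original data; near 0 for an unrelated embedding.
#'
#' @param X_highdim numeric matrix (cells x features).
#' @param Z an `embedding` or numeric matrix with the same cells.
#' @return Kendall tau in `[-1, 1]`.
#' @export
distance_preservation_tau <- function(X_highdim, Z) {
  z <- if (inherits(Z, "embedding")) Z$Z else as.matrix(Z)
  x <- as.matrix(X_highdim)
  if (nrow(x) != nrow(z)) stop("X_highdim and Z must have the same cells")
  if (nrow(x) < 3) stop("need at least 3 cells")
  kendall_tau(as.numeric(dist(x)), as.numeric(dist(z)))
}

#' Per-cluster marker genes by Wilcoxon rank-sum test
#'
#' For every cluster, each gene is tested cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test (tie-corrected normal approximation). Genes with
#' `p < alpha` are kept, ranked per cluster by the (signed) z statistic in
#' descending order — over-expressed markers first — and truncated to
#' `top_n`. P-values are unadjusted by default, matching the common
#' `p < 0.05` marker convention; `adjust = "BH"` applies
#' Benjamini-Hochberg within each cluster.
#'
#' @param m a `norm_matrix`.
#' @param labels cluster labels, one per cell (>= 2 clusters).
#' @param alpha significance threshold on the (possibly adjusted) p-value
#'   (default 0.05).
#' @param top_n markers kept per cluster (default 50).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` with columns `cluster`, `gene`, `statistic` (z),
#'   `p_value`, `rank`. Clusters of size 1 are skipped with a warning.
#' @export
find_markers <- function(m, labels, alpha = 0.05, top_n = 50,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(m, "norm_matrix"))
  labels <- as.vector(labels)
  if (length(labels) != nrow(m$values))
    stop("labels length does not match the number of cells")
  grp <- unique(labels)
  if (length(grp) < 2) stop("need at least 2 clusters")
  v <- m$values
  n <- nrow(v)
  # column-wise average ranks + tie correction term sum(t^3 - t) per gene
  rk <- apply(v, 2, rank, ties.method = "average")
  tie_term <- apply(v, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  out <- vector("list", length(grp))
  for (gi in seq_along(grp)) {
    in_g <- labels == grp[gi]
    n1 <- sum(in_g); n2 <- n - n1
    if (n1 < 2) {
      warning("cluster ", grp[gi], " has fewer than 2 cells; skipped")
      next
    }
    r1 <- colSums(rk[in_g, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(sig2 > 0, (u - mu) / sqrt(sig2), 0)
    p <- 2 * pnorm(-abs(z))
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    keep <- which(p < alpha)
    if (!length(keep)) next
    ord <- keep[order(-z[keep], keep)]
    ord <- ord[seq_len(min(top_n, length(ord)))]
    out[[gi]] <- data.frame(cluster = grp[gi], gene = m$gene_ids[ord],
                            statistic = z[ord], p_value = p[ord],
                            rank = seq_along(ord), row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster = character(0), gene = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      rank = integer(0))
  res
}
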