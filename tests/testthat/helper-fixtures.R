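# programmatic fixtures shared across test files

# small count matrix with deterministic entries
toy_counts <- function(n_cells = 4, n_genes = 3, seed = 1) {
  set.seed(seed)
  count_matrix(matrix(rpois(n_cells * n_genes, 4), n_cells, n_genes))
}

# norm_matrix straight from a numeric matrix (bypasses count validation;
# lets tests plant arbitrary gene profiles, including negatives)
as_norm <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  scCopulaGCN:::.norm_matrix(values, cell_ids, gene_ids,
                             provenance = list(transform = "test"))
}

# 2-block planted-partition graph; returns graph and block labels
make_planted_partition <- function(n = 200, pin = 0.3, pout = 0.02,
                                   seed = 1) {
  set.seed(seed)
  blk <- rep(1:2, each = n / 2)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(blk[ut[, 1]] == blk[ut[, 2]], pin, pout)
  keep <- runif(nrow(ut)) < p
  list(graph = cell_graph(n, ut[keep, , drop = FALSE]), blocks = blk)
}

# two disjoint dense cliques of size m each, with edge probability p_in
make_two_cliques <- function(m = 30, p_in = 1.0, seed = 1) {
  make_planted_partition(2 * m, pin = p_in, pout = 0, seed = seed)
}

# gaussian blob embedding with planted groups
make_blobs <- function(n_per = 30, d = 5, sep = 6, seed = 1) {
  set.seed(seed)
  z <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(Z = z, labels = rep(1:2, each = n_per))
}

# run the complete workflow in memory on a simulation, with QC thresholds
# scaled to the 2000-gene panel; returns everything the evaluation needs
run_workflow <- function(sim, seed, lsh_bits = 10) {
  filt <- filter_cells_genes(sim$counts, min_genes_per_cell = 100,
                             min_count = 1, min_cell_frac = 0.05)
  labs <- sim$true_labels[match(filt$cell_ids, sim$counts$cell_ids)]
  norm <- normalize_log(filt)
  sel <- sample_features(norm, lsh_config(n_bits = lsh_bits, seed = seed))
  cc <- ccor_matrix(norm, sel)
  g <- build_knn_graph(cc, k = 5)
  sp <- split_edges(g, seed = seed)
  fit <- train_gae(g, gcn_params(seed = seed), sp)
  K <- length(unique(labs))
  km <- kmeans_cluster(fit$embedding, K, seed = seed)
  list(norm = norm, selected = sel, graph = g, fit = fit,
       labels = km, true_labels = labs, K = K)
}
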