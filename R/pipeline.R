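#' Pipeline configuration
#'
#' All tunable parameters of the full workflow in one flat record. Defaults
#' follow the method's standard settings: LSH 10 bits / 5 neighbours /
#' 1 iteration, empirical-tau Ccor (Clayton theta -0.5 for the diagnostic
#' mode), 5-NN cell graph, GCN dims 256/128/128 trained 50 epochs with Adam
#' (lr 0.001, dropout 0.1) on an 8:1:1 edge split. QC filter thresholds
#' default to the whole-transcriptome values and should be scaled down for
#' small gene panels or simulations.
#'
#' @param ... overrides of the defaults listed in the function definition.
#' @param seed single global seed; each stage derives its own seed from it
#'   deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  cfg <- list(
    min_genes_per_cell = 1000, min_count = 5, min_cell_frac = 0.10,
    norm_method = "size_factor",
    lsh_bits = 10, lsh_neighbors = 5, lsh_iters = 1, target_genes = NA,
    ccor_mode = "empirical_tau", theta = -0.5, graph_k = 5,
    dims = c(256, 128, 128), epochs = 50, lr = 0.001, dropout = 0.1,
    split_ratios = c(0.8, 0.1, 0.1),
    k_clusters = NA, kmeans_restarts = 10,
    alpha = 0.05, top_n = 50, topo_k = 5, epsilon = 1e-4,
    seed = as.integer(seed))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' Flat JSON mirroring the [pipeline_config()] fields; `parse -> serialize`
#' round-trips to the canonical form.
#'
#' @param cfg a `pipeline_config`.
#' @param path JSON file.
#' @return `read_config()`: a `pipeline_config`; `write_config()`: `path`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$target_genes <- if (is.null(raw$target_genes)) NA else raw$target_genes
  raw$k_clusters <- if (is.null(raw$k_clusters)) NA else raw$k_clusters
  seed <- raw$seed
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

#' Run the full clustering workflow
#'
#' Preprocess -> LSH gene sampling -> Ccor cell graph -> GCN autoencoder
#' embedding -> k-means clustering -> evaluation, writing every stage output
#' plus a manifest into `out_dir`. Reruns with the same config and input
#' reproduce all artifacts byte-identically.
#'
#' When `true_labels` is supplied (or `input` is a `sim_result`), ARI
#' against the known labels is reported and `k_clusters` defaults to the
#' number of distinct labels; otherwise a silhouette-maximizing sweep over
#' K in 2..15 picks K, and the label-dependent metrics are skipped.
#'
#' @param input a [count_matrix()], a [simulate_counts()] result, or a path
#'   readable by [read_counts()].
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param true_labels optional known labels for evaluation.
#' @param verbose print per-stage progress.
#' @return `out_dir`, invisibly; the written `report.json` holds `ari`,
#'   `asw`, `topology_kl`, `distance_tau` and the link-prediction scores,
#'   and `manifest.json` lists every stage output with its md5 hash.
#' @export
run_pipeline <- function(input, cfg = pipeline_config(), out_dir,
                         true_labels = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[", Sys.time(), "] ", ...)
  stage_files <- character(0)
  add <- function(f) stage_files <<- c(stage_files, f)

  if (inherits(input, "sim_result")) {
    if (is.null(true_labels)) true_labels <- input$true_labels
    input <- input$counts
  } else if (is.character(input)) {
    input <- read_counts(input)
  }
  stopifnot(inherits(input, "count_matrix"))

  say("stage 1/6 preprocess: ", nrow(input$values), " cells x ",
      ncol(input$values), " genes")
  filt <- filter_cells_genes(input, cfg$min_genes_per_cell, cfg$min_count,
                             cfg$min_cell_frac)
  if (!is.null(true_labels)) {
    if (length(true_labels) != length(input$cell_ids))
      stop("true_labels length does not match the input cells")
    true_labels <- true_labels[match(filt$cell_ids, input$cell_ids)]
  }
  norm <- normalize_log(filt, method = cfg$norm_method)
  write_counts(filt, file.path(out_dir, "filtered_counts.tsv"))
  add("filtered_counts.tsv")

  say("stage 2/6 lsh sampling: ", ncol(norm$values), " genes")
  lcfg <- lsh_config(cfg$lsh_bits, cfg$lsh_neighbors, cfg$lsh_iters,
                     seed = .stage_seed(cfg$seed, 2))
  subset <- sample_features(norm, lcfg,
                            target_genes = if (is.na(cfg$target_genes)) NULL
                                           else cfg$target_genes)
  writeLines(norm$gene_ids[subset$selected],
             file.path(out_dir, "selected_genes.txt"))
  add("selected_genes.txt")
  jsonlite::write_json(
    table(lengths(subset$buckets)) |> as.list(),
    file.path(out_dir, "bucket_histogram.json"), auto_unbox = TRUE)
  add("bucket_histogram.json")

  say("stage 3/6 ccor graph: ", length(subset$selected), " selected genes")
  cc <- ccor_matrix(norm, subset, mode = cfg$ccor_mode)
  graph <- build_knn_graph(cc, k = cfg$graph_k)
  write_edges(graph, file.path(out_dir, "edges.tsv"))
  add("edges.tsv")

  say("stage 4/6 gcn embedding: ", graph$n_nodes, " nodes, ",
      nrow(graph$edges), " edges")
  split <- split_edges(graph, cfg$split_ratios,
                       seed = .stage_seed(cfg$seed, 4))
  params <- gcn_params(cfg$dims, cfg$dropout, cfg$lr, cfg$epochs,
                       seed = .stage_seed(cfg$seed, 4))
  fit <- train_gae(graph, params, split)
  write_embedding(fit$embedding, file.path(out_dir, "embedding.tsv"))
  add("embedding.tsv")

  say("stage 5/6 clustering")
  K <- cfg$k_clusters
  if (is.na(K)) {
    if (!is.null(true_labels)) {
      K <- length(unique(true_labels))
    } else {
      sweep_k <- 2:min(15, graph$n_nodes - 1)
      asw_k <- vapply(sweep_k, function(k) {
        lab <- kmeans_cluster(fit$embedding, k,
                              seed = .stage_seed(cfg$seed, 5),
                              restarts = cfg$kmeans_restarts)
        silhouette_width(fit$embedding, lab)
      }, numeric(1))
      K <- sweep_k[which.max(asw_k)]
      say("  silhouette sweep chose K = ", K)
    }
  }
  labels <- kmeans_cluster(fit$embedding, K, seed = .stage_seed(cfg$seed, 5),
                           restarts = cfg$kmeans_restarts)
  write.table(data.frame(cell_id = norm$cell_ids, cluster = labels),
              file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add("labels.tsv")

  say("stage 6/6 evaluation")
  nsub <- if (graph$n_nodes > 2000) 200000L else "all"
  topo <- topology_kl(norm$values, fit$embedding, k_ref = cfg$topo_k,
                      epsilon = cfg$epsilon, negative_subsample = nsub,
                      seed = .stage_seed(cfg$seed, 6))
  dtau <- distance_preservation_tau(norm$values, fit$embedding)
  report <- list(
    n_cells = graph$n_nodes, n_genes_filtered = ncol(norm$values),
    n_genes_selected = length(subset$selected),
    n_edges = nrow(graph$edges), k_clusters = K,
    asw = silhouette_width(fit$embedding, labels),
    topology_kl = topo$kl, distance_tau = dtau,
    linkpred = fit$report)
  if (!is.null(true_labels)) report$ari <- ari(labels, true_labels)
  markers <- find_markers(norm, labels, alpha = cfg$alpha, top_n = cfg$top_n)
  write.table(markers, file.path(out_dir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add("markers.tsv")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add("report.json")

  write_config(cfg, file.path(out_dir, "config.json"))
  manifest <- list(
    config = unclass(cfg),
    stages = stage_files,
    hashes = as.list(tools::md5sum(file.path(out_dir, stage_files))))
  names(manifest$hashes) <- stage_files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", out_dir)
  invisible(out_dir)
}
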