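#' Specification for a grouped scRNA-seq count simulation
#'
#' A minimal splatter-style generative model: gene baseline means are drawn
#' from a Gamma distribution, each group up-regulates or down-regulates a
#' `de_prop` fraction of genes by a lognormal fold-change with random sign,
#' cell library sizes are lognormal multipliers, counts are Poisson around
#' the scaled group means, and technical dropout zeroes entries with a
#' probability logistic in the negative log mean, calibrated by bisection so
#' the expected excess-zero fraction equals `dropout_rate`.
#'
#' @param n_cells number of cells.
#' @param n_groups number of groups (>= 1); `n_cells >= n_groups`.
#' @param n_genes number of genes (default 2000).
#' @param group_probs group membership probabilities (default equal).
#' @param de_prop fraction of genes differentially expressed per group
#'   (default 0.4).
#' @param de_logfc_scale median |log fold-change| of DE genes (default 1.0;
#'   magnitudes are LogNormal(log(scale), 0.4) with random sign).
#' @param dropout_rate expected excess-zero fraction added by dropout on top
#'   of Poisson sampling zeros (default 0.2).
#' @param mean_shape,mean_rate Gamma hyperparameters of baseline gene means
#'   (defaults 0.6 and 0.3).
#' @param libsize_logmean,libsize_logsd lognormal parameters of the per-cell
#'   library-size factor (defaults 0 and 0.25; a relative multiplier).
#' @param seed RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_cells, n_groups, n_genes = 2000,
                     group_probs = NULL, de_prop = 0.4,
                     de_logfc_scale = 1.0, dropout_rate = 0.2,
                     mean_shape = 0.6, mean_rate = 0.3,
                     libsize_logmean = 0, libsize_logsd = 0.25, seed = 1) {
  bad <- function(msg) stop("invalid sim_spec: ", msg)
  if (n_groups < 1) bad("n_groups must be >= 1")
  if (n_cells < n_groups) bad("n_cells must be >= n_groups")
  if (is.null(group_probs)) group_probs <- rep(1 / n_groups, n_groups)
  if (length(group_probs) != n_groups) bad("group_probs length != n_groups")
  if (abs(sum(group_probs) - 1) > 1e-8) bad("group_probs must sum to 1")
  if (any(group_probs < 0)) bad("group_probs must be nonnegative")
  if (de_prop < 0 || de_prop > 1) bad("de_prop must lie in [0, 1]")
  if (dropout_rate < 0 || dropout_rate >= 1) bad("dropout_rate must lie in [0, 1)")
  if (de_logfc_scale <= 0) bad("de_logfc_scale must be > 0")
  if (mean_shape <= 0 || mean_rate <= 0) bad("gamma hyperparameters must be > 0")
  if (libsize_logsd < 0) bad("libsize_logsd must be >= 0")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_groups = as.integer(n_groups), group_probs = group_probs,
                 de_prop = de_prop, de_logfc_scale = de_logfc_scale,
                 dropout_rate = dropout_rate, mean_shape = mean_shape,
                 mean_rate = mean_rate, libsize_logmean = libsize_logmean,
                 libsize_logsd = libsize_logsd, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a grouped scRNA-seq-like count matrix
#'
#' Draws from the generative model described in [sim_spec()] and returns the
#' counts together with the planted ground truth (labels, DE gene sets, log
#' fold-changes), so downstream clustering and marker detection can be
#' scored offline.
#'
#' @param spec a [sim_spec()].
#' @return An object of class `sim_result`: `counts` (a [count_matrix()]),
#'   `true_labels` (integer 1..K), `de_genes` (list of per-group gene-index
#'   vectors), `true_logfc` (genes x groups natural-log fold-changes),
#'   `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; G <- spec$n_genes; K <- spec$n_groups
  base <- rgamma(G, shape = spec$mean_shape, rate = spec$mean_rate)
  base <- pmax(base, 1e-8)
  labels <- sample.int(K, n, replace = TRUE, prob = spec$group_probs)
  logfc <- matrix(0, G, K)
  de_genes <- vector("list", K)
  n_de <- round(spec$de_prop * G)
  for (k in seq_len(K)) {
    idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
    de_genes[[k]] <- idx
    if (length(idx)) {
      mag <- rlnorm(length(idx), meanlog = log(spec$de_logfc_scale),
                    sdlog = 0.4)
      logfc[idx, k] <- sample(c(-1, 1), length(idx), replace = TRUE) * mag
    }
  }
  lib <- rlnorm(n, spec$libsize_logmean, spec$libsize_logsd)
  mu <- (lib * exp(logfc[, labels, drop = FALSE] |> t())) *
    matrix(base, n, G, byrow = TRUE)
  counts <- matrix(rpois(n * G, lambda = mu), n, G)
  if (spec$dropout_rate > 0) {
    x0 <- .calibrate_dropout(mu, spec$dropout_rate)
    p_drop <- 1 / (1 + exp(log(mu) - x0))
    counts[runif(n * G) < p_drop] <- 0L
  }
  cm <- count_matrix(counts,
                     cell_ids = sprintf("cell%0*d", nchar(n), seq_len(n)),
                     gene_ids = sprintf("gene%0*d", nchar(G), seq_len(G)))
  structure(list(counts = cm, true_labels = labels, de_genes = de_genes,
                 true_logfc = logfc, spec = spec),
            class = "sim_result")
}

# bisection on the logistic midpoint so that the expected excess-zero
# fraction E[p_drop(mu) * (1 - P(Poisson(mu) = 0))] equals `rate`
.calibrate_dropout <- function(mu, rate) {
  lmu <- log(mu)
  nonzero <- 1 - exp(-mu)
  excess <- function(x0) mean(nonzero / (1 + exp(lmu - x0))) - rate
  lo <- -30; hi <- 30
  if (excess(hi) < 0) return(hi)  # rate unreachable; drop as much as possible
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (excess(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", x$spec$n_cells, "cells x", x$spec$n_genes, "genes,",
      x$spec$n_groups, "groups; zero fraction",
      sprintf("%.2f\n", mean(x$counts$values == 0)))
  invisible(x)
}

#' The four-benchmark simulation series
#'
#' Four grouped simulations of increasing size — 500 cells / 2 groups,
#' 1000 / 3, 1500 / 4 and 2000 / 5 — all with 2000 genes, equal group
#' probabilities, 0.2 dropout rate and 40% DE gene proportion, under
#' distinct fixed seeds.
#'
#' @param seeds four RNG seeds (defaults 101:104).
#' @return List of four [simulate_counts()] results.
#' @export
simulate_dataset_series <- function(seeds = c(101L, 102L, 103L, 104L)) {
  stopifnot(length(seeds) == 4)
  cells <- c(500L, 1000L, 1500L, 2000L)
  groups <- c(2L, 3L, 4L, 5L)
  lapply(seq_len(4), function(i)
    simulate_counts(sim_spec(n_cells = cells[i], n_groups = groups[i],
                             n_genes = 2000, de_prop = 0.4,
                             dropout_rate = 0.2, seed = seeds[i])))
}
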