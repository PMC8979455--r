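test_that("edge split is an 8:1:1 partition keeping all nodes trainable", {
  pp <- make_planted_partition(40, 0.5, 0.1, seed = 6)
  g <- pp$graph
  ne <- nrow(g$edges)
  sp <- split_edges(g, seed = 3)
  expect_equal(nrow(sp$val_edges), floor(0.1 * ne))
  expect_equal(nrow(sp$test_edges), floor(0.1 * ne))
  expect_equal(nrow(sp$train_edges) + nrow(sp$val_edges) +
                 nrow(sp$test_edges), ne)
  # partition: no overlap, union = original
  key <- function(e) paste(e[, 1], e[, 2])
  all_back <- c(key(sp$train_edges), key(sp$val_edges), key(sp$test_edges))
  expect_setequal(all_back, key(g$edges))
  expect_equal(anyDuplicated(all_back), 0L)
  # every node keeps a training edge
  expect_setequal(unique(c(sp$train_edges)), 1:40)
  # negatives are non-edges, disjoint between val and test
  expect_false(any(key(sp$val_neg) %in% key(g$edges)))
  expect_false(any(key(sp$test_neg) %in% key(g$edges)))
  expect_false(any(key(sp$val_neg) %in% key(sp$test_neg)))
  # determinism
  sp2 <- split_edges(g, seed = 3)
  expect_identical(sp, sp2)
  # exact 100-edge case -> 80/10/10
  g100 <- cell_graph(30, t(combn(15, 2))[1:100, ])
  s100 <- split_edges(g100, seed = 1)
  expect_equal(c(nrow(s100$train_edges), nrow(s100$val_edges),
                 nrow(s100$test_edges)), c(80L, 10L, 10L))
  expect_error(split_edges(cell_graph(5, rbind(c(1, 2), c(2, 3)))),
               "fewer than 10")
})

test_that("normalized adjacency matches closed forms and spectral bounds", {
  g2 <- cell_graph(2, rbind(c(1, 2)))
  expect_equal(normalize_adjacency(g2), matrix(0.5, 2, 2))
  g1 <- cell_graph(1, matrix(integer(0), 0, 2))
  expect_equal(normalize_adjacency(g1), matrix(1, 1, 1))
  # 4-cycle: 2-regular, hat degree 3 -> rows sum to 1
  g4 <- cell_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  An <- normalize_adjacency(g4)
  expect_equal(rowSums(An), rep(1, 4))
  expect_true(isSymmetric(An))
  for (s in 1:3) {
    pp <- make_planted_partition(60, 0.2, 0.05, seed = s)
    ev <- eigen(normalize_adjacency(pp$graph), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("encoder: zero weights, twin nodes, permutation equivariance", {
  pp <- make_planted_partition(20, 0.6, 0.2, seed = 2)
  An <- normalize_adjacency(pp$graph)
  params <- gcn_params(layer_dims = c(8, 6, 4), seed = 1)
  W0 <- list(matrix(0, 20, 8), matrix(0, 8, 6), matrix(0, 6, 4))
  expect_true(all(gcn_encode(An, params, W0)$Z == 0))

  # twin nodes: 5 and 6 connected to the same others and to each other,
  # with identical (constant) features
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- 1
  a[5, 1] <- a[5, 2] <- a[6, 1] <- a[6, 2] <- a[5, 6] <- 1
  a <- pmax(a, t(a))
  g <- cell_graph(6, which(upper.tri(a) & a == 1, arr.ind = TRUE))
  An6 <- normalize_adjacency(g)
  X <- matrix(1, 6, 3)  # identical node features
  set.seed(5)
  W <- scCopulaGCN:::.init_gcn_weights(3, c(8, 6, 4))
  z <- gcn_encode(An6, gcn_params(c(8, 6, 4)), W, X = X)$Z
  expect_equal(z[5, ], z[6, ], tolerance = 1e-12)

  # permutation equivariance with identity features
  set.seed(6)
  Wn <- scCopulaGCN:::.init_gcn_weights(20, c(8, 6, 4))
  z1 <- gcn_encode(An, params, Wn)$Z
  p <- sample(20)
  z2 <- gcn_encode(An[p, p], params,
                   list(Wn[[1]][p, ], Wn[[2]], Wn[[3]]))$Z
  expect_equal(z2, z1[p, ], tolerance = 1e-10)
})

test_that("inner-product decoder is a symmetric sigmoid score", {
  z <- rbind(rep(0, 4), c(sqrt(log(3) / 4), sqrt(log(3) / 4),
                          sqrt(log(3) / 4), sqrt(log(3) / 4)),
             rnorm(4))
  expect_equal(inner_product_decode(z, 1, 2), 0.5)
  expect_equal(inner_product_decode(z, 1, 3), 0.5)
  expect_equal(inner_product_decode(z, 2, 2), 0.75)  # ||z||^2 = ln 3
  expect_equal(inner_product_decode(z, 2, 3), inner_product_decode(z, 3, 2))
  full <- inner_product_decode(z)
  expect_true(all(full > 0 & full < 1))
  expect_true(isSymmetric(full))
})

test_that("ROC and AP agree with independent references", {
  set.seed(21)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  expect_equal(roc_auc(pos, neg), 1 - roc_auc(neg, pos))
  skip_if_not_installed("pROC")
  r <- pROC::roc(response = rep(c(1, 0), c(40, 60)),
                 predictor = c(pos, neg), quiet = TRUE)
  expect_equal(roc_auc(pos, neg), as.numeric(pROC::auc(r)), tolerance = 1e-12)
  # AP oracle: direct enumeration of precision at each positive
  sc <- c(pos, neg); y <- rep(c(1, 0), c(40, 60))
  ord <- order(-sc); ys <- y[ord]
  ap_ref <- mean((cumsum(ys) / seq_along(ys))[ys == 1])
  expect_equal(average_precision(pos, neg), ap_ref)
  expect_equal(roc_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(average_precision(c(2, 3), c(0, 1)), 1)
})

test_that("training separates two planted cliques and is deterministic", {
  pp <- make_two_cliques(30, p_in = 0.9, seed = 4)
  sp <- split_edges(pp$graph, seed = 4)
  rocs <- vapply(1:5, function(s) {
    fit <- train_gae(pp$graph, gcn_params(seed = s), sp)
    fit$report$test_roc
  }, numeric(1))
  expect_gte(median(rocs), 0.9)
  # determinism: identical loss trajectory bitwise
  f1 <- train_gae(pp$graph, gcn_params(seed = 11), sp)
  f2 <- train_gae(pp$graph, gcn_params(seed = 11), sp)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$embedding$Z, f2$embedding$Z)
  # soft monotonicity: loss decreases in >= 80% of epochs
  expect_gte(mean(diff(f1$loss) < 0), 0.8)
  # untrained baseline on an unstructured random graph: ROC near chance
  er <- make_planted_partition(60, 0.15, 0.15, seed = 9)  # Erdos-Renyi
  sper <- split_edges(er$graph, seed = 9)
  r0 <- vapply(1:5, function(s)
    train_gae(er$graph, gcn_params(epochs = 0, seed = s),
              sper)$report$test_roc, numeric(1))
  expect_lt(abs(mean(r0) - 0.5), 0.12)
})

test_that("link prediction on a planted partition reaches the block-oracle ROC", {
  res <- vapply(1:3, function(s) {
    pp <- make_planted_partition(200, 0.3, 0.02, seed = 200 + s)
    sp <- split_edges(pp$graph, seed = s)
    fit <- train_gae(pp$graph, gcn_params(seed = s), sp)
    blk <- pp$blocks
    bscore <- function(p) as.numeric(blk[p[, 1]] == blk[p[, 2]])
    oracle <- roc_auc(bscore(sp$test_edges), bscore(sp$test_neg))
    c(gae = fit$report$test_roc, oracle = oracle)
  }, numeric(2))
  # the learned model should be within a small margin of the true-block
  # oracle (the information ceiling for this graph family)
  expect_gte(median(res["gae", ]), 0.95 * median(res["oracle", ]))
  expect_gte(median(res["gae", ]), 0.70)
})

test_that("non-finite loss aborts with diagnostics", {
  pp <- make_two_cliques(10, p_in = 1, seed = 1)
  sp <- split_edges(pp$graph, seed = 1)
  expect_error(train_gae(pp$graph,
                         gcn_params(learning_rate = 1e160, seed = 1), sp),
               "non-finite loss|epoch", ignore.case = TRUE)
})
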