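test_that("k-means recovers planted blobs and is deterministic", {
  b <- make_blobs(n_per = 30, sep = 8, seed = 3)
  lab <- kmeans_cluster(b$Z, K = 2, seed = 1)
  expect_equal(ari(lab, b$labels), 1)
  expect_identical(lab, kmeans_cluster(b$Z, K = 2, seed = 1))
  # K = n: every cell its own cluster
  z <- matrix(rnorm(12), 6, 2)
  labn <- kmeans_cluster(z, K = 6, seed = 2, restarts = 3)
  expect_equal(length(unique(labn)), 6L)
  expect_error(kmeans_cluster(z, K = 7), "exceeds")
})

test_that("ARI: identity, relabeling invariance, hand-counted table, null", {
  a <- c(1, 1, 1, 2, 2, 2)
  expect_equal(ari(a, a), 1)
  expect_equal(ari(a, c(5, 5, 5, 9, 9, 9)), 1)   # renamed labels
  expect_error(ari(a, 1:3), "equal length")

  # contingency [[2,1],[1,2]]: brute-force pair counting oracle
  b <- c(1, 1, 2, 1, 2, 2)
  pairs <- t(combn(6, 2))
  same_a <- a[pairs[, 1]] == a[pairs[, 2]]
  same_b <- b[pairs[, 1]] == b[pairs[, 2]]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  ri <- (n11 + n00) / nrow(pairs)
  # expected RI under permutation model
  exp_ri <- (sum(same_a) * sum(same_b) +
             sum(!same_a) * sum(!same_b)) / nrow(pairs)^2
  ari_ref <- (ri - exp_ri) / (1 - exp_ri)
  expect_equal(ari(a, b), ari_ref)
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:10) {
    x <- sample(1:3, 40, replace = TRUE)
    y <- sample(1:4, 40, replace = TRUE)
    expect_equal(ari(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ARI of independent random labelings is centred on zero", {
  set.seed(11)
  vals <- replicate(200, ari(sample(1:3, 60, replace = TRUE),
                             sample(1:3, 60, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("silhouette: separated blobs, null labels, 4-point hand case", {
  b <- make_blobs(n_per = 25, sep = 40, seed = 5)
  expect_gt(silhouette_width(b$Z, b$labels), 0.95)
  set.seed(6)
  noise <- matrix(rnorm(200), 100, 2)
  s0 <- silhouette_width(noise, sample(1:2, 100, replace = TRUE))
  expect_lt(abs(s0), 0.1)
  # 1-D points 0, 1, 10, 11 in clusters {1,2}, {3,4}
  z <- matrix(c(0, 1, 10, 11), 4, 1)
  # point 1: a = 1, b = (10 + 11)/2 = 10.5 -> 9.5/10.5
  # point 2: a = 1, b = (9 + 10)/2 = 9.5 -> 8.5/9.5; symmetric others
  expected <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(silhouette_width(z, c(1, 1, 2, 2)), expected)
})

test_that("topology KL is zero iff the graphs match, with enumerated mismatches", {
  set.seed(9)
  x <- matrix(rnorm(20 * 6), 20, 6)
  r <- topology_kl(x, x, k_ref = 4)
  expect_equal(r$kl, 0)
  expect_equal(r$n_mismatch, 0)
  # scaling preserves the kNN graph exactly
  expect_equal(topology_kl(x, 3 * x, k_ref = 4)$kl, 0)

  # 4 nodes: reference edge {1,2} only vs embedding edge {3,4} only;
  # k = 1 graphs built from planted coordinates
  xx <- matrix(c(0, 0.1, 5, 9, 0, 0, 0, 0), 4, 2)  # 1-2 close, 3-4 apart
  zz <- matrix(c(0, 5, 9, 9.1, 0, 0, 0, 0), 4, 2)  # 3-4 close
  rx <- topology_kl(xx, zz, k_ref = 1, epsilon = 0.01)
  # reference graph: {1,2}, {3,4}; embedding graph: {3,4}, {1,2}? enumerate:
  # x kNN(1)=2, kNN(2)=1, kNN(3)=4? dist(3,4)=4 vs dist(3,2)=4.9 -> 4
  # so union graphs may share edges; check KL = n_mismatch * log(1/eps)
  expect_equal(rx$kl, rx$n_mismatch * log(1 / 0.01))
  expect_gte(rx$kl, 0)
  expect_error(topology_kl(x, x, epsilon = 0.7), "epsilon")
})

test_that("topology KL decreases as graph overlap increases", {
  # reference: 6 points on a line; move one point gradually away
  x <- matrix(c(1:6, rep(0, 6)), 6, 2)
  kls <- vapply(c(0, 2, 20), function(shift) {
    z <- x; z[6, 2] <- shift
    topology_kl(x, z, k_ref = 1)$kl
  }, numeric(1))
  expect_true(all(diff(kls) >= 0))
  expect_equal(kls[1], 0)
})

test_that("subsampled negatives approximate the exact KL", {
  set.seed(14)
  x <- matrix(rnorm(60 * 4), 60, 4)
  z <- x + matrix(rnorm(60 * 4, sd = 2), 60, 4)
  exact <- topology_kl(x, z, k_ref = 3)
  sub <- topology_kl(x, z, k_ref = 3, negative_subsample = 800L, seed = 2)
  expect_lt(abs(sub$kl - exact$kl) / exact$kl, 0.5)
  expect_equal(sub$n_ref_edges, exact$n_ref_edges)
})

test_that("distance preservation tau: isometries exact, null near zero, brute force", {
  set.seed(17)
  x <- matrix(rnorm(15 * 6), 15, 6)
  # rigid rotation (QR orthogonal factor) + uniform scaling + translation
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  z <- sweep(2.5 * (x %*% q), 2, rnorm(6), "+")
  expect_equal(distance_preservation_tau(x, z), 1)
  # unrelated gaussian embedding
  taus <- vapply(1:5, function(s) {
    set.seed(30 + s)
    distance_preservation_tau(x, matrix(rnorm(15 * 3), 15, 3))
  }, numeric(1))
  expect_lt(abs(median(taus)), 0.15)
  # 4 points: tau equals brute-force tau of the distance vectors
  x4 <- matrix(c(0, 1, 4, 9, 0, 2, 1, 5), 4, 2)
  z4 <- matrix(c(0, 2, 3, 1, 1, 0, 4, 2), 4, 2)
  expect_equal(distance_preservation_tau(x4, z4),
               kendall_tau_ref(as.numeric(dist(x4)), as.numeric(dist(z4))))
})

test_that("marker detection: planted marker tops the list, agrees with wilcox.test", {
  set.seed(19)
  n <- 30
  v <- matrix(abs(rnorm(n * 20)), n, 20)
  labels <- rep(1:2, each = 15)
  v[labels == 1, 7] <- v[labels == 1, 7] + 10   # exclusive to cluster 1
  v[labels == 2, 7] <- 0
  m <- as_norm(v)
  mk <- find_markers(m, labels, alpha = 0.05, top_n = 5)
  top1 <- mk[mk$cluster == 1 & mk$rank == 1, ]
  expect_equal(top1$gene, "g7")
  expect_lt(top1$p_value, 0.05)
  # z and p agree with the base-R normal-approximation test per gene
  for (j in c(1, 7, 12)) {
    wt <- wilcox.test(v[labels == 1, j], v[labels == 2, j],
                      exact = FALSE, correct = FALSE)
    row <- mk[mk$cluster == 1 & mk$gene == paste0("g", j), ]
    if (nrow(row) == 1) expect_equal(row$p_value, wt$p.value,
                                     tolerance = 1e-10)
  }
  # identical distributions: mostly excluded at alpha
  expect_error(find_markers(m, rep(1, n)), "at least 2 clusters")
})

test_that("marker p-values are uniform under the null", {
  set.seed(23)
  n <- 40
  v <- matrix(rnorm(n * 60), n, 60)
  labels <- rep(1:2, each = 20)
  m <- as_norm(v)
  mk <- find_markers(m, labels, alpha = 1.0000001, top_n = 60)
  p1 <- mk$p_value[mk$cluster == 1]
  expect_equal(length(p1), 60L)
  ks <- suppressWarnings(ks.test(p1, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment and small-cluster warnings behave", {
  set.seed(25)
  v <- matrix(rnorm(21 * 10), 21, 10)
  m <- as_norm(v)
  labels <- c(rep(1, 10), rep(2, 10), 3)
  expect_warning(mk <- find_markers(m, labels), "fewer than 2")
  mkbh <- suppressWarnings(find_markers(m, labels, alpha = 1.00001,
                                        adjust = "BH"))
  raw <- suppressWarnings(find_markers(m, labels, alpha = 1.00001))
  expect_true(all(mkbh$p_value >= raw$p_value[match(
    paste(mkbh$cluster, mkbh$gene), paste(raw$cluster, raw$gene))] - 1e-12))
})
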