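# Cluster-based permutation tests: exact null, block recovery,
# adjacency contracts, determinism, p monotonicity.

null_maps <- function(seed, n = 14, nf = 12, nt = 10, sd = 0.5) {
  set.seed(seed)
  array(rnorm(n * nf * nt, sd = sd), c(n, nf, nt))
}

test_that("identical conditions give an empty result", {
  A <- null_maps(1)
  res <- cluster_perm_tf(A, A, n_perm = 200, seed = 2)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$mask == 0))
  expect_true(all(res$t_map == 0))
})

test_that("an injected block is recovered as one significant cluster", {
  A <- null_maps(3, sd = 0.4)
  B <- null_maps(30, sd = 0.4)
  block_f <- 3:6
  block_t <- 4:8
  B[, block_f, block_t] <- B[, block_f, block_t] + 3
  res <- cluster_perm_tf(A, B, n_perm = 500, seed = 4)
  sig <- res$clusters[res$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$sign, "negative")      # A - B < 0
  members <- res$members[[sig$cluster]]
  nf <- 12
  inblock <- as.vector(outer(block_f, (block_t - 1) * nf, "+"))
  expect_gte(length(intersect(members, inblock)), 0.8 * length(inblock))
  # mask is zero outside significant clusters
  expect_true(all(res$mask[-members] == 0))
  expect_true(all(res$mask[members] != 0))
})

test_that("permutations are deterministic and p is monotone in |mass|", {
  A <- null_maps(5)
  B <- null_maps(6)
  B[, 2:5, 2:6] <- B[, 2:5, 2:6] + 1.2
  r1 <- cluster_perm_tf(A, B, n_perm = 300, seed = 7)
  r2 <- cluster_perm_tf(A, B, n_perm = 300, seed = 7)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null, r2$null)
  ord <- order(abs(r1$clusters$mass))
  expect_true(all(diff(r1$clusters$p[ord]) <= 1e-12))
  expect_error(cluster_perm_tf(A, B, n_perm = 50, seed = 1), "at least 100")
  expect_error(cluster_perm_tf(A[1, , , drop = FALSE], B[1, , , drop = FALSE],
                               n_perm = 200), "2 subjects")
})

test_that("channel clusters grow only over the adjacency graph", {
  adj <- electrode_adjacency()
  chans <- montage_1020()$channel
  set.seed(11)
  mk <- function() {
    m <- matrix(rnorm(14 * 32, sd = 0.3), 14, 32)
    colnames(m) <- chans
    m
  }
  A <- mk()
  B <- A + matrix(rnorm(14 * 32, sd = 0.3), 14, 32)
  B[, c("F4", "FC4")] <- B[, c("F4", "FC4")] + 2
  res <- cluster_perm_channels(A, B, adj, n_perm = 300, seed = 12)
  sig <- tidy(res)[tidy(res)$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(vapply(sig$members,
                         \(m) all(c("F4", "FC4") %in% m), logical(1))))
  # effects at non-adjacent electrodes never merge
  B2 <- A + matrix(rnorm(14 * 32, sd = 0.3), 14, 32)
  B2[, c("F4", "P3")] <- B2[, c("F4", "P3")] + 3
  res2 <- cluster_perm_channels(A, B2, adj, n_perm = 300, seed = 13)
  for (m in tidy(res2)$members)
    expect_false(all(c("F4", "P3") %in% m))
  # unknown electrode is rejected
  A3 <- A
  colnames(A3)[1] <- "XX9"
  B3 <- B
  colnames(B3)[1] <- "XX9"
  expect_error(cluster_perm_channels(A3, B3, adj), "absent from adjacency")
})

test_that("the montage adjacency is connected with local neighbourhoods", {
  adj <- electrode_adjacency()
  g <- igraph::graph_from_data_frame(adj, directed = FALSE,
                                     vertices = montage_1020()$channel)
  expect_equal(igraph::components(g)$no, 1)
  nb <- igraph::neighbors(g, "F4")$name
  expect_true("FC4" %in% nb)
  expect_false("O2" %in% nb)
  expect_lt(mean(igraph::degree(g)), 6)
})

test_that("cluster tidiers expose members and summary", {
  A <- null_maps(20)
  B <- null_maps(21)
  B[, 2:4, 2:4] <- B[, 2:4, 2:4] + 2
  res <- cluster_perm_tf(A, B, n_perm = 200, seed = 21,
                         freq = seq(1, 30, length.out = 12),
                         time = seq(-1, 5, length.out = 10))
  td <- tidy(res)
  expect_s3_class(td$members[[1]], "tbl_df")
  g <- glance(res)
  expect_equal(g$n_perm, 200)
  expect_equal(g$n_clusters, nrow(res$clusters))
})
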