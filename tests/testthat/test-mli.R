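test_that("neighborhood slots follow hop priority, degree, then index", {
  net <- toy4()
  # 1-hop of node 2 = {1, 3} with temporal degrees 1 < 2, then 2-hop {4}
  expect_equal(select_neighborhood(net, 2, 4), c(2L, 3L, 1L, 4L))
  expect_equal(select_neighborhood(net, 2, 2), c(2L, 3L))
  # isolated anchor pads with NA
  iso <- temporal_network(list(cbind(1L, 2L)), n_nodes = 4)
  expect_equal(select_neighborhood(iso, 3, 4), c(3L, NA, NA, NA))
  # a clique anchor lists all others, degree-sorted then index-sorted
  tri <- temporal_network(list(rbind(c(1, 2), c(2, 3), c(1, 3)),
                               rbind(c(2, 3))), n_nodes = 3)
  expect_equal(select_neighborhood(tri, 1, 3), c(1L, 2L, 3L))
})

test_that("feature matrices apply early-snapshot decay weights", {
  net <- toy4()
  # alpha = 0.5, L = 3: weights (1, 1/2, 1/4); slots of node 2 are (2, 3)
  M <- feature_matrix(net, 2, D = 2, alpha = 0.5)
  expect_equal(M, rbind(c(1.5, 0.5), c(0.5, 0.75)))
  # isolated anchor embeds to the zero matrix
  iso <- temporal_network(list(cbind(1L, 2L)), n_nodes = 4)
  expect_equal(feature_matrix(iso, 3, 4, 0.5), matrix(0, 4, 4))
  # alpha = 1 degenerates to co-occurrence counts and temporal degrees
  M1 <- feature_matrix(net, 2, D = 4, alpha = 1)
  agg <- aggregate_network(net)
  slots <- select_neighborhood(net, 2, 4)
  expect_equal(diag(M1), as.numeric(agg$temporal_degree[slots]))
  expect_equal(M1[1, 2], 1)  # pair (2,3) appears in one snapshot
})

test_that("feature matrices are symmetric, non-negative, zero on padding", {
  net <- random_temporal_net(9, 4, 0.3, seed = 31)
  feats <- feature_matrices(net, D = 8, alpha = 0.2)
  for (v in c(1, 5, 9)) {
    M <- feats[v, , ]
    expect_equal(M, t(M))
    expect_true(all(M >= 0))
  }
  # anchors with small reachable sets leave zero rows/columns
  iso <- temporal_network(list(cbind(1L, 2L)), n_nodes = 3)
  M <- feature_matrix(iso, 1, 4, 0.2)
  expect_equal(M[3:4, ], matrix(0, 2, 4))
  expect_equal(M[, 3:4], matrix(0, 4, 2))
})

test_that("feature extraction ignores edge-list order and tracks relabeling", {
  net <- random_temporal_net(7, 3, 0.5, seed = 61)
  shuffled <- temporal_network(
    lapply(net$snapshots, function(e) e[rev(seq_len(nrow(e))), , drop = FALSE]),
    n_nodes = 7)
  expect_equal(feature_matrices(net, 4, 0.2),
               feature_matrices(shuffled, 4, 0.2))

  # equivariance needs tie-free layer orderings: build distinct temporal
  # degrees by hand (a star whose spokes repeat different numbers of times)
  net2 <- temporal_network(list(rbind(c(1, 2), c(1, 3), c(1, 4)),
                                rbind(c(1, 2), c(2, 3)),
                                rbind(c(1, 2))), n_nodes = 5)
  tdeg <- aggregate_network(net2)$temporal_degree
  expect_equal(anyDuplicated(tdeg[tdeg > 0]), 0L)
  perm <- c(3L, 5L, 2L, 1L, 4L)
  pnet <- permute_nodes(net2, perm)
  for (v in 1:5)
    expect_equal(feature_matrix(pnet, perm[v], 4, 0.3),
                 feature_matrix(net2, v, 4, 0.3))
})

test_that("ranking is by descending score with index tie-breaks", {
  expect_equal(rank_nodes(c(0.3, 0.9, 0.9, 0.1)), c(2L, 3L, 1L, 4L))
  expect_equal(rank_nodes(c(1, 1, 1)), 1:3)
})

test_that("the training pipeline is reproducible and scores every node", {
  net <- generate_temporal_ba(60, 1, 5, seed = 3)
  m1 <- mli_train(net, D = 4, label_runs = 20, epochs = 20, seed = 11)
  m2 <- mli_train(net, D = 4, label_runs = 20, epochs = 20, seed = 11)
  expect_identical(m1$history, m2$history)
  s1 <- mli_score(m1, net)
  expect_identical(s1, mli_score(m2, net))
  expect_length(s1, 60L)
  expect_true(all(is.finite(s1)))
  # scoring another network of different density works unchanged
  other <- generate_temporal_ba(40, 2, 4, seed = 9)
  expect_length(mli_score(m1, other), 40L)
})

test_that("models persist with their architecture and refuse corruption", {
  net <- generate_temporal_ba(30, 1, 3, seed = 5)
  model <- mli_train(net, D = 4, label_runs = 5, epochs = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_mli_model(model, f)
  back <- load_mli_model(f)
  expect_identical(mli_score(back, net), mli_score(model, net))
  broken <- model
  broken$config$D <- 8L
  saveRDS(broken, f)
  expect_error(load_mli_model(f), "inconsistent")
})
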