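test_that("edge streams are binned into half-open snapshots with a closed final bin", {
  ev <- data.frame(u = c(1, 2), v = c(2, 3), t = c(0.5, 1.5))
  net <- bin_edge_stream(ev, n_snapshots = 2, t_min = 0, t_max = 2)
  expect_equal(net$interval, 1)
  expect_equal(net$snapshots[[1]], cbind(u = 1L, v = 2L))
  expect_equal(net$snapshots[[2]], cbind(u = 2L, v = 3L))

  # boundary: t_max itself lands in the final snapshot
  ev2 <- data.frame(u = c(1, 1), v = c(2, 3), t = c(0, 2))
  net2 <- bin_edge_stream(ev2, 2, t_min = 0, t_max = 2)
  expect_equal(nrow(net2$snapshots[[2]]), 1L)

  # undirected duplicates within a snapshot merge
  ev3 <- data.frame(u = c(1, 2), v = c(2, 1), t = c(0.1, 0.2))
  net3 <- bin_edge_stream(ev3, 1, t_min = 0, t_max = 1)
  expect_equal(n_edges(net3), 1L)
})

test_that("self-loops are dropped and an edgeless network is legal", {
  ev <- data.frame(u = c(3, 1), v = c(3, 2), t = c(0.5, 0.7))
  net <- bin_edge_stream(ev, 1, t_min = 0, t_max = 1)
  expect_equal(n_edges(net), 1L)
  expect_silent(temporal_network(list(cbind(2L, 2L)), n_nodes = 3))
  expect_equal(n_edges(temporal_network(list(cbind(2L, 2L)), n_nodes = 3)), 0L)
})

test_that("binning errors name the offending event and reject empty input", {
  expect_error(bin_edge_stream(data.frame(u = 1, v = 2, t = 5)[0, ], 2),
               "empty")
  ev <- data.frame(u = c(1, 4), v = c(2, 5), t = c(0.5, 7))
  expect_error(bin_edge_stream(ev, 2, t_min = 0, t_max = 2), "event 2")
})

test_that("binning conserves non-self-loop events with distinct pairs", {
  withr::with_seed(7, {
    pairs <- t(utils::combn(12, 2))
    pairs <- pairs[sample.int(nrow(pairs), 40), ]
    ev <- data.frame(u = pairs[, 1], v = pairs[, 2],
                     t = stats::runif(40, 0, 10))
  })
  net <- bin_edge_stream(ev, 5, t_min = 0, t_max = 10)
  expect_equal(n_edges(net), 40L)
})

test_that("aggregation counts multiplicities and temporal degrees", {
  agg <- aggregate_network(toy4())
  expect_equal(agg$multiplicity, c(1L, 1L, 1L))
  expect_equal(agg$temporal_degree, c(1L, 2L, 2L, 1L))

  rep3 <- temporal_network(rep(list(cbind(1L, 2L)), 3), n_nodes = 2)
  agg3 <- aggregate_network(rep3)
  expect_equal(agg3$multiplicity, 3L)
  expect_equal(agg3$temporal_degree, c(3L, 3L))

  empty <- temporal_network(list(NULL, NULL), n_nodes = 3)
  agge <- aggregate_network(empty)
  expect_equal(nrow(agge$pairs), 0L)
  expect_equal(agge$temporal_degree, c(0L, 0L, 0L))
})

test_that("aggregation is invariant under snapshot permutation", {
  net <- random_temporal_net(6, 4, 0.4, seed = 11)
  perm_net <- temporal_network(net$snapshots[c(3, 1, 4, 2)], 6)
  a <- aggregate_network(net)
  b <- aggregate_network(perm_net)
  expect_equal(a$pairs, b$pairs)
  expect_equal(a$multiplicity, b$multiplicity)
  expect_equal(a$temporal_degree, b$temporal_degree)
})

test_that("temporal BA snapshots have exactly m*(n-m) edges each", {
  for (cfg in list(c(5, 1, 2), c(20, 3, 4), c(50, 2, 3))) {
    net <- generate_temporal_ba(cfg[1], cfg[2], cfg[3], seed = 5)
    per_snap <- vapply(net$snapshots, nrow, integer(1))
    expect_equal(per_snap, rep(cfg[2] * (cfg[1] - cfg[2]), cfg[3]))
  }
  expect_error(generate_temporal_ba(3, 3, 2, seed = 1), "exceed")
})

test_that("seeded generation is bitwise reproducible", {
  a <- generate_temporal_ba(40, 2, 3, seed = 99)
  b <- generate_temporal_ba(40, 2, 3, seed = 99)
  expect_identical(a$snapshots, b$snapshots)
  c2 <- generate_temporal_ba(40, 2, 3, seed = 100)
  expect_false(identical(a$snapshots, c2$snapshots))
})

test_that("snapshot files round-trip and tolerate unsorted lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snapshots(toy4(), f)
  back <- read_snapshots(f)
  expect_equal(back$n_nodes, 4L)
  expect_equal(back$snapshots, toy4()$snapshots)

  writeLines(c("4 3", "3 3 4", "1 1 2", "2 2 3"), f)
  shuffled <- read_snapshots(f)
  expect_equal(shuffled$snapshots, toy4()$snapshots)
})

test_that("snapshot files reject bad node indices and malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("4 3", "1 1 5"), f)
  expect_error(read_snapshots(f), "line 2")
  writeLines(c("4 3", "1 1"), f)
  expect_error(read_snapshots(f), "line 2")
  writeLines(c("4 3", "4 1 2"), f)
  expect_error(read_snapshots(f), "snapshot index")
})

test_that("event files accept comments and extra columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("% KONECT-style header", "# comment",
               "1 2 0.5 17", "2 3 1.5 42"), f)
  ev <- read_events(f)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$t, c(0.5, 1.5))
})
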