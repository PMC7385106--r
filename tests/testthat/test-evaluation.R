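test_that("kendall tau on hand-checked pairs", {
  expect_equal(kendall_tau(1:5, 1:5), 1)
  expect_equal(kendall_tau(1:5, 5:1), -1)
  # 5 concordant, 1 discordant of 6 pairs
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 2, 4, 3)), 2 / 3)
  # constant vector: correlation undefined
  expect_true(is.na(kendall_tau(c(1, 1, 1), 1:3)))
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(1, 1), "at least 2")
})

test_that("tie-corrected tau matches the explicit tau-b formula", {
  pairs_stat <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
        if (sx == 0 && sy == 0) next
        if (sx == 0) tx <- tx + 1
        else if (sy == 0) ty <- ty + 1
        else if (sx == sy) conc <- conc + 1
        else disc <- disc + 1
      }
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
  }
  withr::with_seed(13, {
    for (rep in 1:5) {
      x <- sample(1:4, 8, replace = TRUE)
      y <- sample(1:4, 8, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      expect_equal(kendall_tau(x, y), pairs_stat(x, y))
    }
  })
})

test_that("hitting rate counts the recovered top-k fraction", {
  # n = 30, fraction 0.1 -> k = 3; top sets {1,2,3} vs {3,4,5}
  pred <- c(30:1)
  truth <- rep(0, 30); truth[c(3, 4, 5)] <- c(3, 2, 1)
  expect_equal(hitting_rate(pred, truth, 0.1), 1 / 3)
  expect_equal(hitting_rate(pred, pred, 0.1), 1)
  disj <- rep(0, 30); disj[28:30] <- 1:3
  expect_equal(hitting_rate(pred, disj, 0.1), 0)
  expect_error(hitting_rate(pred, truth, 0), "fraction")
})

test_that("tau and hitting rate depend only on rankings", {
  withr::with_seed(29, {
    a <- stats::rnorm(40)
    b <- stats::rnorm(40)
  })
  expect_equal(kendall_tau(exp(a), b), kendall_tau(a, b))
  expect_equal(kendall_tau(a, 3 * b + 1), kendall_tau(a, b))
  expect_equal(hitting_rate(exp(a), b, 0.2), hitting_rate(a, b, 0.2))
})

test_that("method comparison reports a full grid against shared truth", {
  net <- generate_temporal_ba(50, 1, 5, seed = 21)
  model <- mli_train(net, D = 4, label_runs = 10, epochs = 10, seed = 4)
  rep1 <- compare_methods(net, betas = c(0.1, 0.5), model = model,
                          truth_runs = 50, seed = 6, network_id = "ba50")
  expect_equal(nrow(rep1), 12L)  # 6 methods x 2 betas
  expect_setequal(unique(rep1$method), c("mli", "tc", "tb", "tk", "tdd", "tdc"))
  expect_true(all(rep1$hr >= 0 & rep1$hr <= 1))
  expect_true(all(is.na(rep1$tau) | abs(rep1$tau) <= 1))
  expect_equal(unique(rep1$k), 5L)
  # deterministic given the seed
  rep2 <- compare_methods(net, betas = c(0.1, 0.5), model = model,
                          truth_runs = 50, seed = 6, network_id = "ba50")
  expect_identical(rep1, rep2)
  expect_error(compare_methods(net, methods = "pagerank"), "unknown")
  expect_error(compare_methods(net, methods = "mli"), "model")
})

test_that("tau grid reuses one model per training rate and one truth per beta", {
  net <- generate_temporal_ba(40, 1, 4, seed = 31)
  g <- beta_grid(net, betas = c(0, 0.2), beta_ts = 0.2,
                 truth_runs = 30, seed = 9,
                 D = 4, label_runs = 10, epochs = 10)
  expect_equal(dim(g), c(1L, 2L))
  # beta = 0 truth is all ties: undefined tau recorded as NA
  expect_true(is.na(g[1, 1]))
  # the non-degenerate cell equals a direct evaluation with the same seeds
  model <- mli_train(net, beta_t = 0.2, seed = mlinet:::derive_seed(9, 1),
                     D = 4, label_runs = 10, epochs = 10)
  truth <- spreading_influence(net, beta = 0.2, runs = 30,
                               seed = mlinet:::derive_seed(9, 1002))
  expect_equal(g[1, 2], kendall_tau(mli_score(model, net), truth))
})
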