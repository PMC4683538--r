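test_that("the ten-node design meets its structural constraints", {
  for (seed in 1:5) {
    spec <- make_benchmark_10node(seed)
    expect_identical(spec$n_nodes, 10L)
    expect_length(spec$epochs, 7L)
    expect_identical(spec$n_obs, 1019L)
    lens <- vapply(spec$epochs, `[[`, numeric(1), "length")
    expect_true(all(lens >= 20 & lens <= 400))
    for (e in 2:7) {
      d <- sum(xor(spec$epochs[[e]]$adj, spec$epochs[[e - 1]]$adj))
      expect_identical(d, 1L)   # exactly one single-edge change
    }
    expect_true(all(colSums(spec$epochs[[1]]$adj) <= 3))
  }
  expect_false(identical(make_benchmark_10node(1)$epochs[[1]]$adj,
                         make_benchmark_10node(2)$epochs[[1]]$adj))
  small <- make_benchmark_10node(3, segment_samples = 20)
  expect_identical(small$n_obs, 140L)
})

test_that("the hundred-node design meets its structural constraints", {
  spec <- make_benchmark_100node(1)
  expect_identical(spec$n_nodes, 100L)
  expect_length(spec$epochs, 5L)
  expect_identical(spec$n_obs, 5000L)
  expect_identical(sum(spec$epochs[[1]]$adj), 50L)
  for (e in 2:5) {
    d <- sum(xor(spec$epochs[[e]]$adj, spec$epochs[[e - 1]]$adj))
    expect_true(d >= 1 && d <= 3)
  }
})

test_that("simulation follows the generating law", {
  # perfect fidelity, one edge: the child copies its parent exactly
  adj <- matrix(FALSE, 2, 2)
  adj[2, 1] <- TRUE
  spec <- true_network_spec(2, list(list(length = 200, adj = adj)),
                            dependence_strength = 1, seed = 5)
  x <- simulate_timeseries(spec)$values
  expect_identical(x[1, -1], x[2, -200])

  # dependence 0.5 carries no information: empirical MI vanishes
  spec0 <- true_network_spec(2, list(list(length = 5000, adj = adj)),
                             dependence_strength = 0.5, seed = 6)
  x <- simulate_timeseries(spec0)$values
  tab <- table(parent = x[2, -5000], child = x[1, -1]) / 4999
  mi <- 0
  for (a in 1:2) for (b in 1:2)
    mi <- mi + tab[a, b] *
      log(tab[a, b] / (sum(tab[a, ]) * sum(tab[, b])))
  expect_lt(abs(mi), 0.005)

  # empirical conditional law converges to the generating CPD
  spec9 <- true_network_spec(2, list(list(length = 5000, adj = adj)),
                             dependence_strength = 0.9, seed = 7)
  x <- simulate_timeseries(spec9)$values
  p1 <- mean(x[1, -1][x[2, -5000] == 1])
  p0 <- mean(x[1, -1][x[2, -5000] == 0])
  expect_lt(abs(p1 - 0.9), 0.03)
  expect_lt(abs(p0 - 0.1), 0.03)

  # reproducibility
  expect_identical(simulate_timeseries(spec9)$values,
                   simulate_timeseries(spec9)$values)
})

test_that("evaluation implements the per-observation conventions", {
  spec <- make_benchmark_10node(4)
  # a pseudo-prediction identical to the truth scores perfectly
  truth_nodes <- lapply(1:10, function(i) {
    graphs <- unique(lapply(spec$epochs, function(e) which(e$adj[, i])))
    ep <- hmdbn:::epoch_of_column(spec)[-1]
    path <- vapply(ep, function(e) {
      pa <- which(spec$epochs[[e]]$adj[, i])
      which(vapply(graphs, identical, logical(1), pa))
    }, integer(1))
    fake_node(i, graphs, path, spec$n_obs - 1L)
  })
  net <- assemble(truth_nodes)
  ev <- evaluate_network(spec, net)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))

  # empty prediction: precision 1 by convention, recall 0, F1 0
  empty <- assemble(lapply(1:10, function(i)
    fake_node(i, list(integer(0)), rep(1L, spec$n_obs - 1L),
              spec$n_obs - 1L)))
  ev0 <- evaluate_network(spec, empty)
  expect_equal(ev0$precision, 1)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$f1, 0)

  # hand contingency: truth 4 static edges, prediction 3 right + 1 wrong
  adj <- matrix(FALSE, 10, 10)
  adj[cbind(1:4, 5:8)] <- TRUE
  tspec <- true_network_spec(10, list(list(length = 50, adj = adj)),
                             seed = 8)
  pred <- assemble(lapply(1:10, function(i) {
    graphs <- if (i %in% 5:7) list(i - 4L)       # three correct edges
              else if (i == 9) list(4L)          # one spurious edge
              else list(integer(0))
    fake_node(i, graphs, rep(1L, 49), 49)
  }))
  ev <- evaluate_network(tspec, pred)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f1, 0.75)

  expect_error(evaluate_network(tspec, empty), "T = ")
})

test_that("mistimed transitions cost exactly the overlap error", {
  adj1 <- matrix(FALSE, 3, 3)
  adj1[2, 1] <- TRUE
  adj2 <- matrix(FALSE, 3, 3)
  adj2[3, 1] <- TRUE
  spec <- true_network_spec(3, list(list(length = 50, adj = adj1),
                                    list(length = 50, adj = adj2)),
                            seed = 9)
  # prediction switches 5 points late (truth switches at t = 50)
  pred <- assemble(list(
    fake_node(1, list(2L, 3L), rep(c(1L, 2L), c(54, 45)), 99),
    fake_node(2, list(integer(0)), rep(1L, 99), 99),
    fake_node(3, list(integer(0)), rep(1L, 99), 99)))
  ev <- evaluate_network(spec, pred)
  expect_equal(ev$precision, 94 / 99, tolerance = 1e-12)
  expect_equal(ev$recall, 94 / 99, tolerance = 1e-12)
})

test_that("benchmark runs are seed-reproducible", {
  cfg <- search_config()
  b1 <- run_benchmark("ten-node", 2, cfg, seed = 3, segment_samples = 20)
  b2 <- run_benchmark("ten-node", 2, cfg, seed = 3, segment_samples = 20)
  expect_identical(b1$results, b2$results)
  expect_identical(nrow(b1$results), 2L)
  expect_true(all(c("precision", "recall", "f1") %in% names(b1$results)))
})
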