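test_that("ws_network at p = 0 is the ring lattice with conserved edge count", {
  net <- ws_network(8, 2, 0)
  expect_equal(nrow(net$edges), 8)
  expect_equal(net$edges, net$substrate_edges)
  deg <- tabulate(c(net$edges), nbins = 8)
  expect_true(all(deg == 2))

  for (p in c(0, 0.1, 0.5, 1)) {
    for (seed in 1:3) {
      net <- ws_network(100, 6, p, seed = seed)
      expect_equal(nrow(net$edges), 100 * 6 / 2)
      expect_false(any(net$edges[, 1] == net$edges[, 2]))
      expect_equal(anyDuplicated(net$edges), 0)
    }
  }
})

test_that("ws_network rejects invalid degree", {
  expect_error(ws_network(10, 3, 0), "even")
  expect_error(ws_network(10, 12, 0), "even")
})

test_that("ring-lattice clustering matches the closed form and a brute-force count", {
  net <- ws_network(2048, 6, 0)
  expect_equal(network_metrics(net)$avg_clustering, 3 * (6 - 2) / (4 * (6 - 1)),
    tolerance = 1e-12
  )
  small <- ws_network(50, 6, 0)
  expect_equal(
    network_metrics(small)$avg_clustering,
    bf_avg_clustering(50, small$edges),
    tolerance = 1e-12
  )
})

test_that("fully rewired networks approach the random-graph clustering limit", {
  cs <- vapply(1:10, function(s) {
    network_metrics(ws_network(2048, 6, 1, seed = s))$avg_clustering
  }, numeric(1))
  expect_lt(abs(mean(cs) - 6 / 2048), 0.002)
})

test_that("network_metrics agrees with hand-enumerated and brute-force values", {
  triangle <- make_net(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  m <- network_metrics(triangle)
  expect_equal(m$avg_clustering, 1)
  expect_equal(m$avg_shortest_path, 1)

  cycle5 <- make_net(5, ring_edges(5, 2))
  expect_equal(network_metrics(cycle5)$avg_shortest_path, 1.5)

  star4 <- make_net(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(network_metrics(star4)$avg_clustering, 0)

  expect_error(network_metrics(make_net(3, matrix(integer(0), ncol = 2))), "no edges")

  set.seed(42)
  for (i in 1:5) {
    n <- sample(10:30, 1)
    edges <- random_edges(n, sample(n:(2 * n), 1))
    net <- make_net(n, edges)
    m <- network_metrics(net)
    expect_equal(m$avg_clustering, bf_avg_clustering(n, net$edges), tolerance = 1e-12)
    expect_equal(m$avg_shortest_path, bf_avg_path(n, net$edges), tolerance = 1e-12)
  }
})

test_that("small-worldness separates small-world from random structure", {
  # self-reference limit: a G(n, m) draw scored against the G(n, m) null sits
  # near 1, though clustering this sparse is a noisy estimate
  set.seed(2)
  g <- igraph::sample_gnm(1000, 3000)
  er <- make_net(1000, igraph::as_edgelist(g), matrix(integer(0), ncol = 2))
  sigma_er <- small_worldness(er, n_random = 15, seed = 3)
  expect_gt(sigma_er, 0.4)
  expect_lt(sigma_er, 2.5)

  sigma_sw <- small_worldness(ws_network(1000, 6, 0.05, seed = 4), n_random = 10, seed = 5)
  sigma_p1 <- small_worldness(ws_network(1000, 6, 1, seed = 6), n_random = 10, seed = 7)
  expect_gt(sigma_sw, 5)
  expect_lt(sigma_p1, 2.5)
  expect_gt(sigma_sw / sigma_p1, 3)
})

test_that("infer_rewiring_p recovers known rewiring and exact ring targets", {
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  truth <- purrr::map_dfr(1:3, function(s) network_metrics(ws_network(600, 6, 0.2, seed = s)))
  p_hat <- infer_rewiring_p(mean(truth$avg_clustering), mean(truth$avg_shortest_path),
    n = 600, k = 6, p_grid = grid, reps = 3, seed = 9
  )
  step <- which(grid == 0.2)
  expect_true(as.numeric(p_hat) %in% grid[max(1, step - 1):min(length(grid), step + 1)])

  ring <- network_metrics(ws_network(400, 6, 0))
  p0 <- infer_rewiring_p(ring$avg_clustering, ring$avg_shortest_path,
    n = 400, k = 6, p_grid = c(0, 0.1, 0.5), reps = 2, seed = 1
  )
  expect_equal(as.numeric(p0), 0)

  expect_warning(
    infer_rewiring_p(0.9, 2, n = 200, k = 6, p_grid = c(0, 0.5), reps = 1, seed = 1),
    "best-effort"
  )
})

test_that("weighted-edge thresholding is strict and drops isolated nodes", {
  tab <- tibble::tibble(node_a = c(1, 2, 3), node_b = c(2, 3, 4), weight = c(100, 400, 500))
  net <- threshold_weighted_edges(tab, 400)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$n_nodes, 2)
  expect_equal(attr(net, "node_labels"), c(3, 4))

  all_kept <- threshold_weighted_edges(tab, 0)
  expect_equal(nrow(all_kept$edges), 3)

  toy <- tibble::tibble(
    node_a = c(1, 1, 2, 2, 3, 4, 5, 6, 7, 8),
    node_b = c(2, 3, 3, 4, 5, 6, 7, 8, 9, 10),
    weight = c(500, 100, 450, 200, 300, 90, 410, 600, 50, 399)
  )
  net4 <- threshold_weighted_edges(toy, 400)
  # kept: 1-2, 2-3, 5-7, 6-8 -> nodes {1,2,3,5,6,7,8}, mean degree 2*4/7
  expect_equal(nrow(net4$edges), 4)
  expect_equal(net4$n_nodes, 7)
  expect_equal(net4$mean_degree, 8 / 7)

  bad <- tibble::tibble(node_a = c(1, 2), node_b = c(2, 2), weight = c(10, 20))
  expect_error(threshold_weighted_edges(bad, 0), "rows.*2")
})

test_that("weighted edge lists round-trip through plain text with validation", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "node_a node_b weight", "1 2 500", "2 3 100"), path)
  tab <- read_weighted_edges(path)
  expect_equal(tab$weight, c(500, 100))

  writeLines(c("1 2 500", "2 oops 100"), path)
  expect_error(read_weighted_edges(path), "lines: 2")
})

test_that("network edge lists round-trip including the substrate", {
  net <- ws_network(40, 4, 0.2, seed = 5)
  path <- withr::local_tempfile()
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$edges, net$edges)
  expect_equal(back$substrate_edges, net$substrate_edges)
})

test_that("ensemble metrics decrease with rewiring probability", {
  grid <- c(0, 0.2, 0.5, 1)
  means <- purrr::map_dfr(grid, function(p) {
    ms <- purrr::map_dfr(1:20, function(s) {
      network_metrics(ws_network(512, 6, p, seed = 1000 * p + s))
    })
    tibble::tibble(p = p, c = mean(ms$avg_clustering), l = mean(ms$avg_shortest_path))
  })
  expect_true(all(diff(means$c) < 0))
  expect_true(all(diff(means$l) < 0))
})
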