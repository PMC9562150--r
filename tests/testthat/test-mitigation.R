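make_selection_scenario <- function(n = 60, seed = 1) {
  net <- ws_network(n, 6, 0, seed = seed)
  nodes <- traits_from_hesitancy(
    sample_hesitancy(n, calibrate_lambda(0.25), seed = seed + 1)
  )
  list(net = net, nodes = nodes)
}

test_that("zeta matches a brute-force recomputation of its formula", {
  net <- ws_network(10, 6, 0, seed = 2)
  # distinct shapes keep the sample covariance non-singular for the oracle
  nodes <- traits_from_hesitancy(
    sample_hesitancy(10, calibrate_lambda(0.25), seed = 3),
    c(income = 2, household_size = 3)
  )
  sc <- list(net = net, nodes = nodes)
  z <- zeta_index(sc$net, sc$nodes)
  X <- as.matrix(sc$nodes[c("income", "household_size")])
  Z <- scale(X)
  Sinv <- solve(cov(X))
  adj <- adj_list(10, sc$net$edges)
  for (i in 1:10) {
    dists <- vapply(adj[[i]], function(j) {
      d <- X[i, ] - X[j, ]
      drop(t(d) %*% Sinv %*% d)
    }, numeric(1))
    expected <- exp(sum(Z[i, ])) / (1e-9 + mean(dists))
    expect_equal(z$zeta[i], expected, tolerance = 1e-10)
  }
})

test_that("isolated nodes are excluded from the zeta ranking", {
  net <- make_net(4, rbind(c(1, 2), c(2, 3)))
  nodes <- tibble::tibble(node = 1:4, eta = c(0.1, 0.2, 0.3, 0.4),
                          status = "protected",
                          a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  z <- zeta_index(net, nodes)
  expect_true(is.na(z$zeta[4]))
  targets <- select_targets("target_selection", net, nodes, budget_fraction = 0.5)
  expect_false(4 %in% targets)
})

test_that("target selection finds a high-trait, high-conformity pocket", {
  # ring of 50; nodes 21-30 share identical, elevated traits -> tiny neighbour
  # distances and large z-scores, so they dominate the zeta ranking
  net <- ws_network(50, 6, 0, seed = 3)
  nodes <- traits_from_hesitancy(sample_hesitancy(50, calibrate_lambda(0.25), seed = 4))
  block <- 21:30
  nodes$income[block] <- max(nodes$income) * 1.2
  nodes$household_size[block] <- max(nodes$household_size) * 1.2
  targets <- select_targets("target_selection", net, nodes, budget_fraction = 0.10)
  expect_length(targets, 5)
  expect_true(all(targets %in% block))
})

test_that("budgets are exact and rankings deterministic", {
  sc <- make_selection_scenario(100, seed = 5)
  t10 <- select_targets("target_high_hesitancy", sc$net, sc$nodes, budget_fraction = 0.10)
  expect_length(t10, 10)
  expect_setequal(t10, order(-sc$nodes$eta)[1:10])

  r1 <- select_targets("target_random", sc$net, sc$nodes, 0.10, seed = 6)
  r2 <- select_targets("target_random", sc$net, sc$nodes, 0.10, seed = 6)
  expect_identical(r1, r2)
  expect_length(r1, 10)

  # deterministic tie-break by node id
  tied <- sc$nodes
  tied$eta <- rep(0.5, 100)
  expect_identical(
    select_targets("target_high_hesitancy", sc$net, tied, 0.05),
    1:5
  )
})

test_that("protection truncates hesitancy below the vulnerability threshold", {
  sc <- make_selection_scenario(200, seed = 7)
  lambda <- calibrate_lambda(0.25)
  vul <- sc$nodes$node[sc$nodes$status == "vulnerable"]
  out <- apply_protection(sc$nodes, vul, lambda, seed = 8)
  expect_equal(sum(out$status == "vulnerable"), 0)
  expect_true(all(out$eta[vul] < 0.05))
  untouched <- setdiff(sc$nodes$node, vul)
  expect_identical(out$eta[untouched], sc$nodes$eta[untouched])

  expect_identical(apply_protection(sc$nodes, integer(0), lambda), sc$nodes)
  # protecting an already-protected node is a no-op
  prot <- sc$nodes$node[sc$nodes$status == "protected"][1]
  expect_identical(apply_protection(sc$nodes, prot, lambda), sc$nodes)
})

test_that("a null budget leaves clustering exactly at control", {
  out <- evaluate_strategy("target_random", reps = 3, seed = 9, n = 128,
                           budget_fraction = 0)
  expect_true(all(out$relative_clustering == 1))
  expect_true(all(out$clustering_difference == 0))
})

test_that("strategy evaluation returns per-replicate ratios against control", {
  out <- evaluate_strategy("target_high_hesitancy", reps = 5, seed = 10, n = 128,
                           beta_target = 0.5)
  expect_equal(nrow(out) + attr(out, "dropped"), 5)
  expect_true(all(is.finite(out$relative_clustering)))
  rr <- evaluate_strategy("reroute", reps = 3, seed = 11, n = 128, omega = 0.5)
  expect_equal(nrow(rr) + attr(rr, "dropped"), 3)
})
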