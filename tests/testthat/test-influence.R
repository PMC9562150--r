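params_eta <- function(alpha, ...) {
  influence_params(alpha = alpha, exposure = "hesitancy", ...)
}

test_that("the update rule reproduces hand-computed neighbourhood averages", {
  # isolated node: the exposure is its own hesitancy
  net <- make_net(3, rbind(c(2, 3)))
  nodes <- tibble::tibble(node = 1:3, eta = c(0.3, 0.01, 0.01),
                          status = classify_status(c(0.3, 0.01, 0.01)))
  out <- influence_step(net, nodes, params_eta(0.2))
  expect_equal(out$eta[1], 0.31)

  nodes$eta[1] <- 0.1
  out <- influence_step(net, nodes, params_eta(0.2))
  expect_equal(out$eta[1], 0.1)

  # star: centre 0.1, three leaves 0.5, alpha 0.3
  star <- make_net(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  sn <- tibble::tibble(node = 1:4, eta = c(0.1, 0.5, 0.5, 0.5),
                       status = classify_status(c(0.1, 0.5, 0.5, 0.5)))
  out <- influence_step(star, sn, params_eta(0.3))
  expect_equal(out$eta, c(0.11, 0.51, 0.51, 0.51))
  expect_equal(out$status, rep("vulnerable", 4))

  # status exposure: centre sees 3 vulnerable of 4 members
  sn2 <- tibble::tibble(node = 1:4, eta = c(0.01, 0.06, 0.06, 0.06),
                        status = classify_status(c(0.01, 0.06, 0.06, 0.06)))
  out2 <- influence_step(star, sn2, influence_params(alpha = 0.7))
  expect_equal(out2$eta, c(0.02, 0.06, 0.06, 0.06)) # leaves see 1/2 < 0.7
})

test_that("an unreachable tolerance is a fixed point", {
  net <- ws_network(64, 4, 0, seed = 1)
  nodes <- sample_hesitancy(64, calibrate_lambda(0.10), seed = 2)
  traj <- run_influence(net, nodes, influence_params(alpha = 1.01))
  expect_equal(traj$stop_reason, "fixed_point")
  expect_equal(max(traj$steps$step), 0)
  expect_identical(traj$nodes$eta, nodes$eta)
})

test_that("alpha = 0 increments every node and stops on the predicted step", {
  net <- ws_network(200, 6, 0, seed = 3)
  nodes <- sample_hesitancy(200, calibrate_lambda(0.10), seed = 4)
  params <- params_eta(0)
  # with every node firing, the vulnerable set after s steps is {eta0 >= thr - s*delta}
  target_steps <- which(vapply(1:50, function(s) {
    mean(nodes$eta >= 0.05 - s * 0.01) >= 0.25
  }, logical(1)))[1]
  traj <- run_influence(net, nodes, params)
  expect_equal(traj$stop_reason, "fraction_reached")
  expect_equal(max(traj$steps$step), target_steps)
  expect_equal(
    glance(traj)$vulnerable_fraction,
    mean(nodes$eta >= 0.05 - target_steps * 0.01)
  )
})

test_that("influence runs stop at the first crossing of the stop fraction", {
  net <- ws_network(512, 6, 0, seed = 5)
  nodes <- sample_hesitancy(512, calibrate_lambda(0.10), seed = 6)
  traj <- run_influence(net, nodes, influence_params(alpha = 0.2))
  expect_equal(traj$stop_reason, "fraction_reached")
  frac <- glance(traj)$vulnerable_fraction
  expect_gte(frac, 0.25)
  expect_lt(frac, 0.32)
  # the step before the last was below the stop fraction
  pre <- traj$steps$vulnerable_fraction[nrow(traj$steps) - 1]
  expect_lt(pre, 0.25)
  expect_error(
    run_influence(net, sample_hesitancy(512, calibrate_lambda(0.40), seed = 7),
                  influence_params(alpha = 0.2)),
    "already at or above"
  )
})

test_that("hesitancy and vulnerability are monotone along a run", {
  net <- ws_network(256, 6, 0.1, seed = 8)
  nodes <- sample_hesitancy(256, calibrate_lambda(0.10), seed = 9)
  params <- influence_params(alpha = 0.2)
  prev <- nodes
  for (s in 1:10) {
    nxt <- influence_step(net, prev, params)
    expect_true(all(nxt$eta >= prev$eta))
    expect_false(any(prev$status == "vulnerable" & nxt$status == "protected"))
    prev <- nxt
  }
})

test_that("trajectories are deterministic given identical inputs", {
  net <- ws_network(256, 6, 0.2, seed = 10)
  nodes <- sample_hesitancy(256, calibrate_lambda(0.10), seed = 11)
  params <- influence_params(alpha = 0.2)
  t1 <- run_influence(net, nodes, params)
  t2 <- run_influence(net, nodes, params)
  expect_identical(t1$steps, t2$steps)
  r1 <- run_influence_with_rerouting(net, nodes, params, omega = 0.5, seed = 12)
  r2 <- run_influence_with_rerouting(net, nodes, params, omega = 0.5, seed = 12)
  expect_identical(r1$trajectory$steps, r2$trajectory$steps)
  expect_identical(r1$net$edges, r2$net$edges)
})

test_that("omega = 0 rerouting reproduces the plain run and conserves edges", {
  net <- ws_network(256, 6, 0.2, seed = 13)
  nodes <- sample_hesitancy(256, calibrate_lambda(0.10), seed = 14)
  params <- influence_params(alpha = 0.2)
  plain <- run_influence(net, nodes, params)
  zero <- run_influence_with_rerouting(net, nodes, params, omega = 0, seed = 15)
  expect_identical(zero$trajectory$steps, plain$steps)
  expect_identical(zero$net$edges, net$edges)

  full <- run_influence_with_rerouting(net, nodes, params, omega = 1, seed = 16)
  expect_equal(nrow(full$net$edges), nrow(net$edges))
})

test_that("omega = 1 strips a freshly flipped node of its protected neighbours", {
  # node 1 (protected, eta just below threshold) has two vulnerable and one
  # protected neighbour; with alpha = 0.5 it flips on step 1
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(5, 6))
  net <- make_net(6, edges)
  eta <- c(0.045, 0.06, 0.06, 0.01, 0.01, 0.01)
  nodes <- tibble::tibble(node = 1:6, eta = eta, status = classify_status(eta))
  params <- influence_params(alpha = 0.5, stop_fraction = 0.9, max_steps = 1)
  out <- run_influence_with_rerouting(net, nodes, params, omega = 1, seed = 17)
  expect_equal(out$trajectory$nodes$status[1], "vulnerable")
  nb1 <- c(
    out$net$edges[out$net$edges[, 1] == 1, 2],
    out$net$edges[out$net$edges[, 2] == 1, 1]
  )
  expect_true(all(out$trajectory$nodes$status[nb1] == "vulnerable"))
  expect_equal(nrow(out$net$edges), 4)
})

test_that("combined runs anneal first and then diffuse to the stop fraction", {
  net <- ws_network(256, 6, 0, seed = 18)
  traj <- run_combined(net, 0.6, influence_params(alpha = 0.2), seed = 19)
  ann <- attr(traj, "anneal")
  expect_true(ann$converged)
  expect_lt(abs(ann$beta - 0.6), 0.011)
  expect_equal(traj$stop_reason, "fraction_reached")
  expect_gte(glance(traj)$vulnerable_fraction, 0.25)
})
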