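path4 <- rbind(c(1, 2), c(2, 3), c(3, 4))

test_that("mixing fractions classify every spatial edge", {
  st <- c("vulnerable", "vulnerable", "protected", "protected")
  mc <- mixing_counts(st, path4)
  expect_equal(unlist(mc), c(vv = 1 / 3, pp = 1 / 3, vp = 1 / 3))

  all_v <- mixing_counts(rep("vulnerable", 4), path4)
  expect_equal(unlist(all_v), c(vv = 1, pp = 0, vp = 0))

  set.seed(1)
  edges <- random_edges(20, 40)
  st <- sample(c("vulnerable", "protected"), 20, replace = TRUE)
  mc <- mixing_counts(st, edges)
  # brute-force loop
  cnt <- c(vv = 0, pp = 0, vp = 0)
  for (e in seq_len(nrow(edges))) {
    v <- sum(st[edges[e, ]] == "vulnerable")
    cnt[c("pp", "vp", "vv")[v + 1]] <- cnt[c("pp", "vp", "vv")[v + 1]] + 1
  }
  expect_equal(unlist(mc), cnt / 40)
  expect_equal(sum(unlist(mc)), 1)
  expect_error(mixing_counts(st, matrix(integer(0), ncol = 2)), "Empty")
})

test_that("assortativity matches direct substitution in both variants", {
  seg <- tibble::tibble(vv = 0.5, pp = 0.5, vp = 0)
  expect_equal(spatial_assortativity(seg, "as_printed"), 1)
  expect_equal(spatial_assortativity(seg, "newman"), 1)

  thirds <- tibble::tibble(vv = 1 / 3, pp = 1 / 3, vp = 1 / 3)
  expect_equal(spatial_assortativity(thirds, "as_printed"), -2, tolerance = 1e-12)
  expect_equal(spatial_assortativity(thirds, "newman"), 1 / 3, tolerance = 1e-12)

  one_class <- tibble::tibble(vv = 1, pp = 0, vp = 0)
  expect_true(is.na(spatial_assortativity(one_class)))
})

test_that("newman assortativity is a bounded null-centred statistic", {
  net <- ws_network(512, 6, 0, seed = 2)
  set.seed(3)
  rs <- purrr::map_dbl(1:100, function(s) {
    st <- sample(c("vulnerable", "protected"), 512, replace = TRUE, prob = c(0.25, 0.75))
    spatial_assortativity(st, "newman", net$substrate_edges)
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(100))
  expect_true(all(rs >= -1 & rs <= 1))
})

test_that("newman variant agrees with igraph's nominal assortativity", {
  set.seed(4)
  edges <- random_edges(30, 60)
  st <- sample(c("vulnerable", "protected"), 30, replace = TRUE)
  mine <- spatial_assortativity(st, "newman", edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ref <- igraph::assortativity_nominal(g, as.integer(factor(st)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("label-swap symmetry holds for both variants", {
  set.seed(5)
  edges <- random_edges(25, 50)
  st <- sample(c("vulnerable", "protected"), 25, replace = TRUE)
  sw <- ifelse(st == "vulnerable", "protected", "vulnerable")
  for (variant in c("as_printed", "newman")) {
    expect_equal(
      spatial_assortativity(st, variant, edges),
      spatial_assortativity(sw, variant, edges)
    )
  }
})

test_that("vulnerable cluster sizes match a brute-force flood fill", {
  st <- c("vulnerable", "vulnerable", "protected", "vulnerable")
  expect_equal(cluster_size_distribution(st, path4), c(2, 1))
  expect_equal(max_vulnerable_component(st, path4), 2)
  expect_equal(max_vulnerable_component(rep("protected", 4), path4), 0)
  expect_equal(cluster_size_distribution(rep("protected", 4), path4), integer(0))

  set.seed(6)
  for (i in 1:5) {
    edges <- random_edges(20, 30)
    st <- sample(c("vulnerable", "protected"), 20, replace = TRUE)
    sizes <- cluster_size_distribution(st, edges)
    comps <- bf_components(20, edges, keep = which(st == "vulnerable"))
    expect_equal(sizes, sort(lengths(comps), decreasing = TRUE))
    expect_equal(sum(sizes), sum(st == "vulnerable"))
    expect_equal(max_vulnerable_component(st, edges),
                 if (length(sizes)) max(sizes) else 0L)
  }
})

test_that("f_score scores the vulnerable class", {
  st <- c("vulnerable", "protected", "vulnerable")
  expect_equal(f_score(st, st), 1)
  expect_equal(
    f_score(
      c("vulnerable", "protected", "protected"),
      c("protected", "protected", "vulnerable")
    ),
    0
  )
  # predicted {1,2}, observed {2,3}: precision = recall = 0.5
  expect_equal(
    f_score(
      c("vulnerable", "vulnerable", "protected", "protected"),
      c("protected", "vulnerable", "vulnerable", "protected")
    ),
    0.5
  )
  expect_true(is.na(f_score(rep("protected", 3), rep("protected", 3))))
})
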