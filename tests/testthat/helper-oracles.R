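# Small constructors and brute-force oracles, independent of the package's
# igraph-backed implementations.

make_net <- function(n, edges, substrate = edges) {
  vaxscape:::new_landscape_network(n, as.matrix(edges), as.matrix(substrate))
}

adj_list <- function(n, edges) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]
    b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# mean local clustering by explicit triangle counting; degree < 2 contributes 0
bf_avg_clustering <- function(n, edges) {
  adj <- adj_list(n, edges)
  cc <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    d <- length(nb)
    if (d < 2) return(0)
    links <- 0
    for (x in seq_len(d - 1)) {
      for (y in (x + 1):d) {
        if (nb[y] %in% adj[[nb[x]]]) links <- links + 1
      }
    }
    2 * links / (d * (d - 1))
  }, numeric(1))
  mean(cc)
}

bf_components <- function(n, edges, keep = seq_len(n)) {
  adj <- adj_list(n, edges)
  seen <- rep(FALSE, n)
  inset <- rep(FALSE, n)
  inset[keep] <- TRUE
  comps <- list()
  for (s in keep) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(stack) > 0) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, u)
      for (v in adj[[u]]) {
        if (inset[v] && !seen[v]) {
          seen[v] <- TRUE
          stack <- c(stack, v)
        }
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

# mean geodesic over the largest component, by BFS from every node
bf_avg_path <- function(n, edges) {
  comps <- bf_components(n, edges)
  giant <- comps[[which.max(lengths(comps))]]
  adj <- adj_list(n, edges)
  total <- 0
  pairs <- 0
  for (s in giant) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        if (v %in% giant && is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          queue <- c(queue, v)
        }
      }
    }
    total <- total + sum(dist[setdiff(giant, s)])
    pairs <- pairs + length(giant) - 1
  }
  total / pairs
}

bf_global_distance <- function(X, edges) {
  Sinv <- solve(cov(X))
  vals <- vapply(seq_len(nrow(edges)), function(e) {
    d <- X[edges[e, 1], ] - X[edges[e, 2], ]
    drop(t(d) %*% Sinv %*% d)
  }, numeric(1))
  mean(vals)
}

random_edges <- function(n, m) {
  all_pairs <- t(combn(n, 2))
  all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE]
}

ring_edges <- function(n, k) {
  do.call(rbind, lapply(seq_len(k / 2), function(o) {
    cbind(seq_len(n), (seq_len(n) + o - 1L) %% n + 1L)
  }))
}
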