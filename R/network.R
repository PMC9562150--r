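#' Landscape networks of communities
#'
#' A `landscape_network` is an undirected graph whose nodes are communities
#' (counties, municipalities) and whose edges are social ties between them.
#' Alongside the (possibly rewired) interaction edges it keeps the *spatial
#' substrate*: the unrewired ring lattice over the same nodes, which stands in
#' for geographic adjacency whenever spatial clustering is measured.
#'
#' @param n_nodes Number of nodes; ids are `1:n_nodes`.
#' @param edges Two-column integer matrix of undirected edges.
#' @param substrate_edges Two-column integer matrix of spatial-adjacency edges
#'   (may have zero rows when unknown, e.g. for thresholded empirical data).
#' @param rewiring_p The rewiring probability used to generate the network, or
#'   `NA` when unknown.
#' @returns An object of class `landscape_network` with fields `n_nodes`,
#'   `edges`, `substrate_edges`, `rewiring_p`, `mean_degree`.
#' @keywords internal
new_landscape_network <- function(n_nodes, edges, substrate_edges, rewiring_p = NA_real_) {
  edges <- canonical_edges(edges, n_nodes)
  substrate_edges <- canonical_edges(substrate_edges, n_nodes)
  structure(
    list(
      n_nodes = as.integer(n_nodes),
      edges = edges,
      substrate_edges = substrate_edges,
      rewiring_p = rewiring_p,
      mean_degree = if (n_nodes > 0) 2 * nrow(edges) / n_nodes else 0
    ),
    class = "landscape_network"
  )
}

# canonical undirected form: a < b, sorted, unique, no self-loops allowed
canonical_edges <- function(edges, n_nodes) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  if (any(edges < 1L) || any(edges > n_nodes)) {
    abort("Edge endpoints must lie in 1..n_nodes.")
  }
  if (any(edges[, 1] == edges[, 2])) abort("Self-loops are not allowed.")
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  ord <- order(a, b)
  out <- cbind(a = a[ord], b = b[ord])
  if (anyDuplicated(out)) abort("Duplicate edges are not allowed.")
  out
}

#' @export
print.landscape_network <- function(x, ...) {
  cat(sprintf(
    "<landscape_network> %d nodes, %d edges (mean degree %.2f), p = %s, %d substrate edges\n",
    x$n_nodes, nrow(x$edges), x$mean_degree,
    ifelse(is.na(x$rewiring_p), "unknown", format(x$rewiring_p)),
    nrow(x$substrate_edges)
  ))
  invisible(x)
}

ring_lattice_edges <- function(n, k) {
  stopifnot(k %% 2 == 0, k >= 2, n > k)
  i <- rep(seq_len(n), k / 2)
  off <- rep(seq_len(k / 2), each = n)
  j <- (i + off - 1L) %% n + 1L
  cbind(i, j)
}

#' Generate a Watts-Strogatz small-world landscape
#'
#' Builds a ring lattice on `n` nodes where each node is joined to its `k`
#' nearest neighbours, then applies the classic single-endpoint rewiring: each
#' lattice edge, visited in order, has its far endpoint replaced by a uniformly
#' random node with probability `p`, rejecting self-loops and duplicate edges.
#' The unrewired lattice is retained as the spatial substrate, so `p = 0` gives
#' `edges` identical to `substrate_edges` and rewiring conserves the edge count
#' `n * k / 2` exactly.
#'
#' @param n Number of nodes (communities).
#' @param k Even mean degree of the underlying lattice, `2 <= k < n`.
#' @param p Rewiring probability in `[0, 1]`; `p = 0` is a pure ring
#'   (fully spatial), `p = 1` is fully aspatial.
#' @param seed Optional integer seed for reproducibility.
#' @returns A [landscape_network][new_landscape_network].
#' @examples
#' net <- ws_network(64, 6, 0.1, seed = 1)
#' net
#' @export
ws_network <- function(n, k, p, seed = NULL) {
  if (length(k) != 1 || k %% 2 != 0 || k < 2 || k >= n) {
    abort("`k` must be an even count with 2 <= k < n.")
  }
  if (p < 0 || p > 1) abort("`p` must be a probability in [0, 1].")
  lattice <- ring_lattice_edges(n, k)
  edges <- lattice
  if (p > 0) {
    with_seed(seed, {
      keys <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(edges))
      ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
      for (e in seq_len(nrow(edges))) {
        assign(ekey(edges[e, 1], edges[e, 2]), TRUE, envir = keys)
      }
      rewire <- runif(nrow(edges)) < p
      for (e in which(rewire)) {
        a <- edges[e, 1]
        b <- edges[e, 2]
        for (try in seq_len(200)) {
          cand <- sample.int(n, 1)
          if (cand != a && !exists(ekey(a, cand), envir = keys, inherits = FALSE)) {
            rm(list = ekey(a, b), envir = keys)
            assign(ekey(a, cand), TRUE, envir = keys)
            edges[e, 2] <- cand
            break
          }
        }
      }
    })
  }
  net <- new_landscape_network(n, edges, lattice, rewiring_p = p)
  stopifnot(nrow(net$edges) == n * k / 2)
  net
}

#' Convert a landscape network to an igraph object
#'
#' @param net A [landscape_network][new_landscape_network].
#' @param substrate Use the spatial substrate instead of the interaction edges?
#' @returns An [igraph::graph] with `net$n_nodes` vertices.
#' @export
as_igraph <- function(net, substrate = FALSE) {
  edges <- if (substrate) net$substrate_edges else net$edges
  igraph::graph_from_edgelist(edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, net$n_nodes - max(edges, 0L)))
}

#' Structural metrics of a landscape network
#'
#' Average local clustering coefficient (nodes of degree < 2 contribute 0) and
#' mean pairwise geodesic distance. Path lengths are computed on the largest
#' connected component only; the fraction of nodes it covers is reported so
#' that heavily fragmented networks are visible in the output.
#'
#' @inheritParams as_igraph
#' @returns A one-row tibble with columns `avg_clustering`,
#'   `avg_shortest_path`, `component_fraction`, `n_nodes`, `n_edges`.
#' @export
network_metrics <- function(net) {
  if (nrow(net$edges) == 0) abort("Network has no edges; path length is undefined.")
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  tibble(
    avg_clustering = cc,
    avg_shortest_path = igraph::mean_distance(giant),
    component_fraction = max(comp$csize) / net$n_nodes,
    n_nodes = net$n_nodes,
    n_edges = nrow(net$edges)
  )
}

#' Small-worldness coefficient
#'
#' Computes `sigma = (c / c_rand) / (l / l_rand)` where `c` and `l` are the
#' network's average clustering coefficient and mean shortest path, and
#' `c_rand`, `l_rand` are means over an ensemble of `n_random` random graphs
#' with the same number of nodes and edges (Erdos-Renyi G(n, m) null). Values
#' much larger than 1 indicate small-world structure.
#'
#' @inheritParams as_igraph
#' @param n_random Size of the random reference ensemble.
#' @param seed Optional integer seed.
#' @returns A single number.
#' @export
small_worldness <- function(net, n_random = 20, seed = NULL) {
  obs <- network_metrics(net)
  refs <- with_seed(seed, {
    purrr::map(seq_len(n_random), function(i) {
      g <- igraph::sample_gnm(net$n_nodes, nrow(net$edges))
      comp <- igraph::components(g)
      giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
      c(
        c = igraph::transitivity(g, type = "localaverage", isolates = "zero"),
        l = igraph::mean_distance(giant)
      )
    })
  })
  c_rand <- mean(purrr::map_dbl(refs, "c"))
  l_rand <- mean(purrr::map_dbl(refs, "l"))
  if (c_rand == 0) {
    abort("Degenerate reference ensemble: random graphs have zero clustering.")
  }
  (obs$avg_clustering / c_rand) / (obs$avg_shortest_path / l_rand)
}

#' Infer the rewiring probability matching target network metrics
#'
#' Scans a grid of rewiring probabilities, generating `reps` Watts-Strogatz
#' networks per grid point, and returns the grid value whose ensemble-mean
#' clustering coefficient and mean shortest path length minimise the
#' normalised squared distance
#' `((c - c_target)/c_target)^2 + ((l - l_target)/l_target)^2`.
#'
#' This is how the rewiring probability of an empirical connectivity network
#' (known only through its summary metrics) is projected onto the
#' Watts-Strogatz family. If a target lies outside the range the family can
#' reach at this `n` and `k` (a common situation for path-length targets,
#' since degree-heterogeneous empirical networks have shortcuts through hubs),
#' a warning is emitted and the best-matching grid value is still returned.
#'
#' @param c_target,l_target Target average clustering coefficient and average
#'   shortest path length.
#' @param n,k Size and even mean degree of the candidate networks.
#' @param p_grid Grid of rewiring probabilities; defaults to 0 plus 21
#'   log-spaced points in `[1e-3, 1]`.
#' @param reps Networks generated per grid point.
#' @param seed Optional integer seed.
#' @returns The best-matching probability, with the full scan attached as
#'   attribute `"scan"` (a tibble with columns `p`, `c_mean`, `l_mean`,
#'   `distance`).
#' @export
infer_rewiring_p <- function(c_target, l_target, n, k,
                             p_grid = NULL, reps = 10, seed = NULL) {
  p_grid <- p_grid %||% c(0, 10^seq(-3, 0, length.out = 21))
  stopifnot(length(p_grid) >= 1, reps >= 1)
  scan <- with_seed(seed, {
    purrr::map_dfr(p_grid, function(p) {
      ms <- purrr::map_dfr(seq_len(reps), function(r) {
        network_metrics(ws_network(n, k, p))
      })
      tibble(p = p, c_mean = mean(ms$avg_clustering), l_mean = mean(ms$avg_shortest_path))
    })
  })
  scan$distance <- ((scan$c_mean - c_target) / c_target)^2 +
    ((scan$l_mean - l_target) / l_target)^2
  c_max <- 3 * (k - 2) / (4 * (k - 1))
  if (c_target > c_max + 1e-9 || l_target < min(scan$l_mean) || l_target > max(scan$l_mean)) {
    warn("Target metrics lie outside the reachable range; returning the best-effort match.")
  }
  best <- which.min(scan$distance)
  structure(scan$p[best], scan = scan)
}

#' Threshold a weighted edge list into a landscape network
#'
#' Keeps edges whose weight is strictly greater than `threshold` (weights are
#' then discarded), drops nodes left isolated, and relabels the survivors
#' `1..n`. This is the standard reduction of a social-connectedness-index
#' style weighted network to an unweighted interaction network. The spatial
#' substrate is left empty (unknown) and should be supplied separately from a
#' spatial adjacency list when clustering metrics are needed.
#'
#' @param edge_table Data frame with columns `node_a`, `node_b`, `weight`.
#' @param threshold Weight cutoff; strict inequality is used.
#' @returns A [landscape_network][new_landscape_network] whose attribute
#'   `"node_labels"` maps the new ids back to the original ones.
#' @export
threshold_weighted_edges <- function(edge_table, threshold) {
  need <- c("node_a", "node_b", "weight")
  if (!all(need %in% names(edge_table))) {
    abort(paste0("`edge_table` must have columns ", paste(need, collapse = ", "), "."))
  }
  w <- edge_table$weight
  bad <- which(is.na(edge_table$node_a) | is.na(edge_table$node_b) | is.na(w) | w < 0 |
    edge_table$node_a == edge_table$node_b)
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed edge rows (missing fields, negative weight, or self-loop): ",
      paste(head(bad, 20), collapse = ", ")
    ))
  }
  keep <- edge_table[w > threshold, , drop = FALSE]
  labels <- sort(unique(c(keep$node_a, keep$node_b)))
  a <- match(keep$node_a, labels)
  b <- match(keep$node_b, labels)
  dedup <- !duplicated(cbind(pmin(a, b), pmax(a, b)))
  net <- new_landscape_network(
    length(labels), cbind(a, b)[dedup, , drop = FALSE],
    matrix(integer(0), ncol = 2)
  )
  attr(net, "node_labels") <- labels
  net
}

#' Read a weighted edge list from a plain-text file
#'
#' Three whitespace- or comma-separated columns (`node_a`, `node_b`,
#' `weight`); a header row is optional and lines starting with `#` are
#' ignored. Rows that do not parse are reported with their line numbers.
#'
#' @param path Path to the file.
#' @returns A tibble with columns `node_a`, `node_b`, `weight`.
#' @export
read_weighted_edges <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) abort("No data lines in file.")
  split_row <- function(x) strsplit(trimws(x), "[,[:space:]]+")[[1]]
  rows <- lapply(lines[idx], split_row)
  first <- suppressWarnings(as.numeric(rows[[1]]))
  has_header <- any(is.na(first))
  if (has_header) {
    rows <- rows[-1]
    idx <- idx[-1]
  }
  bad_len <- which(lengths(rows) != 3)
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad_num <- which(vapply(vals, function(v) length(v) == 3 && anyNA(v), logical(1)))
  bad <- sort(union(bad_len, bad_num))
  if (length(bad) > 0) {
    abort(paste0("Malformed rows at lines: ", paste(idx[bad], collapse = ", ")))
  }
  m <- do.call(rbind, vals)
  tibble(node_a = m[, 1], node_b = m[, 2], weight = m[, 3])
}

#' Write a landscape network as plain-text edge lists
#'
#' The interaction edges go to `path`; if the network carries a spatial
#' substrate it is written alongside with suffix `".substrate"`.
#'
#' @inheritParams as_igraph
#' @param path Output path for the two-column edge list.
#' @returns `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, row.names = FALSE, col.names = c("a", "b"))
  if (nrow(net$substrate_edges) > 0) {
    utils::write.table(net$substrate_edges, paste0(path, ".substrate"),
      row.names = FALSE, col.names = c("a", "b")
    )
  }
  invisible(path)
}

#' Read a landscape network written by [write_network()]
#'
#' @param path Path to the edge list; a `.substrate` companion file is picked
#'   up automatically when present.
#' @param n_nodes Total node count; defaults to the largest id seen.
#' @returns A [landscape_network][new_landscape_network].
#' @export
read_network <- function(path, n_nodes = NULL) {
  edges <- as.matrix(utils::read.table(path, header = TRUE))
  sub_path <- paste0(path, ".substrate")
  sub <- if (file.exists(sub_path)) {
    as.matrix(utils::read.table(sub_path, header = TRUE))
  } else {
    matrix(integer(0), ncol = 2)
  }
  n_nodes <- n_nodes %||% max(edges, sub)
  new_landscape_network(n_nodes, edges, sub)
}
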