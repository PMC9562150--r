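#' Edge-type mixing fractions on the spatial substrate
#'
#' Classifies every spatial edge by the statuses of its endpoints:
#' vulnerable-vulnerable (`vv`), protected-protected (`pp`), or mixed (`vp`).
#'
#' @param statuses Character vector of `"vulnerable"` / `"protected"`, one per
#'   node.
#' @param spatial_edges Two-column integer matrix of spatial-adjacency edges.
#' @returns A one-row tibble with columns `vv`, `pp`, `vp` summing to 1.
#' @export
mixing_counts <- function(statuses, spatial_edges) {
  if (nrow(spatial_edges) == 0) abort("Empty spatial edge set.")
  va <- statuses[spatial_edges[, 1]] == "vulnerable"
  vb <- statuses[spatial_edges[, 2]] == "vulnerable"
  m <- nrow(spatial_edges)
  tibble(vv = sum(va & vb) / m, pp = sum(!va & !vb) / m, vp = sum(xor(va, vb)) / m)
}

#' Spatial assortativity of vulnerability
#'
#' Categorical assortative-mixing coefficient of the vulnerable/protected
#' labels over spatial edges. Two variants are provided:
#'
#' * `"as_printed"` evaluates
#'   `r = ((VV + PP) - ((VV+VP)^2 + (PP+VP)^2)) / (1 - ((VV+VP)^2 + (PP+VP)^2))`,
#'   i.e. the marginal of each class is taken as its edge fraction plus the
#'   whole mixed fraction. Because mixed edges are counted fully towards both
#'   classes, the marginals can exceed 1 and the coefficient is not bounded
#'   below by -1 (for `VV = PP = VP = 1/3` it equals -2).
#' * `"newman"` is the standard categorical assortativity with edge-end
#'   accounting: marginals `VV + VP/2` and `PP + VP/2`. It is bounded in
#'   `[-1, 1]` and equals 0 in expectation for randomly placed labels.
#'
#' Both equal 1 under perfect segregation (`vp = 0` with both classes
#' present). When only one class is present the coefficient is undefined and
#' `NA` is returned.
#'
#' @param counts Either a mixing tibble from [mixing_counts()] or a character
#'   status vector (in which case `spatial_edges` must be given).
#' @param variant `"as_printed"` (default) or `"newman"`.
#' @param spatial_edges Spatial edges, used when `counts` is a status vector.
#' @returns A single number, or `NA_real_` when undefined.
#' @examples
#' spatial_assortativity(tibble::tibble(vv = 1 / 3, pp = 1 / 3, vp = 1 / 3))
#' spatial_assortativity(tibble::tibble(vv = 1 / 3, pp = 1 / 3, vp = 1 / 3), "newman")
#' @export
spatial_assortativity <- function(counts, variant = c("as_printed", "newman"),
                                  spatial_edges = NULL) {
  variant <- match.arg(variant)
  if (is.character(counts)) {
    counts <- mixing_counts(counts, spatial_edges)
  }
  vv <- counts$vv
  pp <- counts$pp
  vp <- counts$vp
  half <- if (variant == "newman") vp / 2 else vp
  a2 <- (vv + half)^2 + (pp + half)^2
  den <- 1 - a2
  if (den == 0) return(NA_real_)
  ((vv + pp) - a2) / den
}

# adjacency list over an edge matrix, for flood fills
adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) == 0) return(adj)
  split_a <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
  split_b <- split(edges[, 1], factor(edges[, 2], levels = seq_len(n)))
  for (i in seq_len(n)) adj[[i]] <- c(split_a[[i]], split_b[[i]])
  adj
}

#' Connected clusters of vulnerable communities
#'
#' Component sizes of the subgraph induced by vulnerable nodes on the spatial
#' substrate, in decreasing order. The largest of these is the *maximum
#' outbreak size*: the biggest pool of contiguous under-vaccinated
#' communities an introduction could percolate through.
#'
#' @inheritParams mixing_counts
#' @returns `cluster_size_distribution()`: a decreasing integer vector (empty
#'   when no node is vulnerable); `max_vulnerable_component()`: a single
#'   count, 0 when no node is vulnerable.
#' @export
cluster_size_distribution <- function(statuses, spatial_edges) {
  vul <- which(statuses == "vulnerable")
  if (length(vul) == 0) return(integer(0))
  keep <- spatial_edges[
    statuses[spatial_edges[, 1]] == "vulnerable" &
      statuses[spatial_edges[, 2]] == "vulnerable", ,
    drop = FALSE
  ]
  g <- igraph::graph_from_edgelist(
    matrix(match(keep, vul), ncol = 2),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, length(vul) - igraph::gorder(g))
  sort(igraph::components(g)$csize, decreasing = TRUE)
}

#' @rdname cluster_size_distribution
#' @export
max_vulnerable_component <- function(statuses, spatial_edges) {
  sizes <- cluster_size_distribution(statuses, spatial_edges)
  if (length(sizes) == 0) 0L else as.integer(sizes[1])
}

#' F-score of a predicted vulnerability map
#'
#' Harmonic mean of precision and recall for the vulnerable class, comparing
#' predicted to observed statuses over the same node set.
#'
#' @param predicted,observed Character status vectors of equal length.
#' @returns A number in `[0, 1]`, or `NA_real_` when neither vector contains a
#'   vulnerable node (undefined).
#' @export
f_score <- function(predicted, observed) {
  if (length(predicted) != length(observed)) abort("Status vectors differ in length.")
  pv <- predicted == "vulnerable"
  ov <- observed == "vulnerable"
  if (!any(pv) && !any(ov)) return(NA_real_)
  tp <- sum(pv & ov)
  if (tp == 0) return(0)
  precision <- tp / sum(pv)
  recall <- tp / sum(ov)
  2 * precision * recall / (precision + recall)
}
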