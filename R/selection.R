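#' Mahalanobis gap between two trait vectors
#'
#' The per-edge dissimilarity `(x_i - x_j)' S^-1 (x_i - x_j)` used throughout
#' the social-selection machinery. Note this is the quadratic form itself (no
#' square root), matching how the edge-wise distance enters the global mean;
#' set `root = TRUE` for the conventional rooted Mahalanobis distance.
#'
#' @param x_i,x_j Numeric trait vectors of equal length.
#' @param covariance Trait covariance matrix `S`.
#' @param root Return the square root of the quadratic form?
#' @returns A non-negative number.
#' @export
pairwise_distance <- function(x_i, x_j, covariance, root = FALSE) {
  if (length(x_i) != length(x_j) || length(x_i) != nrow(covariance)) {
    abort("Trait vectors and covariance dimensions do not match.")
  }
  d <- x_i - x_j
  q <- drop(t(d) %*% solve_spd(covariance) %*% d)
  if (root) sqrt(q) else q
}

# inverse with a small ridge when S is (near) singular
solve_spd <- function(S) {
  d <- nrow(S)
  tr <- sum(diag(S))
  if (tr <= 0) abort("Degenerate attributes: zero covariance.")
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    inv <- solve(S + diag(1e-8 * tr / d, d))
  }
  inv
}

# edge-wise quadratic forms, vectorised; X is the node x trait matrix
edge_quad_forms <- function(X, edges, Sinv) {
  D <- X[edges[, 1], , drop = FALSE] - X[edges[, 2], , drop = FALSE]
  rowSums((D %*% Sinv) * D)
}

#' Global attribute distance over a network's edges
#'
#' The mean Mahalanobis quadratic form over all interaction edges, with the
#' trait covariance `S` estimated once from all node rows (sample covariance).
#' Small values mean adjacent communities hold similar attributes.
#'
#' @param net A [landscape_network][new_landscape_network].
#' @param nodes Node tibble carrying trait columns (see
#'   [traits_from_hesitancy()]).
#' @param traits Optional character vector naming the trait columns.
#' @returns A non-negative number.
#' @export
global_distance <- function(net, nodes, traits = NULL) {
  if (nrow(net$edges) == 0) abort("Network has no edges.")
  X <- trait_matrix(nodes, traits)
  if (nrow(X) != net$n_nodes) abort("`nodes` must have one row per network node.")
  S <- cov(X)
  if (all(S == 0)) return(0)
  mean(edge_quad_forms(X, net$edges, solve_spd(S)))
}

#' Baseline attribute distance under random placement
#'
#' Monte Carlo estimate of the global distance when attributes are assigned to
#' nodes uniformly at random: the mean of [global_distance()] over `n_perm`
#' random permutations of the node rows. This is the null reference `mu_tilde`
#' in the selection parameter `beta = 1 - mu / mu_tilde`.
#'
#' @inheritParams global_distance
#' @param n_perm Number of random permutations.
#' @param seed Optional integer seed.
#' @returns A non-negative number.
#' @export
baseline_distance <- function(net, nodes, n_perm = 100, seed = NULL, traits = NULL) {
  stopifnot(n_perm >= 1)
  X <- trait_matrix(nodes, traits)
  S <- cov(X)
  if (all(S == 0)) return(0)
  Sinv <- solve_spd(S)
  with_seed(seed, {
    mean(purrr::map_dbl(seq_len(n_perm), function(i) {
      perm <- sample.int(nrow(X))
      mean(edge_quad_forms(X[perm, , drop = FALSE], net$edges, Sinv))
    }))
  })
}

#' Social-selection parameter from observed and baseline distances
#'
#' `beta = 1 - mu / mu_random`. Positive values mean connected communities are
#' more similar than random placement would make them (homophily); zero means
#' no selection; negative values mean neighbours are more dissimilar than
#' random.
#'
#' @param mu Observed global distance.
#' @param mu_random Baseline (random-placement) distance, `> 0`.
#' @returns A real number `<= 1`.
#' @export
selection_beta <- function(mu, mu_random) {
  if (mu_random <= 0) {
    abort("Degenerate attributes: the random-placement baseline distance is zero.")
  }
  1 - mu / mu_random
}

#' Anneal node attributes to a target selection level
#'
#' Rearranges which node holds which (trait vector, hesitancy, status) tuple
#' until the selection parameter `beta` reaches `beta_target`. Two nodes are
#' picked uniformly at random and their full tuples exchanged; the swap is
#' kept only if it moves `beta` strictly closer to the target, and annealing
#' stops once `|beta - beta_target| <= tol` or the proposal budget is
#' exhausted (in which case the result is flagged unconverged rather than
#' erroring). Because swaps only permute rows, the multiset of hesitancy
#' values and the number of vulnerable nodes are conserved exactly, and the
#' sample covariance `S` (estimated once up front) is unchanged throughout.
#'
#' @inheritParams global_distance
#' @param beta_target Desired selection level, `0 <= beta_target < 1`.
#' @param tol Convergence tolerance on `beta`.
#' @param max_swaps Proposal budget.
#' @param n_perm Permutations for the baseline distance `mu_tilde`.
#' @param seed Optional integer seed.
#' @returns A list of class `vh_anneal` with elements `nodes` (the permuted
#'   tibble), `beta`, `mu`, `mu_random`, `swap_count`, `converged`.
#' @examples
#' net <- ws_network(128, 6, 0, seed = 1)
#' nodes <- traits_from_hesitancy(sample_hesitancy(128, calibrate_lambda(0.25), seed = 2))
#' fit <- anneal_to_beta(net, nodes, beta_target = 0.4, seed = 3)
#' glance(fit)
#' @export
anneal_to_beta <- function(net, nodes, beta_target, tol = 0.01,
                           max_swaps = 200000, n_perm = 100, seed = NULL,
                           traits = NULL) {
  if (beta_target < 0 || beta_target >= 1) {
    abort("`beta_target` must satisfy 0 <= beta_target < 1.")
  }
  traits <- trait_columns(nodes, traits)
  X <- as.matrix(nodes[traits])
  if (nrow(X) != net$n_nodes) abort("`nodes` must have one row per network node.")
  S <- cov(X)
  if (all(S == 0)) abort("Degenerate attributes: all nodes identical.")
  Sinv <- solve_spd(S)
  res <- with_seed(seed, {
    mu_random <- mean(purrr::map_dbl(seq_len(n_perm), function(i) {
      perm <- sample.int(nrow(X))
      mean(edge_quad_forms(X[perm, , drop = FALSE], net$edges, Sinv))
    }))
    if (mu_random <= 0) abort("Degenerate attributes: baseline distance is zero.")
    out <- anneal_swaps_cpp(
      net$edges - 1L, X, Sinv, mu_random, beta_target, tol, as.integer(max_swaps)
    )
    out$mu_random <- mu_random
    out
  })
  perm <- res$perm + 1L
  permuted <- nodes
  move_cols <- c("eta", "status", traits)
  permuted[move_cols] <- nodes[perm, move_cols]
  attr(permuted, "trait_names") <- traits
  structure(
    list(
      nodes = permuted, beta = res$beta, mu = res$mu, mu_random = res$mu_random,
      swap_count = res$swap_count, proposals = res$proposals,
      converged = res$converged, beta_target = beta_target, tol = tol
    ),
    class = "vh_anneal"
  )
}

#' @export
print.vh_anneal <- function(x, ...) {
  cat(sprintf(
    "<vh_anneal> beta = %.4f (target %.3f, tol %.3f), %d swaps, %s\n",
    x$beta, x$beta_target, x$tol, x$swap_count,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @rdname anneal_to_beta
#' @param x A `vh_anneal` object.
#' @param ... Unused.
#' @export
glance.vh_anneal <- function(x, ...) {
  tibble(
    beta = x$beta, beta_target = x$beta_target, mu = x$mu,
    mu_random = x$mu_random, swap_count = x$swap_count,
    proposals = x$proposals, converged = x$converged
  )
}

#' @rdname anneal_to_beta
#' @export
tidy.vh_anneal <- function(x, ...) glance.vh_anneal(x, ...)

#' Measure the selection level realised on a network
#'
#' Convenience wrapper returning `beta`, `mu` and `mu_tilde` for a node table
#' as placed on the network.
#'
#' @inheritParams baseline_distance
#' @returns A one-row tibble with `beta`, `mu`, `mu_random`.
#' @export
measure_selection <- function(net, nodes, n_perm = 100, seed = NULL, traits = NULL) {
  mu <- global_distance(net, nodes, traits)
  mu_r <- baseline_distance(net, nodes, n_perm = n_perm, seed = seed, traits = traits)
  tibble(beta = selection_beta(mu, mu_r), mu = mu, mu_random = mu_r)
}
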