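#' Hesitancy-trigger / conformity index for intervention targeting
#'
#' For each community `i` the index is
#' `zeta_i = exp(sum_u z(X_ui)) * (epsilon + mean_j mu_ij)^-1`, where
#' `z(X_ui)` is the across-nodes z-score of trait `u` at node `i` (the
#' "hesitancy triggers" factor: how elevated the node's hesitancy-linked
#' traits are) and the second factor is the inverse mean Mahalanobis gap to
#' its interaction-network neighbours (the "conformity" factor: how similar
#' the neighbourhood is). High-zeta nodes sit in high-trait, high-conformity
#' pockets — exactly where social selection breeds hesitant clusters — and
#' can be ranked for intervention without any hesitancy data. Isolated nodes
#' get `NA` and are excluded from rankings.
#'
#' @inheritParams global_distance
#' @param epsilon Small positive guard added to the mean neighbour distance
#'   before inversion, for the degenerate case of identical neighbours.
#' @returns A tibble with columns `node`, `zeta`.
#' @export
zeta_index <- function(net, nodes, epsilon = 1e-9, traits = NULL) {
  X <- trait_matrix(nodes, traits)
  if (nrow(X) != net$n_nodes) abort("`nodes` must have one row per network node.")
  Z <- scale(X)
  # constant traits have sd 0; their z-score contribution is 0
  Z[!is.finite(Z)] <- 0
  triggers <- exp(rowSums(Z))
  S <- cov(X)
  Sinv <- solve_spd(S)
  q <- edge_quad_forms(X, net$edges, Sinv)
  num <- rep(0, net$n_nodes)
  deg <- rep(0, net$n_nodes)
  for (col in 1:2) {
    agg <- tapply(q, edges_col <- net$edges[, col], sum)
    idx <- as.integer(names(agg))
    num[idx] <- num[idx] + as.numeric(agg)
    cnt <- table(edges_col)
    deg[as.integer(names(cnt))] <- deg[as.integer(names(cnt))] + as.numeric(cnt)
  }
  zeta <- ifelse(deg > 0, triggers / (epsilon + num / deg), NA_real_)
  tibble(node = seq_len(net$n_nodes), zeta = zeta)
}

#' Choose intervention targets under a budget
#'
#' Three targeting rules, each selecting `round(budget_fraction * n)` nodes:
#'
#' * `"target_selection"`: the top nodes by the [zeta_index()] — the
#'   data-light strategy that needs traits and the network but no hesitancy
#'   measurements.
#' * `"target_high_hesitancy"`: the top nodes by observed `eta` — the
#'   best-case comparator that assumes full hesitancy data.
#' * `"target_random"`: a uniform sample — the worst-case comparator.
#'
#' Ties are broken by node id (ascending), so selection is deterministic for
#' the two ranked strategies.
#'
#' @inheritParams zeta_index
#' @param strategy One of `"target_selection"`, `"target_high_hesitancy"`,
#'   `"target_random"`.
#' @param budget_fraction Fraction of nodes to target, in (0, 1).
#' @param seed Optional integer seed (used by `"target_random"` only).
#' @returns An integer vector of node ids.
#' @export
select_targets <- function(strategy = c("target_selection", "target_high_hesitancy",
                                        "target_random"),
                           net, nodes, budget_fraction = 0.10, seed = NULL,
                           traits = NULL) {
  strategy <- match.arg(strategy)
  if (budget_fraction < 0 || budget_fraction >= 1) {
    abort("`budget_fraction` must lie in [0, 1); 0 selects nothing (null strategy).")
  }
  n_targets <- floor(net$n_nodes * budget_fraction + 0.5)
  switch(strategy,
    target_selection = {
      z <- zeta_index(net, nodes, traits = traits)
      ranked <- z$node[order(-z$zeta, z$node, na.last = TRUE)]
      ranked <- ranked[!is.na(z$zeta[ranked])]
      head(ranked, n_targets)
    },
    target_high_hesitancy = {
      head(nodes$node[order(-nodes$eta, nodes$node)], n_targets)
    },
    target_random = with_seed(seed, sample(nodes$node, n_targets))
  )
}

#' Protect targeted communities
#'
#' Each targeted *vulnerable* community has its hesitancy resampled from the
#' population law conditional on being protected — `Exp(lambda)` truncated to
#' `[0, 1 - rho)` — and its status set to protected. Targeting an
#' already-protected node is a no-op, and every non-targeted value is left
#' untouched bit-for-bit.
#'
#' @param nodes Node tibble with `eta` and `status`.
#' @param targets Integer vector of node ids.
#' @param lambda Exponential rate of the hesitancy law.
#' @param rho Herd-immunity threshold.
#' @param seed Optional integer seed.
#' @returns The updated node tibble.
#' @export
apply_protection <- function(nodes, targets, lambda, rho = 0.95, seed = NULL) {
  if (!all(targets %in% nodes$node)) abort("`targets` must be a subset of node ids.")
  hit <- nodes$node %in% targets & nodes$status == "vulnerable"
  if (!any(hit)) return(nodes)
  # keep resampled values clear of the classification boundary
  thr <- (1 - rho) - 1e-8
  p_thr <- 1 - exp(-lambda * thr)
  with_seed(seed, {
    u <- runif(sum(hit))
    nodes$eta[hit] <- -log(1 - u * p_thr) / lambda
  })
  nodes$status[hit] <- "protected"
  nodes
}

#' Evaluate an intervention strategy against a no-action control
#'
#' For the three targeting strategies, each replicate builds a
#' social-selection scenario — a Watts-Strogatz landscape (default `p = 0.2`,
#' matching the rewiring probability inferred for empirical social
#' connectivity), exponential hesitancy with about 25% of communities
#' vulnerable, traits derived from hesitancy, attributes annealed to
#' `beta_target` — measures the spatial assortativity `r_control` of the
#' untreated state, applies the strategy, and measures `r_post`. For
#' `"reroute"`, each replicate instead runs the social-influence process (10%
#' initially vulnerable, up to 25%) twice from the same initial state, with
#' and without edge rerouting at probability `omega`, and compares the final
#' clustering values.
#'
#' Replicates whose control clustering is undefined (a single status class)
#' are dropped and counted.
#'
#' @param strategy One of `"target_selection"`, `"target_high_hesitancy"`,
#'   `"target_random"`, `"reroute"`.
#' @param reps Number of Monte Carlo replicates.
#' @param seed Integer seed for the whole evaluation.
#' @param n,k,p Landscape parameters.
#' @param beta_target Selection level of the scenario (targeting strategies).
#' @param alpha,omega Influence tolerance and rerouting probability (reroute
#'   strategy).
#' @param budget_fraction Targeting budget.
#' @param vulnerable_fraction Fraction of communities vulnerable in the
#'   selection scenarios.
#' @param rho Herd-immunity threshold.
#' @param gammas Trait shapes.
#' @param r_variant Assortativity variant used for the outcome measure.
#' @returns A tibble with one row per kept replicate: `strategy`, `rep`,
#'   `r_control`, `r_post`, `relative_clustering` (= `r_post / r_control`)
#'   and `clustering_difference` (= `r_post - r_control`); the number of
#'   dropped replicates is attached as attribute `"dropped"`.
#' @export
evaluate_strategy <- function(strategy = c("target_selection", "target_high_hesitancy",
                                           "target_random", "reroute"),
                              reps = 50, seed = NULL, n = 512, k = 6, p = 0.2,
                              beta_target = 0.4, alpha = 0.2, omega = 0.5,
                              budget_fraction = 0.10, vulnerable_fraction = 0.25,
                              rho = 0.95, gammas = c(income = 2, household_size = 2),
                              r_variant = "newman") {
  strategy <- match.arg(strategy)
  stopifnot(reps >= 1)
  rows <- with_seed(seed, {
    purrr::map(seq_len(reps), function(rep_i) {
      if (strategy == "reroute") {
        net <- ws_network(n, k, p)
        nodes <- sample_hesitancy(n, calibrate_lambda(0.10, rho), rho)
        params <- influence_params(alpha = alpha, rho = rho)
        control <- run_influence(net, nodes, params, r_variant = r_variant)
        treated <- run_influence_with_rerouting(net, nodes, params, omega = omega,
                                                r_variant = r_variant)$trajectory
        r_control <- glance(control)$r
        r_post <- glance(treated)$r
      } else {
        net <- ws_network(n, k, p)
        nodes <- traits_from_hesitancy(
          sample_hesitancy(n, calibrate_lambda(vulnerable_fraction, rho), rho),
          gammas
        )
        fit <- anneal_to_beta(net, nodes, beta_target)
        r_control <- spatial_assortativity(fit$nodes$status, variant = r_variant,
                                           spatial_edges = net$substrate_edges)
        targets <- select_targets(strategy, net, fit$nodes,
                                  budget_fraction = budget_fraction)
        lambda <- calibrate_lambda(vulnerable_fraction, rho)
        protected <- apply_protection(fit$nodes, targets, lambda, rho)
        r_post <- spatial_assortativity(protected$status, variant = r_variant,
                                        spatial_edges = net$substrate_edges)
      }
      tibble(strategy = strategy, rep = rep_i, r_control = r_control, r_post = r_post)
    })
  })
  out <- dplyr::bind_rows(rows)
  kept <- !is.na(out$r_control) & !is.na(out$r_post) & out$r_control != 0
  dropped <- sum(!kept)
  out <- out[kept, , drop = FALSE]
  out$relative_clustering <- out$r_post / out$r_control
  out$clustering_difference <- out$r_post - out$r_control
  attr(out, "dropped") <- dropped
  out
}
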