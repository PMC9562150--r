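#' Parameters of the social-influence diffusion model
#'
#' The influence model is a bootstrap-percolation style threshold process: at
#' each synchronous time step a community whose neighbourhood exposure meets
#' the tolerance `alpha` raises its hesitancy by `delta`; a protected node
#' crossing `1 - rho` flips to vulnerable (and never reverts). The run stops
#' at the first step where at least `stop_fraction` of communities are
#' vulnerable, at a fixed point, or after `max_steps`.
#'
#' `exposure` picks what the neighbourhood average is taken over:
#'
#' * `"status"` (default): the fraction of vulnerable nodes among the node and
#'   its neighbours. This consensus-style exposure is what the tolerances used
#'   in the study conditions (`alpha = 0.2` for an affectable society,
#'   `alpha = 0.6` for a determined one) act on: at the calibrated exponential
#'   hesitancy levels the raw hesitancy of a neighbourhood averages only a few
#'   percent, so those tolerances can only be meaningful on the status scale
#'   (see the methods vignette for the full argument).
#' * `"hesitancy"`: the mean of the raw hesitancy fractions
#'   `avg({eta_i, eta_j for all neighbours j})`, the influence rule taken
#'   literally; appropriate for tolerances on the scale of `eta`
#'   itself.
#'
#' @param alpha Tolerance: the minimum exposure required for a community's
#'   hesitancy to increase. Exposures never exceed 1, so any `alpha > 1`
#'   freezes the dynamics (useful as a no-dynamics control).
#' @param delta Hesitancy increment per firing step.
#' @param rho Herd-immunity threshold.
#' @param stop_fraction Run until this fraction of communities is vulnerable.
#' @param max_steps Hard cap on steps.
#' @param exposure `"status"` or `"hesitancy"` (see Details).
#' @returns A list of class `influence_params`.
#' @export
influence_params <- function(alpha, delta = 0.01, rho = 0.95, stop_fraction = 0.25,
                             max_steps = 1000, exposure = c("status", "hesitancy")) {
  if (alpha < 0) abort("`alpha` must be non-negative.")
  if (delta <= 0 || delta > 1) abort("`delta` must lie in (0, 1].")
  structure(
    list(
      alpha = alpha, delta = delta, rho = rho, stop_fraction = stop_fraction,
      max_steps = max_steps, exposure = match.arg(exposure)
    ),
    class = "influence_params"
  )
}

influence_adjacency <- function(net) {
  e <- net$edges
  n <- net$n_nodes
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
    x = 1, dims = c(n, n)
  )
}

neighbourhood_exposure <- function(A, eta, vulnerable, params) {
  x <- if (params$exposure == "status") as.numeric(vulnerable) else eta
  deg <- Matrix::rowSums(A)
  as.numeric((A %*% x + x) / (deg + 1))
}

#' One synchronous influence step
#'
#' Every node's exposure is evaluated against the pre-step state; all nodes at
#' or above the tolerance then increment together (`eta` capped at 1) and
#' statuses are re-derived. Already-vulnerable nodes keep incrementing when
#' their neighbourhood permits; no node ever decreases.
#'
#' @param net A [landscape_network][new_landscape_network].
#' @param nodes Node tibble with `eta` and `status`.
#' @param params An [influence_params()] object.
#' @returns The updated node tibble.
#' @export
influence_step <- function(net, nodes, params) {
  if (nrow(nodes) != net$n_nodes) abort("`nodes` must have one row per network node.")
  A <- influence_adjacency(net)
  m <- neighbourhood_exposure(A, nodes$eta, nodes$status == "vulnerable", params)
  fire <- m >= params$alpha
  nodes$eta <- pmin(nodes$eta + params$delta * fire, 1)
  nodes$status <- classify_status(nodes$eta, params$rho)
  nodes
}

new_trajectory <- function(steps, nodes, stop_reason, params, net) {
  structure(
    list(steps = steps, nodes = nodes, stop_reason = stop_reason,
         params = params, net = net),
    class = "vh_trajectory"
  )
}

#' Run the social-influence process
#'
#' Iterates [influence_step()] until the vulnerable fraction first reaches
#' `params$stop_fraction` (overshoot by the nodes that crossed simultaneously
#' in the final synchronous step is allowed and reported), a fixed point (no
#' node fired), or `params$max_steps`. Spatial assortativity of vulnerability
#' is recorded each step against the spatial substrate.
#'
#' @inheritParams influence_step
#' @param r_variant Assortativity variant recorded along the trajectory;
#'   the bounded `"newman"` form by default.
#' @returns A `vh_trajectory`: a list with `steps` (tibble of `step`,
#'   `vulnerable_fraction`, `r`), the final `nodes`, `stop_reason` (one of
#'   `"fraction_reached"`, `"fixed_point"`, `"max_steps"`), `params`, `net`.
#' @examples
#' net <- ws_network(256, 6, 0, seed = 1)
#' nodes <- sample_hesitancy(256, calibrate_lambda(0.10), seed = 2)
#' traj <- run_influence(net, nodes, influence_params(alpha = 0.2))
#' glance(traj)
#' @export
run_influence <- function(net, nodes, params, r_variant = "newman") {
  run_influence_impl(net, nodes, params, omega = 0, seed = NULL, r_variant = r_variant)$trajectory
}

#' Run social influence with protective edge rerouting
#'
#' Identical to [run_influence()] except that whenever a node flips to
#' vulnerable, each of its edges to a still-protected neighbour is,
#' independently with probability `omega`, disconnected from the new
#' vulnerable node and rerouted to a uniformly random protected node (so a
#' vulnerable-protected edge becomes protected-protected). Rerouting happens
#' immediately after the synchronous step in which the flip occurred. Edge
#' count is conserved; when no valid protected target exists the edge is left
#' in place and counted in the `rerouting_failures` attribute of the returned
#' network.
#'
#' @inheritParams run_influence
#' @param omega Per-edge rerouting probability in `[0, 1]`.
#' @param seed Optional integer seed (rerouting is the only random element).
#' @returns A list with elements `trajectory` (as [run_influence()]) and `net`
#'   (the modified network).
#' @export
run_influence_with_rerouting <- function(net, nodes, params, omega, seed = NULL,
                                         r_variant = "newman") {
  if (omega < 0 || omega > 1) abort("`omega` must lie in [0, 1].")
  run_influence_impl(net, nodes, params, omega = omega, seed = seed, r_variant = r_variant)
}

run_influence_impl <- function(net, nodes, params, omega, seed, r_variant) {
  if (nrow(nodes) != net$n_nodes) abort("`nodes` must have one row per network node.")
  init_frac <- mean(nodes$status == "vulnerable")
  if (init_frac >= params$stop_fraction) {
    abort("Initial vulnerable fraction is already at or above `stop_fraction`.")
  }
  with_seed(seed, {
    n <- net$n_nodes
    edges <- net$edges
    A <- influence_adjacency(net)
    record_r <- nrow(net$substrate_edges) > 0
    traj_r <- function(status) {
      if (record_r) {
        spatial_assortativity(status, variant = r_variant,
                              spatial_edges = net$substrate_edges)
      } else {
        NA_real_
      }
    }
    eta <- nodes$eta
    vul <- nodes$status == "vulnerable"
    steps <- list(tibble(step = 0L, vulnerable_fraction = mean(vul),
                         r = traj_r(nodes$status)))
    stop_reason <- "max_steps"
    reroute_failures <- 0L
    for (s in seq_len(params$max_steps)) {
      m <- neighbourhood_exposure(A, eta, vul, params)
      fire <- m >= params$alpha & eta < 1
      if (!any(fire)) {
        stop_reason <- "fixed_point"
        break
      }
      eta <- pmin(eta + params$delta * fire, 1)
      new_vul <- is_vulnerable(eta, params$rho)
      flipped <- which(new_vul & !vul)
      vul <- new_vul
      if (omega > 0 && length(flipped) > 0) {
        rerouted <- reroute_edges(edges, n, flipped, vul, omega)
        edges <- rerouted$edges
        reroute_failures <- reroute_failures + rerouted$failures
        if (rerouted$changed) {
          A <- Matrix::sparseMatrix(
            i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
            x = 1, dims = c(n, n)
          )
        }
      }
      status <- ifelse(vul, "vulnerable", "protected")
      steps[[length(steps) + 1L]] <- tibble(
        step = s, vulnerable_fraction = mean(vul), r = traj_r(status)
      )
      if (mean(vul) >= params$stop_fraction) {
        stop_reason <- "fraction_reached"
        break
      }
    }
    out_nodes <- nodes
    out_nodes$eta <- eta
    out_nodes$status <- ifelse(vul, "vulnerable", "protected")
    out_net <- new_landscape_network(n, edges, net$substrate_edges, net$rewiring_p)
    attr(out_net, "rerouting_failures") <- reroute_failures
    list(
      trajectory = new_trajectory(
        dplyr::bind_rows(steps), out_nodes, stop_reason, params, out_net
      ),
      net = out_net
    )
  })
}

# Replace vulnerable-protected edges of freshly flipped nodes by
# protected-protected ones, each with probability omega.
reroute_edges <- function(edges, n, flipped, vul, omega) {
  failures <- 0L
  changed <- FALSE
  protected <- which(!vul)
  if (length(protected) == 0) {
    return(list(edges = edges, failures = 0L, changed = FALSE))
  }
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(nrow(edges))) {
    assign(paste0(min(edges[e, ]), "_", max(edges[e, ])), TRUE, envir = keys)
  }
  for (v in flipped) {
    incident <- which(edges[, 1] == v | edges[, 2] == v)
    for (e in incident) {
      other <- if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
      if (vul[other]) next
      if (runif(1) >= omega) next
      # candidate protected partners for `other`, avoiding self and duplicates
      ok <- FALSE
      for (try in seq_len(50)) {
        cand <- protected[sample.int(length(protected), 1)]
        key <- paste0(min(other, cand), "_", max(other, cand))
        if (cand != other && !exists(key, envir = keys, inherits = FALSE)) {
          rm(list = paste0(min(v, other), "_", max(v, other)), envir = keys)
          assign(key, TRUE, envir = keys)
          edges[e, ] <- c(min(other, cand), max(other, cand))
          ok <- TRUE
          changed <- TRUE
          break
        }
      }
      if (!ok) failures <- failures + 1L
    }
  }
  list(edges = edges, failures = failures, changed = changed)
}

#' Combined selection-then-influence run
#'
#' Reproduces the combined generative model: hesitancy is sampled so that
#' `init_vulnerable_fraction` of communities start vulnerable, traits are
#' derived from hesitancy, the attribute layout is annealed to the requested
#' selection level `beta_target`, and the social-influence process then runs
#' until `params$stop_fraction` of communities are vulnerable.
#'
#' @inheritParams run_influence
#' @param beta_target Selection level established before diffusion starts.
#' @param seed Optional integer seed governing the whole run.
#' @param init_vulnerable_fraction Fraction of communities vulnerable at
#'   time 0.
#' @param gammas Trait shapes passed to [traits_from_hesitancy()].
#' @param tol,max_swaps,n_perm Annealing controls, see [anneal_to_beta()].
#' @returns A `vh_trajectory` whose `"anneal"` attribute holds the
#'   [anneal_to_beta()] summary.
#' @export
run_combined <- function(net, beta_target, params, seed = NULL,
                         init_vulnerable_fraction = 0.10,
                         gammas = c(income = 2, household_size = 2),
                         tol = 0.01, max_swaps = 200000, n_perm = 100,
                         r_variant = "newman") {
  with_seed(seed, {
    lambda <- calibrate_lambda(init_vulnerable_fraction, params$rho)
    nodes <- traits_from_hesitancy(
      sample_hesitancy(net$n_nodes, lambda, params$rho),
      gammas
    )
    fit <- anneal_to_beta(net, nodes, beta_target, tol = tol,
                          max_swaps = max_swaps, n_perm = n_perm)
    traj <- run_influence(net, fit$nodes, params, r_variant = r_variant)
    attr(traj, "anneal") <- glance(fit)
    traj
  })
}

#' @export
print.vh_trajectory <- function(x, ...) {
  last <- x$steps[nrow(x$steps), ]
  cat(sprintf(
    "<vh_trajectory> %d steps, stop: %s, vulnerable %.3f, r = %s\n",
    max(x$steps$step), x$stop_reason, last$vulnerable_fraction,
    ifelse(is.na(last$r), "NA", sprintf("%.3f", last$r))
  ))
  invisible(x)
}

#' Tidiers for influence trajectories
#'
#' `tidy()` returns the per-step record; `glance()` a one-row summary of the
#' end state, including the size distribution of vulnerable clusters on the
#' spatial substrate.
#'
#' @param x A `vh_trajectory`.
#' @param ... Unused.
#' @returns A tibble.
#' @export
tidy.vh_trajectory <- function(x, ...) x$steps

#' @rdname tidy.vh_trajectory
#' @export
glance.vh_trajectory <- function(x, ...) {
  last <- x$steps[nrow(x$steps), ]
  has_sub <- nrow(x$net$substrate_edges) > 0
  sizes <- if (has_sub) {
    cluster_size_distribution(x$nodes$status, x$net$substrate_edges)
  } else {
    integer(0)
  }
  tibble(
    n_steps = max(x$steps$step),
    stop_reason = x$stop_reason,
    vulnerable_fraction = last$vulnerable_fraction,
    r = last$r,
    n_clusters = length(sizes),
    max_cluster = if (length(sizes)) as.integer(sizes[1]) else 0L
  )
}
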