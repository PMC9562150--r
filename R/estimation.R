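#' Bundle two-timepoint community data
#'
#' Container for the empirical-estimation workflow: per-node hesitancy at two
#' times plus traits, the social interaction edges (over which influence
#' spreads) and the spatial adjacency edges (over which clustering is
#' measured).
#'
#' @param nodes Tibble with columns `node` (ids `1..n`), `eta_t1`, `eta_t2`,
#'   and one numeric column per trait.
#' @param social_edges,spatial_edges Two-column integer edge matrices.
#' @param rho Herd-immunity threshold used to derive statuses.
#' @returns A list of class `two_timepoint_data` with derived columns
#'   `status_t1`, `status_t2`.
#' @export
two_timepoint_data <- function(nodes, social_edges, spatial_edges, rho = 0.95) {
  need <- c("node", "eta_t1", "eta_t2")
  if (!all(need %in% names(nodes))) {
    abort(paste0("`nodes` must have columns ", paste(need, collapse = ", "), "."))
  }
  for (col in c("eta_t1", "eta_t2")) {
    bad <- which(is.na(nodes[[col]]) | nodes[[col]] < 0 | nodes[[col]] > 1)
    if (length(bad) > 0) {
      abort(paste0("`", col, "` outside [0, 1] at nodes: ",
                   paste(head(nodes$node[bad], 20), collapse = ", ")))
    }
  }
  n <- nrow(nodes)
  nodes$status_t1 <- classify_status(nodes$eta_t1, rho)
  nodes$status_t2 <- classify_status(nodes$eta_t2, rho)
  structure(
    list(
      nodes = nodes,
      social_edges = canonical_edges(social_edges, n),
      spatial_edges = canonical_edges(spatial_edges, n),
      n = n, rho = rho
    ),
    class = "two_timepoint_data"
  )
}

#' @export
print.two_timepoint_data <- function(x, ...) {
  cat(sprintf(
    "<two_timepoint_data> %d nodes, %d social / %d spatial edges, vulnerable %.3f -> %.3f\n",
    x$n, nrow(x$social_edges), nrow(x$spatial_edges),
    mean(x$nodes$status_t1 == "vulnerable"), mean(x$nodes$status_t2 == "vulnerable")
  ))
  invisible(x)
}

#' Estimate the social-influence tolerance from two-timepoint data
#'
#' The tolerance is estimated as the average neighbourhood exposure of the
#' communities whose hesitancy increased between the two time points: for
#' each increaser, the exposure (vulnerable fraction of the closed
#' neighbourhood under `exposure = "status"`, mean hesitancy under
#' `"hesitancy"`) over its social contacts, averaged over increasers.
#'
#' Under the influence model every increaser's exposure met the tolerance at
#' the step it fired, and exposures are monotone over a run, so measuring at
#' the later time point (`at = "t2"`, the default) makes the estimate an
#' upper bound on the generating tolerance; `at = "t1"` measures pre-spread
#' exposure instead.
#'
#' @param data A [two_timepoint_data()] object.
#' @param include_self Include the focal node in its own neighbourhood
#'   average, consistent with the influence rule's exposure.
#' @param exposure `"status"` or `"hesitancy"`, matched to the influence
#'   model's exposure definition.
#' @param at Measure contact states at `"t2"` or `"t1"`.
#' @returns The estimated tolerance, or `NA_real_` when no community
#'   increased (or no increaser has contacts).
#' @export
estimate_alpha <- function(data, include_self = TRUE,
                           exposure = c("status", "hesitancy"),
                           at = c("t2", "t1")) {
  exposure <- match.arg(exposure)
  at <- match.arg(at)
  nodes <- data$nodes
  inc <- which(nodes$eta_t2 > nodes$eta_t1)
  if (length(inc) == 0) return(NA_real_)
  eta <- if (at == "t1") nodes$eta_t1 else nodes$eta_t2
  status <- if (at == "t1") nodes$status_t1 else nodes$status_t2
  x <- if (exposure == "status") as.numeric(status == "vulnerable") else eta
  adj <- adjacency_list(data$social_edges, data$n)
  vals <- purrr::map_dbl(inc, function(i) {
    members <- if (include_self) c(i, adj[[i]]) else adj[[i]]
    if (length(members) == 0) return(NA_real_)
    mean(x[members])
  })
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Estimate the social-selection level from trait data
#'
#' Computes `beta = 1 - mu / mu_tilde` on the social edges, with the trait
#' covariance estimated from the sample (see [measure_selection()]).
#'
#' @inheritParams estimate_alpha
#' @param n_perm Permutations for the baseline distance.
#' @param seed Optional integer seed.
#' @param traits Optional character vector naming trait columns.
#' @returns The estimated selection parameter.
#' @export
estimate_beta_empirical <- function(data, n_perm = 100, seed = NULL, traits = NULL) {
  net <- new_landscape_network(data$n, data$social_edges, data$spatial_edges)
  measure_selection(net, data$nodes, n_perm = n_perm, seed = seed, traits = traits)$beta
}

#' Bootstrap an estimator over node-induced subnetworks
#'
#' Each replicate samples `floor(sample_fraction * n)` nodes without
#' replacement, induces the social and spatial subgraphs on them, and re-runs
#' the estimator on the reduced [two_timepoint_data()]. Replicates where the
#' estimator is undefined (`NA`) are dropped and counted.
#'
#' @inheritParams estimate_alpha
#' @param estimator A function `function(data, ...)` returning a single
#'   number, e.g. [estimate_alpha()] or [estimate_beta_empirical()].
#' @param n_boot Number of bootstrap replicates.
#' @param sample_fraction Fraction of nodes kept per replicate.
#' @param seed Optional integer seed.
#' @param ... Passed on to `estimator`.
#' @returns A one-row tibble: `mean`, `ci_lower`, `ci_upper` (2.5% / 97.5%
#'   quantiles), `n_boot`, `n_dropped`.
#' @export
bootstrap_estimate <- function(estimator, data, n_boot = 1000,
                               sample_fraction = 0.7, seed = NULL, ...) {
  stopifnot(n_boot >= 1, sample_fraction > 0, sample_fraction <= 1)
  n_keep <- floor(sample_fraction * data$n)
  vals <- with_seed(seed, {
    purrr::map_dbl(seq_len(n_boot), function(b) {
      keep <- sort(sample.int(data$n, n_keep))
      sub <- induce_subdata(data, keep)
      tryCatch(estimator(sub, ...), error = function(e) NA_real_)
    })
  })
  ok <- vals[!is.na(vals)]
  if (length(ok) == 0) abort("All bootstrap replicates were undefined.")
  tibble(
    mean = mean(ok),
    ci_lower = unname(quantile(ok, 0.025)),
    ci_upper = unname(quantile(ok, 0.975)),
    n_boot = n_boot,
    n_dropped = sum(is.na(vals))
  )
}

induce_subdata <- function(data, keep) {
  relabel <- function(edges) {
    sel <- edges[, 1] %in% keep & edges[, 2] %in% keep
    e <- edges[sel, , drop = FALSE]
    matrix(match(e, keep), ncol = 2)
  }
  nodes <- data$nodes[keep, , drop = FALSE]
  nodes$node <- seq_along(keep)
  two_timepoint_data(nodes, relabel(data$social_edges), relabel(data$spatial_edges),
                     rho = data$rho)
}

#' Forward validation of the influence model on two-timepoint data
#'
#' Seeds the influence process at the first time point's hesitancy on the
#' social edges, runs it to the observed second-timepoint vulnerable
#' fraction, and scores the predicted vulnerability map against the observed
#' one: the F-score for the vulnerable class, and the spatial assortativity
#' of the predicted and observed maps on the spatial edges. The influence
#' update is deterministic, so `reps` matters only insofar as scenario
#' elements (e.g. rerouting) are stochastic; results are averaged.
#'
#' @inheritParams estimate_alpha
#' @param alpha Influence tolerance to simulate with (e.g. an
#'   [estimate_alpha()] value).
#' @param params Optional [influence_params()]; `alpha` and the stop fraction
#'   are overridden by `alpha` and the observed t2 fraction.
#' @param reps Number of forward runs averaged.
#' @param seed Optional integer seed.
#' @returns A one-row tibble: `f_score`, `r_modeled`, `r_observed`,
#'   `vulnerable_fraction_modeled`, `vulnerable_fraction_observed`.
#' @export
validate_forward <- function(data, alpha, params = NULL, reps = 1, seed = NULL) {
  base <- params %||% influence_params(alpha = alpha, rho = data$rho)
  frac_t2 <- mean(data$nodes$status_t2 == "vulnerable")
  frac_t1 <- mean(data$nodes$status_t1 == "vulnerable")
  params <- influence_params(
    alpha = alpha, delta = base$delta, rho = base$rho,
    stop_fraction = frac_t2, max_steps = base$max_steps, exposure = base$exposure
  )
  net <- new_landscape_network(data$n, data$social_edges, data$spatial_edges)
  start <- tibble(
    node = data$nodes$node, eta = data$nodes$eta_t1,
    status = data$nodes$status_t1
  )
  runs <- with_seed(seed, {
    purrr::map(seq_len(reps), function(rep_i) {
      if (frac_t1 >= frac_t2) {
        list(nodes = start)
      } else {
        run_influence(net, start, params)
      }
    })
  })
  fs <- purrr::map_dbl(runs, ~ f_score(.x$nodes$status, data$nodes$status_t2))
  rm_ <- purrr::map_dbl(runs, ~ spatial_assortativity(
    .x$nodes$status, variant = "newman", spatial_edges = data$spatial_edges
  ))
  tibble(
    f_score = mean(fs),
    r_modeled = mean(rm_),
    r_observed = spatial_assortativity(data$nodes$status_t2, variant = "newman",
                                       spatial_edges = data$spatial_edges),
    vulnerable_fraction_modeled = mean(purrr::map_dbl(
      runs, ~ mean(.x$nodes$status == "vulnerable")
    )),
    vulnerable_fraction_observed = frac_t2
  )
}
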