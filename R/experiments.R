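#' Run a scripted simulation experiment
#'
#' Drives the generative models over a parameter grid with replication and
#' returns one tidy row per run. Available experiments:
#'
#' * `"selection_clustering"`: anneal attributes to each `beta_target` on
#'   landscapes of each rewiring `p` (about 25% of communities vulnerable)
#'   and record the spatial clustering of vulnerability.
#' * `"influence_clustering"`: run diffusion from 10% to 25% vulnerable for
#'   each tolerance `alpha` and rewiring `p`, recording final clustering.
#' * `"combined_clustering"`: selection to `beta_target` followed by
#'   diffusion at tolerance `alpha` ([run_combined()]), recording clustering
#'   and the vulnerable-cluster structure.
#' * `"strategy_comparison"`: [evaluate_strategy()] for the three targeting
#'   strategies across `beta_target` levels.
#' * `"reroute_sweep"`: [evaluate_strategy()] for the rerouting strategy
#'   across `omega` (and optionally `alpha`) values.
#' * `"outbreak_size"`: largest vulnerable cluster (maximum outbreak size)
#'   generated by pure selection vs. pure influence at matched vulnerable
#'   fractions.
#'
#' Results are deterministic given `seed`; every row carries the grid cell,
#' the replicate index and its own sub-seed, and the returned table carries a
#' run manifest (`config hash`, seed, package version) as attribute
#' `"manifest"`.
#'
#' @param experiment Experiment name (see Details).
#' @param grid Optional data frame of grid cells overriding the default grid
#'   (columns depend on the experiment, e.g. `p`, `beta_target`, `alpha`,
#'   `omega`, `strategy`).
#' @param n,k Landscape size and even mean degree.
#' @param reps Replicates per grid cell.
#' @param seed Integer master seed.
#' @param rho Herd-immunity threshold.
#' @param r_variant Assortativity variant recorded in the results.
#' @returns A tibble with attributes `"grid_vars"` and `"manifest"`.
#' @examples
#' res <- run_experiment("influence_clustering",
#'   grid = expand.grid(p = c(0, 1), alpha = 0.2),
#'   n = 128, reps = 2, seed = 1
#' )
#' summarize_experiment(res)
#' @export
run_experiment <- function(experiment = c("selection_clustering", "influence_clustering",
                                          "combined_clustering", "strategy_comparison",
                                          "reroute_sweep", "outbreak_size"),
                           grid = NULL, n = 512, k = 6, reps = 50, seed = 1,
                           rho = 0.95, r_variant = "newman") {
  experiment <- tryCatch(match.arg(experiment), error = function(e) {
    abort(paste0(
      "Unknown experiment `", experiment[1], "`. Available: ",
      "selection_clustering, influence_clustering, combined_clustering, ",
      "strategy_comparison, reroute_sweep, outbreak_size"
    ))
  })
  stopifnot(reps >= 1)
  grid <- as_tibble(grid %||% default_grid(experiment))
  grid_vars <- names(grid)
  lambda25 <- calibrate_lambda(0.25, rho)
  lambda10 <- calibrate_lambda(0.10, rho)

  run_cell <- function(cell, rep_i, sub_seed) {
    switch(experiment,
      selection_clustering = with_seed(sub_seed, {
        net <- ws_network(n, k, cell$p)
        nodes <- traits_from_hesitancy(sample_hesitancy(n, lambda25, rho))
        fit <- anneal_to_beta(net, nodes, cell$beta_target)
        tibble(
          r = spatial_assortativity(fit$nodes$status, variant = r_variant,
                                    spatial_edges = net$substrate_edges),
          beta_realised = fit$beta, converged = fit$converged,
          vulnerable_fraction = mean(fit$nodes$status == "vulnerable"),
          max_cluster = max_vulnerable_component(fit$nodes$status, net$substrate_edges)
        )
      }),
      influence_clustering = with_seed(sub_seed, {
        net <- ws_network(n, k, cell$p)
        nodes <- sample_hesitancy(n, lambda10, rho)
        traj <- run_influence(net, nodes, influence_params(alpha = cell$alpha, rho = rho),
                              r_variant = r_variant)
        glance(traj)[c("r", "vulnerable_fraction", "stop_reason", "n_steps",
                       "n_clusters", "max_cluster")]
      }),
      combined_clustering = {
        net <- with_seed(sub_seed, ws_network(n, k, cell$p %||% 0))
        traj <- run_combined(net, cell$beta_target,
                             influence_params(alpha = cell$alpha, rho = rho),
                             seed = sub_seed + 1L, r_variant = r_variant)
        glance(traj)[c("r", "vulnerable_fraction", "stop_reason", "n_steps",
                       "n_clusters", "max_cluster")]
      },
      strategy_comparison = {
        out <- evaluate_strategy(cell$strategy, reps = 1, seed = sub_seed,
                                 n = n, k = k, beta_target = cell$beta_target,
                                 rho = rho, r_variant = r_variant)
        if (nrow(out) == 0) {
          tibble(r_control = NA_real_, r_post = NA_real_,
                 relative_clustering = NA_real_)
        } else {
          out[c("r_control", "r_post", "relative_clustering")]
        }
      },
      reroute_sweep = {
        out <- evaluate_strategy("reroute", reps = 1, seed = sub_seed,
                                 n = n, k = k, alpha = cell$alpha %||% 0.2,
                                 omega = cell$omega, rho = rho, r_variant = r_variant)
        if (nrow(out) == 0) {
          tibble(r_control = NA_real_, r_post = NA_real_,
                 relative_clustering = NA_real_)
        } else {
          out[c("r_control", "r_post", "relative_clustering")]
        }
      },
      outbreak_size = with_seed(sub_seed, {
        net <- ws_network(n, k, cell$p %||% 0)
        if (cell$process == "selection") {
          nodes <- traits_from_hesitancy(sample_hesitancy(n, lambda25, rho))
          fit <- anneal_to_beta(net, nodes, cell$beta_target %||% 0.4)
          status <- fit$nodes$status
        } else {
          nodes <- sample_hesitancy(n, lambda10, rho)
          traj <- run_influence(net, nodes,
                                influence_params(alpha = cell$alpha %||% 0.2, rho = rho))
          status <- traj$nodes$status
        }
        tibble(
          max_cluster = max_vulnerable_component(status, net$substrate_edges),
          vulnerable_fraction = mean(status == "vulnerable")
        )
      })
    )
  }

  cells <- purrr::map(seq_len(nrow(grid)), function(ci) {
    cell <- as.list(grid[ci, , drop = FALSE])
    purrr::map(seq_len(reps), function(rep_i) {
      sub_seed <- (seed * 10000L + ci * 100L + rep_i) %% .Machine$integer.max
      dplyr::bind_cols(
        grid[ci, , drop = FALSE],
        tibble(rep = rep_i, sub_seed = sub_seed),
        run_cell(cell, rep_i, sub_seed)
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "grid_vars") <- grid_vars
  attr(out, "manifest") <- list(
    experiment = experiment,
    config_hash = rlang::hash(list(experiment, grid, n, k, reps, seed, rho, r_variant)),
    seed = seed, n = n, k = k, reps = reps,
    package_version = as.character(utils::packageVersion("vaxscape"))
  )
  out
}

default_grid <- function(experiment) {
  switch(experiment,
    selection_clustering = expand.grid(
      p = c(0, 0.1, 0.5, 1), beta_target = c(0.2, 0.5, 0.8)
    ),
    influence_clustering = expand.grid(
      p = c(0, 0.01, 0.1, 0.5, 1), alpha = c(0.2, 0.4, 0.6)
    ),
    combined_clustering = expand.grid(
      p = 0, beta_target = c(0, 0.4, 0.8), alpha = c(0.2, 0.6)
    ),
    strategy_comparison = expand.grid(
      strategy = c("target_selection", "target_high_hesitancy", "target_random"),
      beta_target = c(0.16, 0.5, 0.8),
      stringsAsFactors = FALSE
    ),
    reroute_sweep = expand.grid(omega = c(0, 0.25, 0.5, 0.75, 1), alpha = 0.2),
    outbreak_size = expand.grid(process = c("selection", "influence"), p = c(0, 0.2),
                                stringsAsFactors = FALSE)
  )
}

#' Summarise an experiment table by grid cell
#'
#' Groups by the experiment's grid variables and reports the mean, Monte
#' Carlo standard error, and replicate counts for every numeric outcome
#' column. Cells with a single kept replicate get an `NA` standard error.
#'
#' @param results A table from [run_experiment()] (or any data frame; grid
#'   variables are then taken from `group_vars`).
#' @param group_vars Optional character vector of grouping columns.
#' @returns A tibble in long format: one row per cell and outcome, with
#'   columns `mean`, `se`, `n_reps`, `n_dropped`.
#' @export
summarize_experiment <- function(results, group_vars = NULL) {
  if (nrow(results) == 0) abort("Empty results table.")
  group_vars <- group_vars %||% attr(results, "grid_vars", exact = TRUE)
  if (is.null(group_vars)) abort("No grouping variables found or supplied.")
  metrics <- setdiff(
    names(results)[vapply(results, is.numeric, logical(1))],
    c(group_vars, "rep", "sub_seed")
  )
  long <- tidyr::pivot_longer(
    results[c(group_vars, metrics)],
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_vars, "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = if (sum(!is.na(.data$value)) > 1) {
        sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
      } else {
        NA_real_
      },
      n_reps = sum(!is.na(.data$value)),
      n_dropped = sum(is.na(.data$value)),
      .groups = "drop"
    )
}
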