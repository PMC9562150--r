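#' Specification of a synthetic county-like fixture
#'
#' Collects every knob of the generative pipeline in one validated object so
#' fixtures are reproducible from their manifest alone. Defaults encode the
#' study conditions: a 512-community landscape (the reduced scale used for
#' simulation suites; 2048 is the full-scale size), mean degree 6, rewiring
#' probability 0.2 (the value inferred for empirical social connectivity),
#' exponential hesitancy calibrated so 10% of communities start vulnerable,
#' two Weibull-shape-2 traits, and diffusion (tolerance `alpha_true` on the
#' status exposure) run until 25% of communities are vulnerable.
#'
#' @param n,k,p_social Landscape size, even mean degree, rewiring probability.
#' @param init_vulnerable_fraction Vulnerable fraction at time 1; fixes
#'   `lambda` via [calibrate_lambda()] unless `lambda` is given.
#' @param lambda Optional explicit exponential rate.
#' @param gammas Trait shapes for [traits_from_hesitancy()].
#' @param beta_target Selection level annealed into the time-1 layout.
#' @param alpha_true Influence tolerance generating the time-2 state.
#' @param delta Hesitancy increment per firing step.
#' @param rho Herd-immunity threshold.
#' @param stop_fraction Vulnerable fraction at which diffusion stops.
#' @param exposure Influence exposure definition (see [influence_params()]).
#' @param seed Integer seed; fixtures are byte-identical given the same spec.
#' @returns A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n = 512, k = 6, p_social = 0.2,
                         init_vulnerable_fraction = 0.10, lambda = NULL,
                         gammas = c(income = 2, household_size = 2),
                         beta_target = 0.4, alpha_true = 0.2, delta = 0.01,
                         rho = 0.95, stop_fraction = 0.25,
                         exposure = "status", seed = 1) {
  lambda <- lambda %||% calibrate_lambda(init_vulnerable_fraction, rho)
  spec <- list(
    n = n, k = k, p_social = p_social,
    init_vulnerable_fraction = init_vulnerable_fraction, lambda = lambda,
    gammas = gammas, beta_target = beta_target, alpha_true = alpha_true,
    delta = delta, rho = rho, stop_fraction = stop_fraction,
    exposure = exposure, seed = seed
  )
  stopifnot(
    n > k, k %% 2 == 0, p_social >= 0, p_social <= 1, lambda > 0,
    all(gammas > 0), beta_target >= 0, beta_target < 1, alpha_true >= 0,
    delta > 0, delta <= 1, rho > 0, rho < 1
  )
  structure(spec, class = "fixture_spec")
}

#' Generate a single-timepoint landscape fixture
#'
#' Builds the full generative state the analysis modules consume: a
#' Watts-Strogatz landscape with its ring substrate, exponential hesitancy
#' (capped at 1), power-transform traits, and an attribute layout annealed to
#' the requested selection level.
#'
#' @param spec A [fixture_spec()].
#' @returns A list with elements `net` (a landscape network), `nodes` (node
#'   tibble with traits), and `anneal` (a one-row annealing summary).
#' @export
make_landscape_fixture <- function(spec) {
  with_seed(spec$seed, {
    net <- ws_network(spec$n, spec$k, spec$p_social)
    nodes <- traits_from_hesitancy(
      sample_hesitancy(spec$n, spec$lambda, spec$rho),
      spec$gammas
    )
    fit <- anneal_to_beta(net, nodes, spec$beta_target)
    list(net = net, nodes = fit$nodes, anneal = glance(fit))
  })
}

#' Generate a two-timepoint fixture by running the influence model
#'
#' Time 1 comes from [make_landscape_fixture()]; time 2 is produced by running
#' the social-influence process with tolerance `alpha_true` until
#' `stop_fraction` of communities are vulnerable. Social edges are the
#' (possibly rewired) interaction network and spatial edges its ring
#' substrate. The generating parameters are attached as the `"truth"`
#' attribute so recovery studies never have to re-derive them.
#'
#' @param spec A [fixture_spec()].
#' @returns A [two_timepoint_data()] object with attribute `"truth"` (the
#'   spec plus the realised annealing summary and stop reason).
#' @export
make_two_timepoint_fixture <- function(spec) {
  fx <- make_landscape_fixture(spec)
  params <- influence_params(
    alpha = spec$alpha_true, delta = spec$delta, rho = spec$rho,
    stop_fraction = spec$stop_fraction, exposure = spec$exposure
  )
  traj <- run_influence(fx$net, fx$nodes, params)
  nodes <- fx$nodes
  nodes_tt <- tibble(
    node = nodes$node, eta_t1 = nodes$eta, eta_t2 = traj$nodes$eta
  )
  for (tr in trait_columns(nodes)) nodes_tt[[tr]] <- nodes[[tr]]
  out <- two_timepoint_data(nodes_tt, fx$net$edges, fx$net$substrate_edges,
                            rho = spec$rho)
  attr(out, "truth") <- c(
    unclass(spec),
    list(anneal = fx$anneal, stop_reason = traj$stop_reason,
         vulnerable_fraction_t2 = mean(out$nodes$status_t2 == "vulnerable"))
  )
  out
}

#' Write a two-timepoint fixture to a run directory
#'
#' Plain-text, full-precision layout: `nodes_t1.csv` and `nodes_t2.csv` (node
#' id, hesitancy, status, one column per trait), `social.edges` and
#' `spatial.edges` (two-column edge lists), and `manifest.json` carrying the
#' generating spec so a fixture is self-describing.
#'
#' @param data A [two_timepoint_data()] object.
#' @param dir Output directory (created if needed).
#' @returns `dir`, invisibly.
#' @export
write_fixture <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data$nodes
  traits <- setdiff(
    names(nodes)[vapply(nodes, is.numeric, logical(1))],
    c("node", "eta_t1", "eta_t2")
  )
  t1 <- tibble(node = nodes$node, eta = nodes$eta_t1, status = nodes$status_t1)
  t2 <- tibble(node = nodes$node, eta = nodes$eta_t2, status = nodes$status_t2)
  for (tr in traits) {
    t1[[tr]] <- nodes[[tr]]
    t2[[tr]] <- nodes[[tr]]
  }
  # doubles are serialised at 17 significant digits so files round-trip
  # bit-exactly
  full_precision <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    })
    df
  }
  readr::write_csv(full_precision(t1), file.path(dir, "nodes_t1.csv"))
  readr::write_csv(full_precision(t2), file.path(dir, "nodes_t2.csv"))
  utils::write.table(data$social_edges, file.path(dir, "social.edges"),
                     row.names = FALSE, col.names = c("a", "b"))
  utils::write.table(data$spatial_edges, file.path(dir, "spatial.edges"),
                     row.names = FALSE, col.names = c("a", "b"))
  truth <- attr(data, "truth", exact = TRUE)
  manifest <- list(n = data$n, rho = data$rho, truth = truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture written by [write_fixture()]
#'
#' Validates the schema (named columns present, hesitancy within `[0, 1]`)
#' and reports offending nodes when it is not.
#'
#' @param dir Fixture directory.
#' @returns A [two_timepoint_data()] object; the manifest is attached as
#'   attribute `"manifest"`.
#' @export
read_fixture <- function(dir) {
  read_nodes <- function(path) {
    # base parser: exact strtod round-trip of the 17-digit serialisation
    df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    need <- c("node", "eta", "status")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0) {
      abort(paste0(basename(path), " is missing columns: ",
                   paste(missing, collapse = ", ")))
    }
    bad <- which(is.na(df$eta) | df$eta < 0 | df$eta > 1)
    if (length(bad) > 0) {
      abort(paste0(basename(path), ": eta outside [0, 1] at nodes ",
                   paste(head(df$node[bad], 20), collapse = ", ")))
    }
    df
  }
  t1 <- read_nodes(file.path(dir, "nodes_t1.csv"))
  t2 <- read_nodes(file.path(dir, "nodes_t2.csv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  traits <- setdiff(
    names(t1)[vapply(t1, is.numeric, logical(1))],
    c("node", "eta")
  )
  nodes <- tibble(node = t1$node, eta_t1 = t1$eta, eta_t2 = t2$eta)
  for (tr in traits) nodes[[tr]] <- t1[[tr]]
  social <- as.matrix(utils::read.table(file.path(dir, "social.edges"), header = TRUE))
  spatial <- as.matrix(utils::read.table(file.path(dir, "spatial.edges"), header = TRUE))
  out <- two_timepoint_data(nodes, social, spatial,
                            rho = manifest$rho %||% 0.95)
  attr(out, "manifest") <- manifest
  out
}
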