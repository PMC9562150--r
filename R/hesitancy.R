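#' Herd-immunity threshold from the basic reproduction number
#'
#' `rho = 1 - 1/R0`, the vaccination coverage above which sustained
#' transmission is not expected. For measles (`R0` around 20) this gives 0.95,
#' the case-study value used throughout the package defaults.
#'
#' @param r0 Basic reproduction number, `> 1`.
#' @returns A probability.
#' @examples
#' herd_immunity_threshold(20)
#' @export
herd_immunity_threshold <- function(r0) {
  if (any(r0 <= 1)) abort("`r0` must exceed 1; no herd-immunity threshold exists otherwise.")
  1 - 1 / r0
}

#' Calibrate the exponential hesitancy rate to a vulnerable fraction
#'
#' Community hesitancy `eta` is modelled as exponential, `P(eta) = lambda *
#' exp(-lambda * eta)`. A community is *vulnerable* when `eta >= 1 - rho`, so
#' the rate solving `P(eta >= 1 - rho) = f` is `lambda = -log(f) / (1 - rho)`.
#' With `rho = 0.95`, a 25% vulnerable fraction (the 2018-like condition) gives
#' `lambda ~ 27.7` and a 10% fraction (the 2015-like initial condition for
#' influence runs) gives `lambda ~ 46.1`.
#'
#' @param target_vulnerable_fraction Desired fraction of vulnerable
#'   communities, strictly between 0 and 1.
#' @param rho Herd-immunity threshold.
#' @returns The exponential rate `lambda`.
#' @export
calibrate_lambda <- function(target_vulnerable_fraction, rho = 0.95) {
  f <- target_vulnerable_fraction
  if (any(f <= 0) || any(f >= 1)) {
    abort("`target_vulnerable_fraction` must lie strictly between 0 and 1.")
  }
  -log(f) / (1 - rho)
}

#' Classify communities as vulnerable or protected
#'
#' @param eta Numeric vector of hesitancy fractions in `[0, 1]`.
#' @param rho Herd-immunity threshold; a community with `eta >= 1 - rho` is
#'   below the required coverage and therefore vulnerable (the boundary case
#'   is vulnerable).
#' @returns Character vector of `"vulnerable"` / `"protected"`.
#' @export
classify_status <- function(eta, rho = 0.95) {
  ifelse(is_vulnerable(eta, rho), "vulnerable", "protected")
}

# boundary-inclusive threshold comparison, robust to floating-point noise in
# 1 - rho (e.g. 1 - 0.95 is slightly above 0.05 in binary)
is_vulnerable <- function(eta, rho) {
  eta >= (1 - rho) - 1e-9
}

#' Sample a community hesitancy state
#'
#' Draws `n` i.i.d. exponential hesitancy fractions (capped at 1; at the
#' calibrated rates the cap has probability below 1e-12) and classifies each
#' node against the herd-immunity threshold.
#'
#' @param n Number of communities.
#' @param lambda Exponential rate, e.g. from [calibrate_lambda()].
#' @param rho Herd-immunity threshold.
#' @param seed Optional integer seed.
#' @returns A tibble with columns `node`, `eta`, `status`.
#' @examples
#' nodes <- sample_hesitancy(100, calibrate_lambda(0.25), seed = 1)
#' mean(nodes$status == "vulnerable")
#' @export
sample_hesitancy <- function(n, lambda, rho = 0.95, seed = NULL) {
  if (lambda <= 0) abort("`lambda` must be positive.")
  eta <- with_seed(seed, pmin(rexp(n, rate = lambda), 1))
  tibble(node = seq_len(n), eta = eta, status = classify_status(eta, rho))
}

#' Derive socio-economic traits from hesitancy
#'
#' Appends one trait column per entry of `gammas`, each a deterministic power
#' transform `X_u = eta^(1/gamma_u)` of the node's hesitancy. When `eta` is
#' exponential with rate `lambda` this makes each trait Weibull distributed
#' with shape `gamma_u` and survival `exp(-lambda * x^gamma_u)`, so traits are
#' monotone proxies of hesitancy (any empirical trait that correlates
#' negatively, such as household income vs. hesitancy in some settings, is
#' assumed to have been sign-flipped upstream). Exact zeros in `eta` are
#' replaced by the smallest positive value present so the transform stays
#' strictly monotone.
#'
#' @param nodes Hesitancy state tibble from [sample_hesitancy()].
#' @param gammas Named (or unnamed) vector of positive Weibull shapes, one per
#'   trait; defaults to two traits of shape 2.
#' @returns `nodes` with one extra numeric column per trait.
#' @export
traits_from_hesitancy <- function(nodes, gammas = c(income = 2, household_size = 2)) {
  if (any(gammas <= 0)) abort("All `gammas` must be positive.")
  nms <- names(gammas) %||% paste0("trait", seq_along(gammas))
  if (is.null(names(gammas))) names(gammas) <- nms
  eta <- nodes$eta
  if (any(eta == 0)) {
    pos <- eta[eta > 0]
    if (length(pos) == 0) abort("All hesitancy values are zero; traits undefined.")
    eta[eta == 0] <- min(pos)
  }
  for (u in seq_along(gammas)) {
    nodes[[names(gammas)[u]]] <- eta^(1 / gammas[u])
  }
  attr(nodes, "trait_names") <- names(gammas)
  nodes
}

# Columns of `nodes` holding trait values. Uses the trait_names attribute when
# present, otherwise every numeric column other than the bookkeeping ones.
trait_columns <- function(nodes, traits = NULL) {
  traits <- traits %||% attr(nodes, "trait_names", exact = TRUE)
  if (is.null(traits)) {
    reserved <- c("node", "eta", "eta_t1", "eta_t2", "status", "status_t1", "status_t2")
    traits <- setdiff(names(nodes)[vapply(nodes, is.numeric, logical(1))], reserved)
  }
  if (length(traits) == 0) abort("No trait columns found.")
  traits
}

trait_matrix <- function(nodes, traits = NULL) {
  as.matrix(nodes[trait_columns(nodes, traits)])
}
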