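---
title: "Generative models of spatial clustering in vaccine hesitancy"
author: "vaxscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative models of spatial clustering in vaccine hesitancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxscape)
```

## The problem

Vaccine hesitancy does not spread itself evenly over a country: communities
that fall below the herd-immunity vaccination threshold tend to sit next to
each other, and those contiguous pockets — not the national average — are
what drives outbreak risk for highly transmissible pathogens such as measles.
`vaxscape` implements two generative mechanisms that can each produce such
spatial clustering at the landscape (county) scale, tools to measure the
clustering, estimators that recover each mechanism's parameter from
two-timepoint community data, and two intervention strategies that try to
break the clusters up.

The two mechanisms are:

* **Social selection.** Communities with similar hesitancy-linked
  socio-economic traits occupy adjacent network positions. Hesitancy is never
  transmitted; clustering in behaviour simply mirrors clustering in traits.
* **Social influence.** Hesitancy is contagious between socially connected
  communities: a community surrounded by hesitant neighbours becomes more
  hesitant itself, in the manner of bootstrap percolation.

Both run on the same scaffold, a Watts-Strogatz small-world landscape.

## The landscape

`ws_network(n, k, p)` builds a ring lattice of `n` communities, each tied to
its `k` nearest neighbours, and rewires the far endpoint of each lattice edge
with probability `p` (classic single-endpoint rewiring, rejecting self-loops
and duplicates, so the edge count `n k / 2` is conserved exactly). The
unrewired ring is kept as the **spatial substrate**: it stands in for
geographic adjacency, and *every* spatial-clustering quantity in the package
is computed on it, never on the rewired interaction edges. That separation is
what lets clustering fall as `p` grows — the social process operates on
increasingly aspatial ties while the yardstick stays geographic.

Defaults across the simulation suites are `n = 512`, `k = 6`. The 512 is a
deliberate reduced scale chosen so that full multi-seed sweeps stay cheap;
`n = 2048` reproduces full-scale landscapes and `n = 2496` with `k = 6`
matches the size and mean degree of a thresholded empirical
social-connectivity network. For empirical edge lists,
`threshold_weighted_edges()` keeps ties with weight strictly above a cutoff
and discards the weights afterwards.

`infer_rewiring_p()` projects a network known only through two summary
metrics — average local clustering coefficient $c$ and mean shortest path
$\ell$ — onto the Watts-Strogatz family by scanning a grid of `p` and
minimising $((c - c^\*)/c^\*)^2 + ((\ell - \ell^\*)/\ell^\*)^2$ over
ensemble means. Two caveats are documented rather than hidden. First, a
degree-homogeneous ring family cannot reach path lengths as short as
hub-rich empirical networks: at `n = 2496`, `k = 6` the ensemble mean
$\ell$ never drops below about 4.8, so a target such as $\ell^\* = 3.8$ is
unreachable and the function warns while returning the best-effort
minimiser. Second, the minimiser then reflects a compromise: for targets
$(0.29, 3.8)$ the clustering target alone points at `p` slightly above 0.2,
while the unreachable path-length term drags the optimum one grid step
higher, to 0.25 on a 0.05-spaced grid. The full scan is attached to the
result so users can see the trade-off.

`small_worldness()` uses a same-`n`, same-edge-count uniform random graph
null (`n_random = 20` by default). At six edges per node the clustering of
such sparse random graphs is an inherently noisy quantity, so values should
be read on a log scale: small-world inputs score in the tens to hundreds,
random inputs near 1 within a factor of about two.

## Hesitancy, vulnerability, traits

Community hesitancy $\eta \in [0,1]$ is exponential,
$P(\eta) = \lambda e^{-\lambda \eta}$, capped at 1 (cap probability below
$10^{-12}$ at the calibrated rates; capping was chosen over resampling for
simplicity). A community is **vulnerable** when $\eta \ge 1 - \rho$, where
$\rho = 1 - 1/R_0$ is the herd-immunity threshold; the measles case study
($R_0 \approx 20$, $\rho = 0.95$) is the package default, making the
vulnerability cutoff $\eta \ge 0.05$. The boundary case is vulnerable, and
the comparison carries a $10^{-9}$ guard so that increments landing exactly
on the threshold in floating point classify correctly.

`calibrate_lambda(f, rho)` inverts the tail: $\lambda = -\log f/(1-\rho)$.
Two calibrations recur: $f = 0.25$ ($\lambda \approx 27.7$) for
selection-style scenarios where a quarter of communities are vulnerable, and
$f = 0.10$ ($\lambda \approx 46.1$) for the initial state of influence runs,
which then grow to 25%.

Traits are deterministic power transforms $X_u = \eta^{1/\gamma_u}$, making
each trait Weibull with shape $\gamma_u$ and scale $\lambda^{-1/\gamma_u}$.
The shapes are genuinely free parameters with no canonical empirical
value, and the default is two traits of shape 2, named after the two
empirical traits usually invoked (income, household size), with the
convention that any negatively-correlated empirical trait is sign-flipped
upstream so larger transformed values always mean more hesitancy-prone. No
independent noise is added on top of the transform; with equal shapes the
default traits are therefore perfectly collinear, which the Mahalanobis
machinery below tolerates by ridge regularisation
($10^{-8}\,\mathrm{tr}(S)/d$ on the diagonal) when the trait covariance is
singular.

## Social selection

Homophily is measured through the mean edge-wise Mahalanobis quadratic form

$$\mu = \frac{1}{|E|}\sum_{(i,j)\in E} (X_i - X_j)^\top S^{-1} (X_i - X_j),$$

with $S$ the sample covariance over all nodes. The per-edge term enters
as the quadratic form itself, without a square root (a `root = TRUE`
option gives the conventional rooted distance). Against a
random-placement baseline $\tilde\mu$ (mean of $\mu$ over 100 uniformly
random row permutations), the selection level is
$\beta = 1 - \mu/\tilde\mu$: zero for random placement, positive for
homophily, at most 1.

A target level $\beta^\*$ is installed by annealing: propose exchanging the
full (traits, $\eta$, status) tuples of two uniformly chosen nodes, keep the
swap only if it moves $\beta$ strictly closer to $\beta^\*$, stop at
$|\beta-\beta^\*| \le \mathrm{tol}$ (default 0.01). "Keep only if it
improves" cannot terminate *at* a target, so the rule is stated as
strictly-closer with a tolerance — the one generalisation needed to make the
procedure well-posed. Swaps permute rows, so the hesitancy multiset, the
vulnerable count, and the sample covariance are conserved exactly; the
covariance is computed once up front. The inner loop is compiled (Rcpp) with
incremental edge updates, which keeps 50-seed sweeps over five `beta_target`
levels interactive.

## Social influence

At each synchronous step every community evaluates its **exposure** against
a tolerance $\alpha$; those at or above it raise their hesitancy by
$\delta = 0.01$ (capped at 1), statuses are re-derived, and a protected node
crossing $1-\rho$ becomes vulnerable and never reverts. Runs stop at the
first step where at least `stop_fraction` (default 25%) of communities are
vulnerable — overshoot by the final synchronous wave is allowed and
reported — at a fixed point, or at `max_steps`. Synchronous updating was
chosen because the update rule is stated per-node without an ordering;
asynchronous sweeps would make results depend on node order.

The exposure definition deserves its own section because it is the one
place where this package had to make a substantive modelling call.

### Which average does the tolerance act on?

The influence rule is usually written as "the average hesitancy of the node
and its neighbours exceeds $\alpha$", with societies characterised as
*affectable* ($\alpha = 0.2$) or *determined* ($\alpha = 0.6$). Those two
statements cannot both be taken literally under the exponential hesitancy
calibration. With $\lambda \approx 46$ the mean community hesitancy is
$1/\lambda \approx 0.022$ and the largest value among even 2048 draws is
about 0.16, so the mean of any 7-member closed neighbourhood is bounded far
below 0.2: the literal rule never fires at either tolerance and the process
is frozen at its initial state (we verified this directly; the probability
that any neighbourhood average reaches 0.2 is of order $10^{-20}$ per
node).

What does behave exactly as described is the **vulnerable-status fraction**
of the closed neighbourhood: a consensus-style exposure in the spirit of
bootstrap percolation, on the same $[0,1]$ scale as the quoted tolerances.
With `exposure = "status"` (the default), runs initialised at 10% vulnerable
reach 25% in a handful of steps at $\alpha = 0.2$, final spatial clustering
declines smoothly as the landscape is rewired from ring to random, and a
tolerance-recovery estimator lands in the right range. The literal
hesitancy-mean rule remains available as `exposure = "hesitancy"` and is the
right choice when tolerances are expressed on the hesitancy scale itself
(meaningful values are then roughly 0.02-0.06 under the default
calibration); the package's worked arithmetic examples use it.

One structural consequence is worth stating plainly, because it is a
finding, not a bug. On a degree-6 landscape a node just outside a vulnerable
cluster sees at most 3 vulnerable members among its 7-member closed
neighbourhood — an exposure of $3/7 \approx 0.43$. A determined society
($\alpha = 0.6$) therefore cannot push a cluster boundary outward under any
bounded neighbourhood-averaging rule: its dynamics freeze near the initial
vulnerable fraction, with only fully surrounded enclaves at risk. In our
combined-model runs at high selection ($\beta^\* = 0.8$, ring substrate, 50
seeds) the affectable society grows and merges the annealed blocks (ending
near 26% vulnerable in about 10 clusters with maximum size ~32) while the
determined society keeps its initial ~12 smaller blocks at 10% vulnerable.
A narrative in which determined societies consolidate hesitancy into few
large clusters *while still reaching the same prevalence* is not realisable
on these landscapes; we report what the model actually does.

### Rerouting interventions

`run_influence_with_rerouting()` adds the edge-level intervention: when a
node flips to vulnerable, each of its edges to still-protected neighbours
is, independently with probability $\omega$, disconnected from it and
reattached to a uniformly random protected node (vulnerable-protected
becomes protected-protected), immediately after the synchronous step in
which the flip occurred. Edge count is conserved; if no valid protected
target exists (avoiding self-loops and duplicates) the edge stays and the
failure is counted on the returned network.

## Measuring clustering

Spatial clustering of the vulnerable/protected partition is a categorical
assortativity over substrate edges, from the edge-type fractions
$VV$, $PP$, $VP$. Two variants are exposed because conventions differ in
how mixed edges enter the class marginals:

* `as_printed`: marginals $(VV+VP)$ and $(PP+VP)$. Mixed edges count fully
  towards both classes, so the marginals can sum above 1 and the coefficient
  is unbounded below (at $VV=PP=VP=1/3$ it equals $-2$). Provided for
  fidelity, and the default of `spatial_assortativity()`.
* `newman`: standard edge-end accounting, marginals $(VV+VP/2)$ and
  $(PP+VP/2)$; bounded in $[-1,1]$ and null-centred at 0. All trajectory
  records, experiment tables and intervention outcomes use this variant,
  because means and trends of an unbounded statistic are not interpretable.

Both variants equal 1 under perfect segregation and are invariant to
swapping the two labels; single-class partitions return `NA` (undefined)
rather than a number. `cluster_size_distribution()` and
`max_vulnerable_component()` give the vulnerable-cluster structure on the
substrate — the latter is the *maximum outbreak size*, the largest pool of
contiguous under-vaccinated communities.

## Estimation from two-timepoint data

`two_timepoint_data()` bundles per-node hesitancy at two times, traits,
social edges and spatial edges. The selection level is estimated exactly as
defined ($\hat\beta = 1 - \mu/\tilde\mu$ on the social edges). The
influence tolerance is estimated as the mean neighbourhood exposure of the
communities whose hesitancy increased between the time points, with the
exposure definition matched to the model's. Exposures are measured at the
later time point by default: statuses only ever accumulate, so each
increaser's final exposure dominates its exposure at the step it first
fired, making $\hat\alpha$ an upper bound on the generating tolerance — the
property the recovery tests assert. Measuring at the earlier time point
(`at = "t1"`) is available but is *not* a bound: communities recruited late
in a cascade had low initial exposure.

`bootstrap_estimate()` quantifies uncertainty by node subsampling without
replacement (default 70% of nodes, 1000 replicates), inducing the social
and spatial subgraphs on each subsample. With-replacement node resampling
was rejected because duplicated nodes have no graph meaning. Replicates
where an estimator is undefined (e.g. no increasers survive the subsample)
are dropped and counted. `validate_forward()` seeds the influence model at
the first time point and runs to the observed second-timepoint vulnerable
fraction, scoring the predicted map by the F-score of the vulnerable class
and by the spatial assortativity of predicted vs. observed maps; the update
being deterministic, replicate averaging matters only when stochastic
elements (rerouting) are in play.

## Interventions

`zeta_index()` ranks communities by
$\zeta_i = \exp\left(\sum_u z(X_{ui})\right) \times
\left(\varepsilon + \frac{1}{k_i}\sum_{j \in N(i)} \mu_{ij}\right)^{-1}$ —
elevated hesitancy-linked traits times neighbourhood conformity — computed
on the interaction network. The $\varepsilon = 10^{-9}$ guard handles
identical neighbours; isolated nodes are excluded from rankings.
`select_targets()` implements the three budgeted rules (top-$\zeta$,
top-$\eta$ as the best-case comparator needing full hesitancy data, and
uniform random as the worst case), with deterministic id-ordered
tie-breaking, and `apply_protection()` flips targeted vulnerable communities
to protected, resampling their hesitancy from the population law truncated
below the vulnerability threshold — so the protected stratum keeps its
distributional shape rather than being set to an arbitrary constant.

`evaluate_strategy()` wraps the whole loop against a no-action control and
reports `r_post / r_control` per replicate (the difference is also emitted,
since a ratio and a difference can order strategies differently when
control clustering is small); control-degenerate replicates are dropped and
counted. Targeting evaluations run on `p = 0.2` landscapes — the rewiring
level matched to empirical connectivity — with 25% vulnerable and a 10%
budget; rerouting evaluations pair runs with and without rerouting from
identical initial states.

## What the synthetic generator does and does not emulate

`fixture_spec()` / `make_two_timepoint_fixture()` produce county-like data
with the statistical structure the analyses assume: exponential hesitancy,
traits deterministically tied to hesitancy by power transforms, mixed
spatial/aspatial connectivity from one Watts-Strogatz draw, time-2 states
generated by the influence model itself, and a manifest carrying all ground
truth. Passing recovery tests on these fixtures demonstrates internal
consistency of the estimators — that the pipeline inverts its own generative
model — not that real counties obey it. Real data differ in known ways:
degree heterogeneity (hubs shorten paths far below the ring family's
minimum), traits that are noisy, partially observed and not monotone
transforms of hesitancy, hesitancy measured with error from exemption
records, and spatial adjacency that is planar rather than a ring. Fixture
files are plain text, serialised at 17 significant digits so write/read
round-trips are bit-exact.

## Numerical and design choices, in one place

* Node ids are `1..n`; all file formats carry explicit ids.
* Boundary rule: $\eta \ge 1-\rho$ is vulnerable, with a $10^{-9}$
  floating-point guard.
* Ridge $10^{-8}\,\mathrm{tr}(S)/d$ for singular trait covariances.
* Annealing acceptance is strictly-closer-to-target; tolerance 0.01;
  proposal budget 200,000; non-convergence is flagged, not thrown.
* Influence updates are synchronous; already-vulnerable nodes keep
  incrementing while their neighbourhood permits; $\eta$ capped at 1;
  capped nodes no longer count as firing (so saturation is a fixed point).
* Rerouting happens immediately after the step that caused the flip, and
  failures (no valid protected target) leave the edge in place.
* Stop conditions report first crossing; simultaneous crossers overshoot.
* Budgeted target counts are `round(n * budget)` with id-ordered
  tie-breaking.
* Experiment sub-seeds are derived deterministically from (master seed,
  grid cell, replicate), so tables are exactly reproducible.
* Simulation suites run at `n = 512` with 50 seeds per condition, and
  recovery studies at `n = 256` with 20 fixtures per condition — scales at
  which every trend reported here is stable yet a full run of the test
  suite stays in the minutes range.

## Known limitations

* The determined-society regime is structurally frozen on sparse
  landscapes (see above); conclusions about high-tolerance societies from
  this model family are conclusions about near-frozen dynamics.
* Traits are constant in time and perfectly informative about hesitancy by
  construction; the selection estimator's clean recovery depends on that.
* The model is growth-only: hesitancy never declines and vulnerable
  communities never recover, so it describes the build-up phase, not
  equilibrium or decline.
* No disease transmission is simulated; "maximum outbreak size" is a
  network quantity (largest vulnerable component), a proxy for outbreak
  reach, not an epidemic simulation.
* The small-worldness coefficient depends on the choice of null ensemble
  and its size; values from different null conventions are not comparable.
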