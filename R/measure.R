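#' Empirical (finitely supported) probability measures
#'
#' A finite list of atoms with positive weights summing to one, the carrier
#' for all distributional diagnostics.
#'
#' @param points numeric n x 3 matrix of atom locations (or a 3-vector).
#' @param weights optional positive weights; equal weights when missing.
#'   Normalized to sum to 1.
#' @return An object of class `empirical_measure` with fields `points` and
#'   `weights`.
#' @export
empirical_measure <- function(points, weights = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L, all(is.finite(points)))
  if (is.null(weights)) weights <- rep(1, nrow(points))
  stopifnot(length(weights) == nrow(points), all(is.finite(weights)),
            all(weights > 0))
  structure(list(points = unname(points), weights = weights / sum(weights)),
            class = "empirical_measure")
}

#' @export
print.empirical_measure <- function(x, ...) {
  cat(sprintf("Empirical measure: %d atoms in R^3\n", nrow(x$points)))
  invisible(x)
}

#' Markov (transfer) operator on test functions
#'
#' Evaluates `(Tf)(x) = p0(x) f(S0(x)) + p1(x) f(S1(x))`: the expected value
#' of `f` one step ahead, starting from `x`.  `T` is linear in `f`,
#' preserves constants and positivity, and applied to an indicator yields the
#' one-step transition probability.
#'
#' @param ppair a [probability_pair()].
#' @param maps an [ifs_maps()] object.
#' @param f bounded test function of a 3-vector.
#' @param x evaluation point (3-vector).
#' @return Scalar.
#' @export
markov_T <- function(ppair, maps, f, x) {
  stopifnot(inherits(ppair, "probability_pair"), is.function(f))
  .check_state(x)
  p0 <- ppair$p0(x)
  p0 * f(apply_map(maps, 0, x)) + (1 - p0) * f(apply_map(maps, 1, x))
}

#' Push-forward of a measure by one process step
#'
#' The dual operator on measures: each atom `(x, w)` splits into
#' `(S0(x), w p0(x))` and `(S1(x), w p1(x))`.  Atoms with weight below
#' `prune_threshold` (relative to total mass) are dropped and the result is
#' renormalized; with `prune_threshold = 0` the push-forward is exact and
#' satisfies the duality `int f d(F nu) = int (T f) d nu`.
#'
#' @inheritParams markov_T
#' @param nu an [empirical_measure()].
#' @param prune_threshold relative weight below which atoms are dropped.
#' @return An [empirical_measure()].
#' @export
pushforward_measure <- function(ppair, maps, nu, prune_threshold = 1e-12) {
  stopifnot(inherits(nu, "empirical_measure"))
  p0 <- apply(nu$points, 1, ppair$p0)
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 > 1))
    stop("probability rule returned a value outside [0, 1]", call. = FALSE)
  pts <- rbind(apply_map(maps, 0, nu$points), apply_map(maps, 1, nu$points))
  w <- c(nu$weights * p0, nu$weights * (1 - p0))
  keep <- w > prune_threshold
  if (!any(keep)) stop("all atoms pruned; lower prune_threshold",
                       call. = FALSE)
  empirical_measure(pts[keep, , drop = FALSE], w[keep])
}

#' Integrate a test function against an empirical measure
#'
#' @param nu an [empirical_measure()].
#' @param f function of a 3-vector.
#' @return Scalar `sum_k w_k f(x_k)`.
#' @export
integrate_measure <- function(nu, f) {
  stopifnot(inherits(nu, "empirical_measure"), is.function(f))
  sum(nu$weights * apply(nu$points, 1, f))
}

#' Estimate the invariant measure from a long simulated orbit
#'
#' Runs a simulator, discards a burn-in prefix and returns the equal-weight
#' empirical measure of the remaining states.  When the switching
#' probabilities are bounded away from 0 and 1 the process converges in
#' distribution to its unique invariant measure, so long-orbit empirical
#' measures from different starts or seeds agree up to Monte-Carlo error.
#'
#' @param simulator either an `ifs_trajectory`, a point matrix, or a function
#'   `function(n_steps, seed)` returning one of those.
#' @param n_steps orbit length requested from a function simulator.
#' @param burn_in number of initial states to discard.
#' @param seed optional integer seed passed to a function simulator.
#' @return An [empirical_measure()].
#' @export
estimate_invariant_measure <- function(simulator, n_steps = NULL,
                                       burn_in = 0, seed = NULL) {
  obj <- if (is.function(simulator)) simulator(n_steps, seed) else simulator
  pts <- if (inherits(obj, "ifs_trajectory"))
    as.matrix(obj[, c("xi1", "xi2", "xi3")])
  else as.matrix(obj)
  stopifnot(ncol(pts) == 3L)
  if (burn_in >= nrow(pts))
    stop("burn_in leaves no states", call. = FALSE)
  if (burn_in > 0) pts <- pts[-seq_len(burn_in), , drop = FALSE]
  empirical_measure(pts)
}

#' Energy distance between empirical measures
#'
#' The (squared) energy distance
#' `2 E|X - Y| - E|X - X'| - E|Y - Y'|`
#' between two weighted samples, which metrizes convergence in distribution
#' on bounded sets.  It is nonnegative, symmetric, and zero iff the measures
#' coincide; for two point masses at `x` and `y` it equals `2 |x - y|`.
#'
#' @param mu,nu [empirical_measure()] objects.
#' @return Nonnegative scalar.
#' @export
energy_distance <- function(mu, nu) {
  stopifnot(inherits(mu, "empirical_measure"),
            inherits(nu, "empirical_measure"))
  2 * cpp_energy_cross(mu$points, mu$weights, nu$points, nu$weights) -
    cpp_energy_cross(mu$points, mu$weights, mu$points, mu$weights) -
    cpp_energy_cross(nu$points, nu$weights, nu$points, nu$weights)
}

#' Per-step distance from a trajectory to a reference set
#'
#' For each state of a (reduced-coordinate) trajectory, the Euclidean
#' distance to the nearest point of a reference cloud sampling the invariant
#' set `K`.  Trajectories attracted to `K` show this sequence decaying to the
#' cloud resolution and staying there.
#'
#' @param traj an `ifs_trajectory` or an n x 3 matrix of states.
#' @param k_cloud a nonempty [point_cloud()] sampling the reference set.
#' @return Numeric vector of nearest-neighbour distances, one per state.
#' @export
distance_to_attractor <- function(traj, k_cloud) {
  pts <- if (inherits(traj, "ifs_trajectory"))
    as.matrix(traj[, c("xi1", "xi2", "xi3")])
  else as.matrix(traj)
  ref <- .cloud_matrix(k_cloud)
  if (nrow(ref) == 0L) stop("reference cloud is empty", call. = FALSE)
  as.numeric(cpp_nn_dist(pts, ref))
}
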