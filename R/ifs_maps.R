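#' The pair of affine contraction maps in reduced coordinates
#'
#' In reduced (starred) coordinates one time step with gene state `i` is the
#' affine map
#' \deqn{S_i(x) = \big(a x_1 + u_1 i,\; b x_2 + u_2 i,\; c x_3 + u_3 i\big),}
#' with translation
#' `u = (1/((a-c)(a-b)), 1/((b-a)(b-c)), 1/((c-a)(c-b)))`.  Both maps are
#' contractions with constant `max(a, b, c) < 1`; `S0` fixes the origin and
#' `S1` fixes the vector `v = u / (1 - (a, b, c))` (see [v_vector()]).
#'
#' @param reduced a [reduced_params()] object (or a [kinetic_params()] object,
#'   which is reduced first).
#' @return An object of class `ifs_maps` with fields `reduced` and `u`.
#' @examples
#' m <- ifs_maps(reduced_params(1/2, 3/4, 2/3))
#' apply_map(m, 1, c(0, 0, 0))  # the translation u = c(24, 48, -72)
#' @export
ifs_maps <- function(reduced) {
  reduced <- .as_reduced(reduced)
  a <- reduced$a; b <- reduced$b; c <- reduced$c
  u <- c(1 / ((a - c) * (a - b)),
         1 / ((b - a) * (b - c)),
         1 / ((c - a) * (c - b)))
  structure(list(reduced = reduced, u = u), class = "ifs_maps")
}

#' @export
print.ifs_maps <- function(x, ...) {
  r <- x$reduced
  cat(sprintf("IFS maps S0, S1 on R^3: factors (%g, %g, %g), ", r$a, r$b, r$c))
  cat(sprintf("contraction constant %g\n", contraction_constant(r)))
  cat(sprintf("  S1 translation u = (%g, %g, %g)\n", x$u[1], x$u[2], x$u[3]))
  invisible(x)
}

#' Apply one of the two maps
#'
#' @param maps an [ifs_maps()] object.
#' @param i map index / gene state, 0 or 1.
#' @param x numeric 3-vector or n x 3 matrix of reduced-coordinate points.
#' @return Same shape as `x`: the image under `S_i`.
#' @export
apply_map <- function(maps, i, x) {
  stopifnot(inherits(maps, "ifs_maps"))
  .check_gene(i)
  r <- maps$reduced
  fac <- c(r$a, r$b, r$c)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    sweep(x, 2, fac, `*`) +
      matrix(maps$u * i, nrow(x), 3, byrow = TRUE)
  } else {
    .check_state(x)
    fac * x + maps$u * i
  }
}

#' Contraction constant of the map pair
#'
#' Both maps contract Euclidean distances by at least `max(a, b, c) < 1`.
#'
#' @param reduced a [reduced_params()] (or [kinetic_params()]) object.
#' @return Scalar in (0, 1).
#' @export
contraction_constant <- function(reduced) {
  r <- .as_reduced(reduced)
  max(r$a, r$b, r$c)
}

#' Point clouds
#'
#' A light container for finite weighted point sets in R^3 (attractor
#' samples, empirical supports).  Weights, when present, are normalized to
#' sum to 1.
#'
#' @param points numeric n x 3 matrix (or 3-vector for a single point).
#' @param weights optional nonnegative weights, recycled/normalized.
#' @return An object of class `point_cloud`: a matrix with columns
#'   `x`, `y`, `z` and an optional `weights` attribute.
#' @export
point_cloud <- function(points, weights = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  colnames(points) <- c("x", "y", "z")
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(points), all(weights >= 0),
              sum(weights) > 0)
    attr(points, "weights") <- weights / sum(weights)
  }
  class(points) <- c("point_cloud", class(points))
  points
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points in R^3%s\n", nrow(x),
              if (is.null(attr(x, "weights"))) "" else " (weighted)"))
  invisible(x)
}

.cloud_matrix <- function(cloud) {
  stopifnot(is.matrix(cloud), ncol(cloud) == 3L)
  m <- unclass(cloud)
  attr(m, "weights") <- NULL
  m
}

#' Hutchinson set iteration
#'
#' Iterates the set operator `S(A) = S0(A) U S1(A)` starting from a seed
#' cloud.  The iterates converge to the unique compact invariant set `K` of
#' the pair in the Hausdorff metric, geometrically with ratio at most
#' `max(a, b, c)`.  To keep the doubling point count bounded, after each
#' iteration points are deduplicated on a uniform grid of side
#' `dedup_resolution`.
#'
#' @param maps an [ifs_maps()] object.
#' @param seed_cloud a [point_cloud()] (reduced coordinates).
#' @param n_iter number of iterations (>= 0).
#' @param dedup_resolution grid side for merging nearby points; `0` disables
#'   deduplication.
#' @param max_points error out if an iterate would exceed this many points
#'   after deduplication.
#' @return A [point_cloud()] with the points of the n-th iterate.
#' @export
hutchinson_iterate <- function(maps, seed_cloud, n_iter,
                               dedup_resolution = 1e-4,
                               max_points = 2e6) {
  stopifnot(inherits(maps, "ifs_maps"), n_iter >= 0)
  pts <- .cloud_matrix(seed_cloud)
  if (n_iter == 0) return(point_cloud(pts))
  for (k in seq_len(n_iter)) {
    pts <- rbind(apply_map(maps, 0, pts), apply_map(maps, 1, pts))
    if (dedup_resolution > 0) {
      key <- paste(round(pts[, 1] / dedup_resolution),
                   round(pts[, 2] / dedup_resolution),
                   round(pts[, 3] / dedup_resolution))
      pts <- pts[!duplicated(key), , drop = FALSE]
    }
    if (nrow(pts) > max_points)
      stop("hutchinson_iterate: point budget exceeded (", nrow(pts), " > ",
           max_points, " points); increase dedup_resolution", call. = FALSE)
  }
  point_cloud(pts)
}

#' Chaos-game sampling of the attractor
#'
#' Runs the random orbit `x_{n+1} = S_{j_n}(x_n)` where the map index `j_n`
#' is drawn with place-dependent probabilities `p0(x_n)`, `p1(x_n)` evaluated
#' at the *current* point, and returns the orbit after discarding a burn-in
#' prefix.  With constant probabilities 1/2 this is the classical chaos game;
#' the orbit accumulates on the invariant set of the map pair.
#'
#' @param maps an [ifs_maps()] object.
#' @param ppair a [probability_pair()]; defaults to constant 1/2.
#' @param n_points number of points to return (post burn-in).
#' @param burn_in points to discard at the start.
#' @param x0 starting point (reduced coordinates).
#' @param seed optional integer seed for reproducibility.
#' @param choices optional integer vector in {0,1} of forced map choices of
#'   length `burn_in + n_points`, overriding the random draws (used for
#'   coupling experiments).
#' @return A [point_cloud()] of `n_points` orbit points, with the drawn map
#'   indices in attribute `choices`.
#' @export
chaos_game <- function(maps, ppair = probability_pair(constant_prob(0.5)),
                       n_points, burn_in = 1000, x0 = c(0, 0, 0),
                       seed = NULL, choices = NULL) {
  stopifnot(inherits(maps, "ifs_maps"), n_points >= 0, burn_in >= 0)
  .check_state(x0)
  if (!is.null(seed)) set.seed(seed)
  total <- burn_in + n_points
  if (n_points == 0)
    return(point_cloud(matrix(numeric(0), 0, 3,
                              dimnames = list(NULL, c("x", "y", "z")))))
  if (!is.null(choices)) {
    stopifnot(length(choices) == total, all(choices %in% c(0, 1)))
  }
  r <- maps$reduced
  fac <- c(r$a, r$b, r$c)
  u <- maps$u
  p0 <- ppair$p0
  us <- if (is.null(choices)) stats::runif(total) else NULL
  out <- matrix(NA_real_, n_points, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  kept_choice <- integer(n_points)
  x <- x0
  for (n in seq_len(total)) {
    if (is.null(choices)) {
      p <- p0(x)
      if (!is.finite(p) || p < 0 || p > 1)
        stop("probability rule returned a value outside [0, 1]",
             call. = FALSE)
      j <- if (us[n] < p) 0L else 1L
    } else j <- choices[n]
    x <- fac * x + u * j
    if (n > burn_in) {
      out[n - burn_in, ] <- x
      kept_choice[n - burn_in] <- j
    }
  }
  cl <- point_cloud(out)
  attr(cl, "choices") <- kept_choice
  cl
}

#' Hausdorff distance between two point clouds
#'
#' The maximum over both clouds of the distance to the nearest point of the
#' other cloud; zero iff the clouds coincide as sets.
#'
#' @param cloud_a,cloud_b [point_cloud()] objects (nonempty).
#' @return Nonnegative scalar.
#' @export
hausdorff_distance <- function(cloud_a, cloud_b) {
  A <- .cloud_matrix(cloud_a); B <- .cloud_matrix(cloud_b)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("hausdorff_distance: clouds must be nonempty", call. = FALSE)
  max(max(cpp_nn_dist(A, B)), max(cpp_nn_dist(B, A)))
}
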