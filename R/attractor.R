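#' Closed-form geometry of the invariant set
#'
#' `attractor_spec()` collects the quantities that parametrize the invariant
#' set `A` of the reduced dynamics: the `S1` fixed point
#' \deqn{v = \Big(\frac{1}{(a-c)(a-b)(1-a)},\;
#'               \frac{1}{(b-a)(b-c)(1-b)},\;
#'               \frac{1}{(c-a)(c-b)(1-c)}\Big),}
#' the exponents `e_b = log_a b`, `e_c = log_a c` (both positive for
#' `a, b, c` in (0,1)), and the symmetry center `v/2`: the set `A` satisfies
#' `v - A = A`.
#'
#' @param reduced a [reduced_params()] (or [kinetic_params()]) object.
#' @return An object of class `attractor_spec` with fields `reduced`, `v`,
#'   `e_b`, `e_c`, `center`.
#' @examples
#' sp <- attractor_spec(reduced_params(1/2, 3/4, 2/3))
#' sp$v   # c(48, 192, -216)
#' @export
attractor_spec <- function(reduced) {
  reduced <- .as_reduced(reduced)
  v <- v_vector(reduced)
  a <- reduced$a
  structure(list(reduced = reduced, v = v,
                 e_b = log(reduced$b) / log(a),
                 e_c = log(reduced$c) / log(a),
                 center = v / 2),
            class = "attractor_spec")
}

#' @export
print.attractor_spec <- function(x, ...) {
  cat(sprintf("Attractor geometry: v = (%g, %g, %g), exponents (1, %g, %g)\n",
              x$v[1], x$v[2], x$v[3], x$e_b, x$e_c))
  invisible(x)
}

#' Fixed point v of the active-gene map in reduced coordinates
#'
#' @inheritParams attractor_spec
#' @return Numeric 3-vector.
#' @export
v_vector <- function(reduced) {
  r <- .as_reduced(reduced)
  a <- r$a; b <- r$b; c <- r$c
  c(1 / ((a - c) * (a - b) * (1 - a)),
    1 / ((b - a) * (b - c) * (1 - b)),
    1 / ((c - a) * (c - b) * (1 - c)))
}

.check_simplex <- function(s, tol = 1e-12) {
  if (is.matrix(s)) {
    ok <- s[, 1] <= 1 + tol & s[, 1] >= s[, 2] - tol &
      s[, 2] >= s[, 3] - tol & s[, 3] >= -tol
    if (!all(ok))
      stop("simplex coordinates must satisfy 1 >= x >= y >= z >= 0",
           call. = FALSE)
  } else {
    if (!(length(s) == 3L && s[1] <= 1 + tol && s[1] >= s[2] - tol &&
          s[2] >= s[3] - tol && s[3] >= -tol))
      stop("simplex coordinates must satisfy 1 >= x >= y >= z >= 0",
           call. = FALSE)
  }
  invisible(s)
}

.simplex_powers <- function(s, e) {
  # x^e with the continuity convention 0^e = 0 (e > 0), vectorized
  if (is.matrix(s)) s^e else s^e
}

#' Parametric points of the solid invariant set
#'
#' Every point of the invariant set `A` is the image of an ordered simplex
#' coordinate `1 >= x >= y >= z >= 0` under
#' \deqn{\big(v_1 (x - y + z),\; v_2 (x^{e_b} - y^{e_b} + z^{e_b}),\;
#'       v_3 (x^{e_c} - y^{e_c} + z^{e_c})\big),}
#' the closed form of a two-switch trajectory started from `v`.
#' `attractor_point_alt()` is the equivalent complementary parametrization
#' `v_k (1 - x^{e} + y^{e} - z^{e})`; the identity
#' `attractor_point_alt(s) = v - attractor_point(s)` is exact and expresses
#' the central symmetry of `A` through `v/2`.
#'
#' @param spec an [attractor_spec()].
#' @param s simplex coordinates: a 3-vector or n x 3 matrix with
#'   `1 >= x >= y >= z >= 0` rowwise.
#' @return A 3-vector or n x 3 matrix of points in reduced coordinates.
#' @export
attractor_point <- function(spec, s) {
  stopifnot(inherits(spec, "attractor_spec"))
  .check_simplex(s)
  v <- spec$v
  if (is.matrix(s)) {
    cbind(v[1] * (s[, 1] - s[, 2] + s[, 3]),
          v[2] * (s[, 1]^spec$e_b - s[, 2]^spec$e_b + s[, 3]^spec$e_b),
          v[3] * (s[, 1]^spec$e_c - s[, 2]^spec$e_c + s[, 3]^spec$e_c))
  } else {
    c(v[1] * (s[1] - s[2] + s[3]),
      v[2] * (s[1]^spec$e_b - s[2]^spec$e_b + s[3]^spec$e_b),
      v[3] * (s[1]^spec$e_c - s[2]^spec$e_c + s[3]^spec$e_c))
  }
}

#' @rdname attractor_point
#' @export
attractor_point_alt <- function(spec, s) {
  stopifnot(inherits(spec, "attractor_spec"))
  .check_simplex(s)
  out <- attractor_point(spec, s)
  if (is.matrix(out)) sweep(-out, 2, spec$v, `+`) else spec$v - out
}

#' Boundary surfaces of the invariant set
#'
#' The solid `A` is bounded by two one-switch trajectory surfaces:
#' `A0(alpha, beta) = ((alpha - beta) v_1, (alpha^{e_b} - beta^{e_b}) v_2,
#' (alpha^{e_c} - beta^{e_c}) v_3)` (trajectories through the origin) and its
#' mirror image `A1 = v - A0` (trajectories through `v`), for
#' `1 >= alpha >= beta >= 0`.  `A0` collapses to the origin and `A1` to `v`
#' when `alpha = beta`.
#'
#' @param spec an [attractor_spec()].
#' @param which `"A0"` or `"A1"`.
#' @param alpha,beta parameters with `1 >= alpha >= beta >= 0` (vectors of
#'   equal length allowed).
#' @return A 3-vector, or an n x 3 matrix for vector input.
#' @export
boundary_surface <- function(spec, which = c("A0", "A1"), alpha, beta) {
  stopifnot(inherits(spec, "attractor_spec"))
  which <- match.arg(which)
  stopifnot(length(alpha) == length(beta))
  if (any(alpha > 1 + 1e-12) || any(beta > alpha + 1e-12) || any(beta < -1e-12))
    stop("need 1 >= alpha >= beta >= 0", call. = FALSE)
  v <- spec$v
  a0 <- cbind((alpha - beta) * v[1],
              (alpha^spec$e_b - beta^spec$e_b) * v[2],
              (alpha^spec$e_c - beta^spec$e_c) * v[3])
  out <- if (which == "A0") a0 else sweep(-a0, 2, v, `+`)
  if (length(alpha) == 1L) drop(out) else out
}

#' Closed form of a two-switch trajectory segment
#'
#' Composition of three constant-gene flow segments of the reduced system
#' with alternating gene state, in closed form.  Starting active
#' (`start_i = 1`, segments 1/0/1 of durations `t1, t2, t3`):
#' `v_k (1 - l^{t3} + l^{t2+t3} - l^{t1+t2+t3}) + l^{t1+t2+t3} x_k` per
#' coordinate with ratio `l` in `{a, b, c}`; starting inactive
#' (`start_i = 0`, segments 0/1/0):
#' `v_k (l^{t3} - l^{t2+t3}) + l^{t1+t2+t3} x_k`.  Every point of the
#' invariant set `A` is reached this way from `x = v` (or `x = 0`), which is
#' how the solid parametrization of [attractor_point()] arises.
#'
#' @param spec an [attractor_spec()] (or reduced/kinetic parameters).
#' @param start_i gene state of the first segment, 0 or 1.
#' @param t1,t2,t3 nonnegative segment durations (real, step units).
#' @param x starting point in reduced coordinates.
#' @return Numeric 3-vector.
#' @export
two_switch_state <- function(spec, start_i, t1, t2, t3, x) {
  if (!inherits(spec, "attractor_spec")) spec <- attractor_spec(spec)
  .check_gene(start_i)
  stopifnot(t1 >= 0, t2 >= 0, t3 >= 0)
  .check_state(x)
  r <- spec$reduced
  l <- c(r$a, r$b, r$c)
  v <- spec$v
  if (start_i == 1)
    v * (1 - l^t3 + l^(t2 + t3) - l^(t1 + t2 + t3)) + l^(t1 + t2 + t3) * x
  else
    v * (l^t3 - l^(t2 + t3)) + l^(t1 + t2 + t3) * x
}

#' Deterministic grid sample of the invariant set
#'
#' Evaluates [attractor_point()] on the regular grid of the ordered simplex
#' `{1 >= x >= y >= z >= 0}` with `n_per_axis` levels per axis.  The returned
#' cloud carries attributes `h` (simplex grid spacing), `axis_spacing` (the
#' average image-space spacing per axis, `|v_k| * h`, since each coordinate
#' sweeps a range of `|v_k|` across the grid) and `resolution` (the Euclidean
#' norm of `axis_spacing`), used as the default membership scale.
#'
#' @param spec an [attractor_spec()].
#' @param n_per_axis number of grid levels per simplex axis (>= 2).
#' @return A [point_cloud()] in reduced coordinates.
#' @export
attractor_cloud <- function(spec, n_per_axis = 101L) {
  stopifnot(inherits(spec, "attractor_spec"), n_per_axis >= 2L)
  g <- seq(0, 1, length.out = n_per_axis)
  s <- as.matrix(expand.grid(x = g, y = g, z = g))
  s <- s[s[, 1] >= s[, 2] & s[, 2] >= s[, 3], , drop = FALSE]
  cl <- point_cloud(attractor_point(spec, s))
  h <- 1 / (n_per_axis - 1)
  axis_spacing <- abs(spec$v) * h
  attr(cl, "h") <- h
  attr(cl, "axis_spacing") <- axis_spacing
  attr(cl, "resolution") <- sqrt(sum(axis_spacing^2))
  cl
}

#' Sample-based membership test for the invariant set
#'
#' Tests whether points lie on the invariant set `A` by nearest-neighbour
#' distance against a deterministic grid cloud of [attractor_cloud()].  A
#' point is declared inside when its distance is at most `tol`; the default
#' tolerance is 3 times the cloud's image-space resolution.
#'
#' @param spec an [attractor_spec()].
#' @param points a 3-vector, n x 3 matrix or [point_cloud()] of
#'   reduced-coordinate points to test.
#' @param reference optional precomputed [attractor_cloud()]; built at
#'   `n_per_axis` when missing.
#' @param tol membership tolerance; defaults to `3 * resolution` of the
#'   reference cloud.  A warning is issued if `tol` is at or below the
#'   resolution (the grid cannot resolve membership that finely).
#' @param n_per_axis grid used when `reference` is missing.
#' @return A list with logical vector `inside`, numeric vector `distance`,
#'   and the scalars `tol` and `resolution`.
#' @export
attractor_membership <- function(spec, points, reference = NULL, tol = NULL,
                                 n_per_axis = 101L) {
  stopifnot(inherits(spec, "attractor_spec"))
  if (is.null(reference)) reference <- attractor_cloud(spec, n_per_axis)
  res <- attr(reference, "resolution")
  if (is.null(res)) res <- 0
  if (is.null(tol)) {
    if (res == 0)
      stop("tol must be given when the reference cloud has no resolution ",
           "attribute", call. = FALSE)
    tol <- 3 * res
  }
  if (res > 0 && tol <= res)
    warning("tol <= reference grid resolution (", signif(res, 3),
            "); membership at this tolerance is not resolved by the grid",
            call. = FALSE)
  if (!is.matrix(points)) points <- matrix(points, ncol = 3, byrow = TRUE)
  d <- as.numeric(cpp_nn_dist(.cloud_matrix(point_cloud(points)),
                              .cloud_matrix(reference)))
  list(inside = d <= tol, distance = d, tol = tol, resolution = res)
}
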