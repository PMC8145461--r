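#' One step of the molecule-level dynamics
#'
#' Advances the three molecule levels (pre-mRNA, mRNA, protein) by one time
#' step `delta` with the gene state held at `i`:
#' \deqn{\xi_1' = R i + (1 - C - \mu_{PR})\,\xi_1,\quad
#'       \xi_2' = C \xi_1 + (1 - \mu_R)\,\xi_2,\quad
#'       \xi_3' = P \xi_2 + (1 - \mu_P)\,\xi_3.}
#' The update uses the gene state *at the current time*: when simulating a
#' switching trajectory, the value of `i` in force during the step determines
#' the new molecule levels, not the value after the step.
#'
#' @param params a [kinetic_params()] object.
#' @param state numeric 3-vector of molecule levels (concentrations).
#' @param i gene state, 0 (inactive) or 1 (active).
#' @return Numeric 3-vector: the state one step later.
#' @examples
#' kp <- canonical_params()
#' gene_step(kp, c(1, 1, 1), i = 0)  # c(0.5, 1, 1)
#' @export
gene_step <- function(params, state, i) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_state(state)
  .check_gene(i)
  c(params$R * i + (1 - params$C - params$mu_PR) * state[1],
    params$C * state[1] + (1 - params$mu_R) * state[2],
    params$P * state[2] + (1 - params$mu_P) * state[3])
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 3L || !all(is.finite(state)))
    stop("state must be a finite numeric 3-vector", call. = FALSE)
  invisible(state)
}

.check_gene <- function(i) {
  if (!(length(i) == 1L && i %in% c(0, 1)))
    stop("gene state i must be 0 or 1", call. = FALSE)
  invisible(i)
}

#' Geometric-mode decomposition of the constant-gene solution
#'
#' With the gene held at `i`, each coordinate of the solution is a linear
#' combination of three geometric modes with ratios `a = 1 - C - mu_PR`,
#' `b = 1 - mu_R`, `c = 1 - mu_P`, plus a constant:
#' \deqn{\xi_k(t) = M_{k,a}\, a^{t/\delta} + M_{k,b}\, b^{t/\delta} +
#'       M_{k,c}\, c^{t/\delta} + M_{k,\mathrm{const}}.}
#' The constant column equals `w * i` and the row sums at `t = 0` recover the
#' initial state.  For the canonical parameter set of [canonical_params()] with
#' zero initial state and `i = 1` the protein row is
#' `(-4, -16, 18, 2)`: coefficient 18 on the `(2/3)^t` mode, -16 on
#' `(3/4)^t`, -4 on `(1/2)^t`, constant 2.
#'
#' @inheritParams gene_step
#' @return A list with `ratios` (named vector `a`, `b`, `c`) and
#'   `coefficients`, a 3 x 4 matrix with columns `a`, `b`, `c`, `const` and
#'   rows `xi1`, `xi2`, `xi3`.
#' @export
mode_decomposition <- function(params, state, i) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_state(state); .check_gene(i)
  .check_nondegenerate(params)
  R <- params$R; C <- params$C; P <- params$P
  A <- C + params$mu_PR; muR <- params$mu_R; muP <- params$mu_P
  M <- matrix(0, 3, 4,
              dimnames = list(c("xi1", "xi2", "xi3"),
                              c("a", "b", "c", "const")))
  M["xi1", "a"] <- state[1] - (R / A) * i
  M["xi1", "const"] <- (R / A) * i
  M["xi2", "a"] <- -C / (A - muR) * state[1] + R * C / ((A - muR) * A) * i
  M["xi2", "b"] <- state[2] + C / (A - muR) * state[1] -
    R * C / ((A - muR) * muR) * i
  M["xi2", "const"] <- R * C / (A * muR) * i
  M["xi3", "a"] <- P * C / ((A - muR) * (A - muP)) * state[1] -
    P * C * R / ((A - muR) * (A - muP) * A) * i
  M["xi3", "b"] <- -P / (muR - muP) * state[2] -
    P * C / ((muR - muP) * (A - muR)) * state[1] +
    P * C * R / ((A - muR) * (muR - muP) * muR) * i
  M["xi3", "c"] <- state[3] + P / (muR - muP) * state[2] +
    P * C / ((muR - muP) * (A - muP)) * state[1] -
    P * C * R / ((muR - muP) * (A - muP) * muP) * i
  M["xi3", "const"] <- P * C * R / (A * muR * muP) * i
  r <- reduce_params(params)
  list(ratios = c(a = r$a, b = r$b, c = r$c), coefficients = M)
}

#' Closed-form constant-gene flow
#'
#' Evaluates the closed-form solution of the constant-gene difference system
#' at an arbitrary real time `t >= 0` (in the same units as `delta`); on the
#' step grid `t = n * delta` it coincides with `n` applications of
#' [gene_step()], and the geometric modes extend it continuously between
#' steps.  As `t` grows the flow relaxes to `w * i`.
#'
#' @inheritParams gene_step
#' @param t nonnegative time (scalar or vector), in physical units.
#' @return If `t` is scalar, a numeric 3-vector; otherwise a `length(t)` x 3
#'   matrix with one row per time point.
#' @examples
#' kp <- canonical_params()
#' gene_flow(kp, 3, c(0, 0, 0), i = 1)
#' @export
gene_flow <- function(params, t, state, i) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be nonnegative and finite", call. = FALSE)
  md <- mode_decomposition(params, state, i)
  e <- t / params$delta
  basis <- cbind(md$ratios[["a"]]^e, md$ratios[["b"]]^e,
                 md$ratios[["c"]]^e, 1)
  out <- basis %*% t(md$coefficients)
  colnames(out) <- c("xi1", "xi2", "xi3")
  if (length(t) == 1L) unname(drop(out)) else out
}

#' Map between original and reduced (starred) coordinates
#'
#' The triangular linear change of variables
#' \deqn{\xi_1 = R (a-c)(a-b)\, \xi_1^*,\qquad
#'       \xi_2 = C R \big((a-c) \xi_1^* + (b-c) \xi_2^*\big),\qquad
#'       \xi_3 = P C R\, (\xi_1^* + \xi_2^* + \xi_3^*)}
#' conjugates the molecule-level dynamics to a diagonal affine system in
#' which both gene states act as coordinatewise contractions with factors
#' `a`, `b`, `c`.  `to_reduced()` maps original to starred coordinates;
#' `from_reduced()` is its exact inverse.
#'
#' @param params a [kinetic_params()] object.
#' @param state numeric 3-vector (original coordinates for `to_reduced`,
#'   starred coordinates for `from_reduced`).
#' @return Numeric 3-vector in the other coordinate system.
#' @export
to_reduced <- function(params, state) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_state(state)
  r <- reduce_params(params)
  a <- r$a; b <- r$b; c <- r$c
  R <- params$R; C <- params$C; P <- params$P
  s1 <- state[1] / (R * (a - c) * (a - b))
  s2 <- (state[2] / (C * R) - (a - c) * s1) / (b - c)
  s3 <- state[3] / (P * C * R) - s1 - s2
  c(s1, s2, s3)
}

#' @rdname to_reduced
#' @export
from_reduced <- function(params, state) {
  stopifnot(inherits(params, "kinetic_params"))
  .check_state(state)
  r <- reduce_params(params)
  a <- r$a; b <- r$b; c <- r$c
  R <- params$R; C <- params$C; P <- params$P
  c(R * (a - c) * (a - b) * state[1],
    C * R * ((a - c) * state[1] + (b - c) * state[2]),
    P * C * R * (state[1] + state[2] + state[3]))
}

#' Residual of the on/off flow symmetry
#'
#' The two constant-gene flows are mirror images through `w/2`:
#' `pi_0(t, w - xi) = w - pi_1(t, xi)` for every time and state.  This helper
#' evaluates both sides by the closed-form flow and returns the Euclidean norm
#' of their difference, which should be at machine-precision level.
#'
#' @inheritParams gene_step
#' @param t nonnegative scalar time.
#' @return Nonnegative scalar residual.
#' @export
symmetry_residual <- function(params, t, state) {
  w <- fixed_point_w(params)
  lhs <- gene_flow(params, t, w - state, i = 0)
  rhs <- w - gene_flow(params, t, state, i = 1)
  sqrt(sum((lhs - rhs)^2))
}
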