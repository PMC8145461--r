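#' Built-in probability and intensity functions
#'
#' The switching machinery accepts any R function mapping a numeric 3-vector
#' to a scalar.  Three families cover the canonical configurations:
#' * `constant_prob(p)` — the constant function, e.g. the chaos game with
#'   `p0 = p1 = 1/2`;
#' * `rational_prob()` — the rational form `p0(x) = 1 / (2 (1 + |x|^2))`
#'   used in the package's reference stochastic simulation;
#' * `logistic_prob(k, mid)` — a logistic function of the squared norm,
#'   `plogis(k (|x|^2 - mid))`.
#'
#' @param p constant value in `[0, 1]` (or a positive intensity for
#'   `constant_intensity()`).
#' @param k,mid slope and midpoint of the logistic form.
#' @return A function of a numeric 3-vector returning a scalar.
#' @export
constant_prob <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  force(p)
  f <- function(x) p
  attr(f, "spec") <- list(name = "constant", value = p)
  f
}

#' @rdname constant_prob
#' @export
rational_prob <- function() {
  f <- function(x) 1 / (2 * (1 + sum(x^2)))
  attr(f, "spec") <- list(name = "rational")
  f
}

#' @rdname constant_prob
#' @export
logistic_prob <- function(k = 1, mid = 0) {
  stopifnot(is.finite(k), is.finite(mid))
  force(k); force(mid)
  f <- function(x) stats::plogis(k * (sum(x^2) - mid))
  attr(f, "spec") <- list(name = "logistic", k = k, mid = mid)
  f
}

#' @rdname constant_prob
#' @export
constant_intensity <- function(p) {
  stopifnot(is.finite(p), p > 0)
  force(p)
  f <- function(x) p
  attr(f, "spec") <- list(name = "constant", value = p)
  f
}

.box_grid <- function(box, n = 10L) {
  g <- lapply(1:3, function(k) seq(box[1, k], box[2, k], length.out = n))
  as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
}

#' Place-dependent map-selection probabilities
#'
#' A pair of functions `p0(x)`, `p1(x)` with `p0 + p1 = 1`: the probability
#' of applying map `S0` (gene off) or `S1` (gene on) in the next step, as a
#' function of the current point.  Uniqueness of the invariant measure is
#' guaranteed when both probabilities are Holder continuous and uniformly
#' bounded below by some `delta0 > 0`; `delta0`, if supplied together with
#' `params`, is checked empirically on a regular grid of the invariant box
#' and violations raise a warning (the hypothesis is the user's
#' responsibility, not a hard precondition).
#'
#' @param p0 function of a 3-vector: probability of choosing map 0.
#' @param p1 optional; defaults to `function(x) 1 - p0(x)`.  If supplied, the
#'   complement identity is spot-checked.
#' @param delta0 optional claimed uniform lower bound for both probabilities.
#' @param params optional [kinetic_params()]; provides the box on which
#'   `delta0` and the complement identity are spot-checked.
#' @return An object of class `probability_pair`.
#' @export
probability_pair <- function(p0, p1 = NULL, delta0 = NULL, params = NULL) {
  stopifnot(is.function(p0))
  explicit_p1 <- !is.null(p1)
  if (!explicit_p1) p1 <- function(x) 1 - p0(x)
  obj <- structure(list(p0 = p0, p1 = p1, delta0 = delta0),
                   class = "probability_pair")
  pts <- rbind(diag(3), -diag(3), 0, 1)
  if (!is.null(params)) pts <- rbind(pts, .box_grid(invariant_box(params), 5L))
  v0 <- apply(pts, 1, p0); v1 <- apply(pts, 1, p1)
  if (any(!is.finite(v0)) || any(v0 < 0) || any(v0 > 1) ||
      any(!is.finite(v1)) || any(v1 < 0) || any(v1 > 1))
    stop("probability functions must take values in [0, 1]", call. = FALSE)
  if (explicit_p1 && any(abs(v0 + v1 - 1) > 1e-12))
    stop("p0(x) + p1(x) must equal 1 for every x", call. = FALSE)
  if (!is.null(delta0) && any(pmin(v0, v1) < delta0))
    warning("claimed lower bound delta0 = ", delta0,
            " is violated at sampled points; the uniqueness hypothesis ",
            "may fail", call. = FALSE)
  obj
}

#' State-dependent jump intensities
#'
#' A pair of positive bounded functions `q0(x)`, `q1(x)`: the hazard of
#' leaving gene state 0 (resp. 1) per time step when the molecule levels are
#' at `x`.  The supremum `q_max` over the invariant box bounds the jump
#' cumulative distribution, `F(t) <= 1 - exp(-q_max t)`, and the expected
#' number of jumps up to time `t` by `exp(q_max t)`.  When `params` is
#' supplied `q_max` is estimated on a regular 10 x 10 x 10 grid of the
#' invariant box; nonpositive intensities there raise a warning.
#'
#' @param q0,q1 intensity functions of a 3-vector (`q1` defaults to `q0`).
#' @param params optional [kinetic_params()] providing the invariant box.
#' @param q_max optional known supremum bound; estimated from the grid when
#'   missing and `params` is given.
#' @return An object of class `intensity_pair`.
#' @export
intensity_pair <- function(q0, q1 = q0, params = NULL, q_max = NULL) {
  stopifnot(is.function(q0), is.function(q1))
  est <- NA_real_
  if (!is.null(params)) {
    pts <- .box_grid(invariant_box(params), 10L)
    v <- c(apply(pts, 1, q0), apply(pts, 1, q1))
    if (any(!is.finite(v)))
      stop("intensity functions must be finite on the invariant box",
           call. = FALSE)
    if (any(v <= 0))
      warning("intensity functions should be strictly positive on the ",
              "invariant box; jumps may never occur where q <= 0",
              call. = FALSE)
    est <- max(v)
    if (!is.null(q_max) && est > q_max)
      warning("supplied q_max = ", q_max,
              " is exceeded on the sampled grid (max ", signif(est, 4), ")",
              call. = FALSE)
  }
  if (is.null(q_max)) q_max <- est
  structure(list(q0 = q0, q1 = q1, q_max = q_max),
            class = "intensity_pair")
}

.orbit_hazards <- function(q, params, i, x0, n) {
  # q evaluated along the exact step orbit at relative times 0 .. n-1
  h <- numeric(n)
  x <- x0
  for (s in seq_len(n)) {
    h[s] <- q(x)
    if (!is.finite(h[s]))
      stop("intensity function returned a non-finite value", call. = FALSE)
    x <- gene_step(params, x, i)
  }
  h
}

#' Discrete life-span (survival) function
#'
#' The probability that no gene switch has occurred by time `t` when the gene
#' is held at `i` and the molecule levels follow the deterministic orbit from
#' `x0`:
#' \deqn{\Phi_{x_0}(t) = \exp\Big\{-\sum_{s=0}^{\lfloor t\rfloor - 1}
#'       q\big(\pi_i(s, x_0)\big)\Big\},}
#' with the empty sum for `t < 1` giving `Phi = 1`.  Time is measured in
#' steps.  `survival_product()` is the exact per-step product form
#' `prod(1 - q(pi(s)))`, which agrees with the exponential form to first
#' order when `q` is small; it requires `q < 1` along the orbit.
#' `jump_cdf()` is the complement `F = 1 - Phi` of the exponential form: the
#' cumulative distribution function of the first switch time.
#'
#' @param q intensity function (of a 3-vector).
#' @param params a [kinetic_params()] object.
#' @param i gene state held constant along the orbit.
#' @param x0 initial molecule state.
#' @param t nonnegative time(s), in step units; may be a vector.
#' @return Numeric vector like `t` with values in (0, 1] (`life_span`,
#'   `survival_product`) or \[0, 1) (`jump_cdf`).
#' @export
life_span <- function(q, params, i, x0, t) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  n <- floor(t)
  nmax <- max(n)
  if (nmax == 0) return(rep(1, length(t)))
  cum <- c(0, cumsum(.orbit_hazards(q, params, i, x0, nmax)))
  exp(-cum[n + 1])
}

#' @rdname life_span
#' @export
survival_product <- function(q, params, i, x0, t) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  n <- floor(t)
  nmax <- max(n)
  if (nmax == 0) return(rep(1, length(t)))
  h <- .orbit_hazards(q, params, i, x0, nmax)
  if (any(h >= 1))
    stop("survival_product: q >= 1 encountered along the orbit; the ",
         "product form is not a probability there", call. = FALSE)
  cum <- c(1, cumprod(1 - h))
  cum[n + 1]
}

#' @rdname life_span
#' @export
jump_cdf <- function(q, params, i, x0, t) {
  1 - life_span(q, params, i, x0, t)
}

#' Sample the first switch time
#'
#' Draws the first switch time `t1` (a positive integer number of steps) from
#' the discrete law `P(t1 > n) = Phi(n)` of [life_span()] by inverse-CDF
#' search: draw `U ~ Unif(0,1)` and return the smallest `n >= 1` with
#' `F(n) >= U`.  If no switch has occurred by `t_cap` steps an error of class
#' `ifsgene_cap_exceeded` is raised carrying `Phi(t_cap)` in its `phi` field.
#'
#' @inheritParams life_span
#' @param t_cap maximum number of steps to search (default `1e6`).
#' @param u optional uniform draw in (0, 1); taken from the RNG when missing.
#' @return Positive integer: the sampled switch step.
#' @export
sample_jump_time <- function(q, params, i, x0, t_cap = 1e6, u = NULL) {
  stopifnot(t_cap >= 1)
  if (is.null(u)) u <- stats::runif(1)
  stopifnot(u > 0, u < 1)
  thr <- -log1p(-u)          # F(n) >= u  <=>  sum of hazards >= thr
  acc <- 0
  x <- x0
  for (n in seq_len(t_cap)) {
    h <- q(x)
    if (!is.finite(h))
      stop("intensity function returned a non-finite value", call. = FALSE)
    acc <- acc + h
    if (acc >= thr) return(as.integer(n))
    x <- gene_step(params, x, i)
  }
  cond <- structure(
    class = c("ifsgene_cap_exceeded", "error", "condition"),
    list(message = sprintf(
      "no switch sampled within t_cap = %d steps (survival Phi = %.3g)",
      as.integer(t_cap), exp(-acc)),
      call = sys.call(-1), phi = exp(-acc)))
  stop(cond)
}

.new_trajectory <- function(df, params, semantics, jump_steps, coordinates) {
  structure(df, class = c("ifs_trajectory", "data.frame"),
            params = params, semantics = semantics,
            jump_steps = as.integer(jump_steps), coordinates = coordinates)
}

#' @export
print.ifs_trajectory <- function(x, ...) {
  cat(sprintf(
    "Hybrid trajectory: %d steps (%s switching, %s coordinates), %d switches\n",
    nrow(x) - 1L, attr(x, "semantics"), attr(x, "coordinates"),
    length(attr(x, "jump_steps"))))
  NextMethod()
}

#' Switch steps and jump counts of a trajectory
#'
#' `jump_steps()` returns the step indices at which the gene state flipped;
#' `n_jumps_by()` counts the switches that happened strictly before physical
#' time `t`.
#'
#' @param traj an `ifs_trajectory` as returned by the simulators.
#' @param t physical time (same units as `delta`); may be a vector.
#' @return Integer vector.
#' @export
jump_steps <- function(traj) attr(traj, "jump_steps")

#' @rdname jump_steps
#' @export
n_jumps_by <- function(traj, t) {
  js <- attr(traj, "jump_steps")
  delta <- if (!is.null(attr(traj, "params")$delta))
    attr(traj, "params")$delta else 1
  vapply(t, function(tt) sum(js * delta < tt), integer(1))
}

#' Simulate the intensity-driven jump process
#'
#' The piecewise-deterministic simulator: between switches the molecule
#' levels follow the deterministic one-step dynamics with the gene state held
#' constant, and switch times are sampled from the life-span law of
#' [life_span()] by inverse-CDF search.  At a switch step the molecule state
#' is the deterministic flow endpoint and the recorded gene state is already
#' flipped; the new segment restarts from there.
#'
#' @param params a [kinetic_params()] object.
#' @param qpair an [intensity_pair()].
#' @param init initial molecule state (3-vector).
#' @param gene initial gene state (0 or 1).
#' @param horizon number of steps to simulate.
#' @param seed optional integer seed.
#' @param t_cap per-segment cap passed to the jump-time sampler.
#' @return An `ifs_trajectory`: a data frame with columns `step`, `t`,
#'   `xi1`, `xi2`, `xi3`, `i` and attributes `jump_steps`, `semantics`
#'   (`"intensity"`), `params`.
#' @export
simulate_jump_process <- function(params, qpair, init, gene = 1L,
                                  horizon, seed = NULL, t_cap = 1e6) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(qpair, "intensity_pair"), horizon >= 1)
  .check_state(init); .check_gene(gene)
  if (!is.null(seed)) set.seed(seed)
  qs <- list(qpair$q0, qpair$q1)
  X <- matrix(NA_real_, horizon + 1L, 3)
  gv <- integer(horizon + 1L)
  x <- init; i <- as.integer(gene)
  X[1L, ] <- x; gv[1L] <- i
  jumps <- integer(0)
  thr <- -log1p(-stats::runif(1))
  acc <- 0; rel <- 0L
  for (n in seq_len(horizon)) {
    h <- qs[[i + 1L]](x)
    if (!is.finite(h))
      stop("intensity function returned a non-finite value", call. = FALSE)
    x <- gene_step(params, x, i)   # molecule update uses the pre-switch gene
    acc <- acc + h
    rel <- rel + 1L
    if (acc >= thr) {              # switch occurs at this step
      i <- 1L - i
      jumps <- c(jumps, n)
      thr <- -log1p(-stats::runif(1))
      acc <- 0; rel <- 0L
    } else if (rel >= t_cap) {
      cond <- structure(
        class = c("ifsgene_cap_exceeded", "error", "condition"),
        list(message = sprintf(
          "no switch within t_cap = %d steps (survival Phi = %.3g)",
          as.integer(t_cap), exp(-acc)), call = sys.call(), phi = exp(-acc)))
      stop(cond)
    }
    X[n + 1L, ] <- x; gv[n + 1L] <- i
  }
  df <- data.frame(step = 0:horizon, t = (0:horizon) * params$delta,
                   xi1 = X[, 1], xi2 = X[, 2], xi3 = X[, 3], i = gv)
  .new_trajectory(df, params, "intensity", jumps, "original")
}

.rule_p1 <- function(rule, x, i) {
  # probability that the NEXT gene state is 1, given current point and gene
  if (inherits(rule, "probability_pair")) {
    p0 <- rule$p0(x)
    if (!is.finite(p0) || p0 < 0 || p0 > 1)
      stop("probability rule returned a value outside [0, 1]", call. = FALSE)
    1 - p0
  } else if (inherits(rule, "switch_rule")) {
    q <- rule$q[[i + 1L]](x)
    if (!is.finite(q) || q < 0)
      stop("bridged intensity returned an invalid value", call. = FALSE)
    if (q >= 1)
      stop("bridged intensity q >= 1: not a per-step switch probability",
           call. = FALSE)
    if (i == 1L) 1 - q else q
  } else stop("rule must be a probability_pair or switch_rule", call. = FALSE)
}

#' Simulate the place-dependent IFS process
#'
#' The per-step simulator: at every step a gene state `j` is drawn with
#' probabilities `p0`/`p1` evaluated at the *current* molecule state, the
#' one-step map with that `j` is applied (the affine map `S_j` in reduced
#' coordinates, the kinetic step in original coordinates), and the gene
#' coordinate is set to `j`.  With a [probability_pair()] the draw ignores
#' the current gene state; a `switch_rule` from
#' [switch_semantics_bridge()] instead switches away from the current state
#' `i` with probability `q_i(x)`.
#'
#' @param params a [kinetic_params()] object (original coordinates) or a
#'   [reduced_params()]/[ifs_maps()] object (reduced coordinates).
#' @param rule a [probability_pair()] or a `switch_rule`.
#' @param init initial state (3-vector, in the chosen coordinates).
#' @param gene initial gene state (recorded at step 0).
#' @param n_steps number of steps.
#' @param seed optional integer seed.
#' @param coordinates `"original"` or `"reduced"`; inferred from `params`
#'   when missing.
#' @return An `ifs_trajectory` with `semantics = "per-step"`.
#' @export
simulate_ifs_process <- function(params, rule, init, gene = 1L, n_steps,
                                 seed = NULL, coordinates = NULL) {
  stopifnot(n_steps >= 1)
  .check_state(init); .check_gene(gene)
  if (is.null(coordinates))
    coordinates <- if (inherits(params, "kinetic_params"))
      "original" else "reduced"
  coordinates <- match.arg(coordinates, c("original", "reduced"))
  if (coordinates == "reduced") {
    maps <- if (inherits(params, "ifs_maps")) params else ifs_maps(params)
    stepfun <- function(x, j) apply_map(maps, j, x)
    delta <- 1
    par_attr <- maps
  } else {
    stopifnot(inherits(params, "kinetic_params"))
    stepfun <- function(x, j) gene_step(params, x, j)
    delta <- params$delta
    par_attr <- params
  }
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(NA_real_, n_steps + 1L, 3)
  gv <- integer(n_steps + 1L)
  x <- init; i <- as.integer(gene)
  X[1L, ] <- x; gv[1L] <- i
  jumps <- integer(0)
  us <- stats::runif(n_steps)
  for (n in seq_len(n_steps)) {
    p1 <- .rule_p1(rule, x, i)
    j <- if (us[n] < p1) 1L else 0L
    x <- stepfun(x, j)
    if (j != i) jumps <- c(jumps, n)
    i <- j
    X[n + 1L, ] <- x; gv[n + 1L] <- i
  }
  df <- data.frame(step = 0:n_steps, t = (0:n_steps) * delta,
                   xi1 = X[, 1], xi2 = X[, 2], xi3 = X[, 3], i = gv)
  .new_trajectory(df, par_attr, "per-step", jumps, coordinates)
}

#' Bridge from jump intensities to a per-step switching rule
#'
#' The exact per-step reading of the product-form survival function: from
#' gene state `i` at point `x`, switch to `1 - i` with probability `q_i(x)`.
#' Under this rule the first-switch law of [simulate_ifs_process()] equals
#' [survival_product()] exactly, and for small intensities it agrees with
#' the exponential life-span law to first order.
#'
#' Unlike a [probability_pair()], whose map choice ignores the current gene
#' state, the bridged rule depends on it whenever `q0 != q1`; the returned
#' object records this in its `i_dependent` field.  The model leaves the
#' exact correspondence between the two parametrizations open, so the bridge
#' is the only relation derivable from the product form, not a claimed
#' equivalence.
#'
#' @param qpair an [intensity_pair()] with values below 1 wherever evaluated.
#' @return An object of class `switch_rule` with fields `q` (list of the two
#'   intensity functions) and `i_dependent`.
#' @export
switch_semantics_bridge <- function(qpair) {
  stopifnot(inherits(qpair, "intensity_pair"))
  if (is.finite(qpair$q_max) && qpair$q_max >= 1)
    stop("bridge requires q < 1 everywhere: q_max = ", qpair$q_max,
         call. = FALSE)
  pts <- rbind(diag(3), 0, 0.5, 2)
  dep <- !identical(qpair$q0, qpair$q1) &&
    any(abs(apply(pts, 1, qpair$q0) - apply(pts, 1, qpair$q1)) > 1e-12)
  structure(list(q = list(qpair$q0, qpair$q1), i_dependent = dep),
            class = "switch_rule")
}
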