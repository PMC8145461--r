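#' Kinetic parameters of the three-stage expression model
#'
#' Bundles the per-step reaction rates of the discrete-time gene expression
#' model: synthesis of pre-mRNA while the gene is active, conversion of
#' pre-mRNA to mRNA and of mRNA to protein, and first-order degradation of all
#' three species.  All rates are per time step of length `delta` and therefore
#' dimensionless.
#'
#' Validity requires `0 < C + mu_PR < 1`, `0 < mu_R + P < 1` and
#' `0 < mu_P < 1` (a step cannot degrade more molecules than are present), and
#' the non-degeneracy conditions `C + mu_PR != mu_R`, `mu_R != mu_P`,
#' `mu_P != C + mu_PR`, under which the linear system has three distinct
#' geometric modes and a closed-form solution.
#'
#' @param R pre-mRNA synthesis rate while the gene is active (> 0).
#' @param C pre-mRNA to mRNA conversion rate (> 0).
#' @param P mRNA to protein conversion rate (> 0).
#' @param mu_PR,mu_R,mu_P degradation rates of pre-mRNA, mRNA and protein.
#' @param delta length of one time step (> 0); defaults to 1.
#' @return An object of class `kinetic_params`.
#' @seealso [reduce_params()], [fixed_point_w()], [gene_step()], [gene_flow()]
#' @examples
#' kp <- kinetic_params(R = 1, C = 1/4, P = 1/3,
#'                      mu_PR = 1/4, mu_R = 1/4, mu_P = 1/3)
#' fixed_point_w(kp)
#' @export
kinetic_params <- function(R, C, P, mu_PR, mu_R, mu_P, delta = 1) {
  vals <- c(R = R, C = C, P = P, mu_PR = mu_PR, mu_R = mu_R,
            mu_P = mu_P, delta = delta)
  if (!all(is.finite(vals)))
    stop("all kinetic parameters must be finite numbers", call. = FALSE)
  if (any(vals <= 0))
    stop("kinetic parameters must be strictly positive; offending: ",
         paste(names(vals)[vals <= 0], collapse = ", "), call. = FALSE)
  if (C + mu_PR >= 1)
    stop("need 0 < C + mu_PR < 1: a step cannot degrade or convert more ",
         "pre-mRNA than is present", call. = FALSE)
  if (mu_R + P >= 1)
    stop("need 0 < mu_R + P < 1", call. = FALSE)
  if (mu_P >= 1)
    stop("need 0 < mu_P < 1", call. = FALSE)
  obj <- structure(as.list(vals), class = "kinetic_params")
  .check_nondegenerate(obj)
  obj
}

.check_nondegenerate <- function(p, tol = 0) {
  s1 <- p$C + p$mu_PR
  if (s1 == p$mu_R || p$mu_R == p$mu_P || p$mu_P == s1)
    stop("degenerate parameters: C + mu_PR, mu_R and mu_P must be pairwise ",
         "distinct (repeated geometric modes are not supported)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (per step of length delta = ", x$delta, ")\n",
      sep = "")
  cat(sprintf("  R = %g, C = %g, P = %g\n", x$R, x$C, x$P))
  cat(sprintf("  mu_PR = %g, mu_R = %g, mu_P = %g\n",
              x$mu_PR, x$mu_R, x$mu_P))
  r <- reduce_params(x)
  cat(sprintf("  contraction factors: a = %g, b = %g, c = %g\n",
              r$a, r$b, r$c))
  invisible(x)
}

#' Reduced contraction factors (a, b, c)
#'
#' Collapses the kinetic rates to the three per-coordinate geometric ratios of
#' the linear dynamics: `a = 1 - C - mu_PR`, `b = 1 - mu_R`, `c = 1 - mu_P`.
#' Each lies in (0, 1) and they must be pairwise distinct; `max(a, b, c)` is
#' the contraction constant of the induced affine maps.
#'
#' @param params a [kinetic_params()] object.
#' @return An object of class `reduced_params` with fields `a`, `b`, `c`.
#' @examples
#' reduce_params(canonical_params())  # a = 1/2, b = 3/4, c = 2/3
#' @export
reduce_params <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  reduced_params(a = 1 - params$C - params$mu_PR,
                 b = 1 - params$mu_R,
                 c = 1 - params$mu_P)
}

#' Construct reduced parameters directly
#'
#' @param a,b,c contraction factors, each in (0, 1), pairwise distinct.
#' @return An object of class `reduced_params`.
#' @rdname reduce_params
#' @export
reduced_params <- function(a, b, c) {
  v <- c(a = a, b = b, c = c)
  if (!all(is.finite(v)) || any(v <= 0) || any(v >= 1))
    stop("contraction factors a, b, c must lie strictly inside (0, 1)",
         call. = FALSE)
  if (a == b || b == c || c == a)
    stop("degenerate parameters: a, b, c must be pairwise distinct",
         call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("Reduced contraction factors: a = %g, b = %g, c = %g (max %g)\n",
              x$a, x$b, x$c, max(x$a, x$b, x$c)))
  invisible(x)
}

.as_reduced <- function(params) {
  if (inherits(params, "reduced_params")) params else reduce_params(params)
}

#' Active-gene steady state w and the invariant box
#'
#' `fixed_point_w()` returns the steady state of the dynamics with the gene
#' permanently active:
#' `w = (R/(C+mu_PR), RC/((C+mu_PR) mu_R), PCR/((C+mu_PR) mu_R mu_P))`.
#' It is the fixed point of the one-step map with gene state 1, and every
#' constant-gene trajectory relaxes to `w * i` geometrically.
#' `invariant_box()` returns the product interval `[0, w1] x [0, w2] x
#' [0, w3]`, which the process never leaves once entered.
#'
#' @param params a [kinetic_params()] object.
#' @return `fixed_point_w()`: numeric 3-vector.  `invariant_box()`: a 2 x 3
#'   matrix with rows `lower`, `upper`.
#' @examples
#' fixed_point_w(canonical_params())  # c(2, 2, 2)
#' @export
fixed_point_w <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  s1 <- params$C + params$mu_PR
  w1 <- params$R / s1
  w2 <- w1 * params$C / params$mu_R
  w3 <- w2 * params$P / params$mu_P
  c(w1, w2, w3)
}

#' @rdname fixed_point_w
#' @export
invariant_box <- function(params) {
  w <- fixed_point_w(params)
  rbind(lower = c(0, 0, 0), upper = w)
}
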