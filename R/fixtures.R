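#' Canonical parameter set of the worked example
#'
#' The reference kinetic configuration used throughout the documentation and
#' tests: `delta = 1`, `R = 1`, `mu_PR = 1/4`, `C = mu_R = 1/4`,
#' `P = mu_P = 1/3`.  Its contraction factors are `a = 1/2`, `b = 3/4`,
#' `c = 2/3`, its active steady state is `w = (2, 2, 2)`, and the
#' zero-initial-state active solution has protein-mode coefficients
#' 18, -16, -4 and constant 2.
#'
#' @return A [kinetic_params()] object.
#' @export
canonical_params <- function() {
  kinetic_params(R = 1, C = 1/4, P = 1/3,
                 mu_PR = 1/4, mu_R = 1/4, mu_P = 1/3, delta = 1)
}

#' Named canonical run configurations
#'
#' Three ready-made configurations mirror the package's reference
#' computations:
#' * `"canonical"` — the [canonical_params()] kinetics, deterministic flow
#'   context (constant-gene trajectories);
#' * `"chaos"` — the reduced system with `a = 1/2`, `b = 3/4`, `c = 2/3`,
#'   chaos game from the origin with constant probabilities 1/2 and 100000
#'   iterations;
#' * `"rational"` — the example kinetics with the rational place-dependent
#'   probability `p0(x) = 1/(2(1+|x|^2))`, started from `(1/2, 1/2, 1/2)`.
#'
#' @param name one of `"canonical"`, `"chaos"`, `"rational"`.
#' @return A run-configuration list (see [read_run_config()]).
#' @export
ifs_fixture <- function(name = c("canonical", "chaos", "rational")) {
  name <- match.arg(name)
  switch(name,
    canonical = list(
      name = "canonical",
      model = list(kind = "kinetic", R = 1, C = 0.25, P = 1/3,
                   mu_PR = 0.25, mu_R = 0.25, mu_P = 1/3, delta = 1),
      switching = list(semantics = "per-step",
                       p0 = list(name = "constant", value = 0.5)),
      run = list(init = c(0, 0, 0), gene = 1, steps = 100, burn_in = 0,
                 seed = 1),
      output = list(prefix = "canonical")),
    chaos = list(
      name = "chaos",
      model = list(kind = "reduced", a = 0.5, b = 0.75, c = 2/3),
      switching = list(semantics = "per-step",
                       p0 = list(name = "constant", value = 0.5)),
      run = list(init = c(0, 0, 0), gene = 1, steps = 100000, burn_in = 0,
                 seed = 1),
      output = list(prefix = "chaos")),
    rational = list(
      name = "rational",
      model = list(kind = "kinetic", R = 1, C = 0.25, P = 1/3,
                   mu_PR = 0.25, mu_R = 0.25, mu_P = 1/3, delta = 1),
      switching = list(semantics = "per-step",
                       p0 = list(name = "rational")),
      run = list(init = c(0.5, 0.5, 0.5), gene = 1, steps = 10000,
                 burn_in = 0, seed = 1),
      output = list(prefix = "rational")))
}

.resolve_fun <- function(spec, kind = c("prob", "intensity")) {
  kind <- match.arg(kind)
  if (is.function(spec)) return(spec)
  stopifnot(is.list(spec), !is.null(spec$name))
  switch(spec$name,
    constant = if (kind == "prob") constant_prob(spec$value)
               else constant_intensity(spec$value),
    rational = rational_prob(),
    logistic = logistic_prob(k = spec$k %||% 1, mid = spec$mid %||% 0),
    stop("unknown built-in function name: ", spec$name, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_params <- function(config) {
  m <- config$model
  if (identical(m$kind, "kinetic"))
    kinetic_params(R = m$R, C = m$C, P = m$P, mu_PR = m$mu_PR,
                   mu_R = m$mu_R, mu_P = m$mu_P, delta = m$delta %||% 1)
  else if (identical(m$kind, "reduced"))
    reduced_params(a = m$a, b = m$b, c = m$c)
  else stop("config$model$kind must be 'kinetic' or 'reduced'",
            call. = FALSE)
}

.validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$model), !is.null(config$run))
  if (!identical(config$model$kind, "kinetic") &&
      !identical(config$model$kind, "reduced"))
    stop("exactly one parameter block, kinetic or reduced, must be present",
         call. = FALSE)
  sw <- config$switching
  if (!is.null(sw)) {
    sem <- sw$semantics %||% "per-step"
    if (!sem %in% c("per-step", "intensity"))
      stop("switching$semantics must be 'per-step' or 'intensity'",
           call. = FALSE)
    if (sem == "per-step" && is.null(sw$p0))
      stop("per-step switching requires a p0 function spec", call. = FALSE)
    if (sem == "intensity" && is.null(sw$q0))
      stop("intensity switching requires a q0 function spec", call. = FALSE)
    if (is.null(config$run$seed))
      stop("seed is mandatory for stochastic runs", call. = FALSE)
  }
  invisible(config)
}

#' Read and write run-configuration files
#'
#' Run configurations are stored as flat YAML with sections `model`
#' (`kind: kinetic` with the six rates and `delta`, or `kind: reduced` with
#' `a`, `b`, `c`), `switching` (`semantics: per-step` with a `p0` built-in
#' spec, or `semantics: intensity` with `q0`/`q1` specs), `run` (`init`,
#' `gene`, `steps`, `burn_in`, `seed`) and `output` (`prefix`).  Function
#' specs name a built-in (`constant`, `rational`, `logistic`) plus its
#' parameters.
#'
#' @param path file path.
#' @param config configuration list.
#' @return `read_run_config()`: the validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  config <- yaml::read_yaml(path)
  if (!is.null(config$run$init)) config$run$init <- as.numeric(config$run$init)
  .validate_config(config)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  .validate_config(config)
  # full double precision so rates like 1/3 survive the round trip
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' Run the simulator described by a configuration
#'
#' Dispatches on the configuration's switching semantics: `"per-step"` runs
#' [simulate_ifs_process()], `"intensity"` runs [simulate_jump_process()]
#' (kinetic parameters only).
#'
#' @param config a run-configuration list.
#' @param steps,seed optional overrides of the configured values.
#' @return An `ifs_trajectory`.
#' @export
run_config_simulation <- function(config, steps = NULL, seed = NULL) {
  .validate_config(config)
  params <- .config_params(config)
  run <- config$run
  steps <- steps %||% run$steps
  seed <- seed %||% run$seed
  sem <- config$switching$semantics %||% "per-step"
  if (sem == "per-step") {
    ppair <- probability_pair(.resolve_fun(config$switching$p0, "prob"))
    simulate_ifs_process(params, ppair, init = run$init,
                         gene = run$gene %||% 1L, n_steps = steps,
                         seed = seed)
  } else {
    if (!inherits(params, "kinetic_params"))
      stop("intensity switching requires kinetic parameters", call. = FALSE)
    q0 <- .resolve_fun(config$switching$q0, "intensity")
    q1 <- if (is.null(config$switching$q1)) q0
          else .resolve_fun(config$switching$q1, "intensity")
    qpair <- intensity_pair(q0, q1, params = params)
    simulate_jump_process(params, qpair, init = run$init,
                          gene = run$gene %||% 1L, horizon = steps,
                          seed = seed)
  }
}
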