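# Seedable Langevin dynamics over pluggable systems. The integrator is the
# BAOAB splitting: deterministic force half-kicks and drifts around an exact
# Ornstein-Uhlenbeck velocity update, which samples configurations accurately
# at practical timesteps and reduces to velocity Verlet at zero friction.

#' Langevin integration parameters
#'
#' @param n_steps number of integration steps.
#' @param seed RNG seed; recorded in all outputs.
#' @param temperature temperature in K (default 300); ignored if `kT` given.
#' @param kT thermal energy in kcal/mol, overrides `temperature`.
#' @param friction friction coefficient in ps^-1.
#' @param timestep integration timestep in ps.
#' @param mass particle mass (scalar or per-coordinate), in units making
#'   `force/mass` an acceleration in A/ps^2.
#' @param stride recording stride (steps between stored samples).
#' @return object of class `langevin_params`.
#' @export
langevin_params <- function(n_steps, seed, temperature = 300, kT = NULL,
                            friction = 5, timestep = 0.002, mass = 1,
                            stride = 1L) {
  kT <- kT %||% kT_kcal(temperature)
  if (kT < 0 || friction <= 0 || timestep <= 0 || n_steps < 0)
    stopf("kT must be >= 0; friction, timestep positive; n_steps >= 0")
  structure(list(n_steps = as.integer(n_steps), seed = as.integer(seed),
                 kT = kT, friction = friction, timestep = timestep,
                 mass = mass, stride = as.integer(stride)),
            class = "langevin_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Run Langevin dynamics under a set of biases
#'
#' Integrates the system with the BAOAB scheme under the summed system and
#' bias forces, recording the trajectory and a time series of every biased
#' collective variable and the total bias energy at the given stride. Output
#' is bit-identical for identical `(system, biases, params, x0)`.
#'
#' @param system a `potential_surface` or `charged_cluster`.
#' @param biases list of [bias_spec()] objects (may be empty).
#' @param params a [langevin_params()].
#' @param x0 starting configuration (default [sys_start()]).
#' @param observe optional named list of extra `collective_variable`s to
#'   record.
#' @return object of class `langevin_trajectory`: list with `configurations`
#'   (matrix, one recorded configuration per row, step 0 included), `series`
#'   (data.frame: `step`, `time`, one column per biased CV and observer,
#'   `bias_energy`), `final` configuration, and the `params`/`seed` used.
#' @export
langevin_run <- function(system, biases = list(), params, x0 = NULL,
                         observe = list()) {
  x <- as.numeric(x0 %||% sys_start(system))
  dim <- sys_dim(system)
  if (length(x) != dim) stopf("x0 has length %d, system dimension is %d", length(x), dim)
  dt <- params$timestep
  gamma <- params$friction
  kT <- params$kT
  m <- rep(params$mass, length.out = dim)
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(kT * (1 - c1^2))
  cv_names <- vapply(biases, function(b) b$cv$label, character(1))
  cv_names <- make.unique(c(cv_names, names(observe)), sep = "_")
  n_cv <- length(cv_names)
  n_rec <- params$n_steps %/% params$stride + 1L
  conf <- matrix(NA_real_, n_rec, dim)
  series <- matrix(NA_real_, n_rec, n_cv + 1L)
  steps_rec <- integer(n_rec)

  # pre-extracted accessors keep the per-step loop lean
  n_bias <- length(biases)
  bias_eval <- lapply(biases, function(b) b$cv$eval)
  obs_eval <- lapply(observe, function(ob) ob$eval)
  grad_fn <- if (inherits(system, "potential_surface")) system$gradient else
    function(x) sys_gradient(system, x)
  eval_all <- function(x, t) {
    g <- grad_fn(x)
    if (!all(is.finite(g))) return(NULL)
    force <- -g
    vals <- numeric(n_cv)
    ub <- 0
    for (k in seq_len(n_bias)) {
      ev <- bias_eval[[k]](system, x)
      vals[k] <- ev$value
      b <- biases[[k]]
      ub <- ub + bias_energy_value(b, ev$value, t)
      force <- force - bias_dudcv(b, ev$value, t) * ev$gradient
    }
    for (k in seq_along(obs_eval))
      vals[n_bias + k] <- obs_eval[[k]](system, x)$value
    list(force = force, vals = vals, bias_energy = ub)
  }

  with_seed(params$seed, {
    v <- if (kT > 0) stats::rnorm(dim, sd = sqrt(kT / m)) else numeric(dim)
    ev <- eval_all(x, 0)
    if (is.null(ev)) stopf("non-finite force at step 0")
    rec <- 1L
    conf[rec, ] <- x
    series[rec, ] <- c(ev$vals, ev$bias_energy)
    steps_rec[rec] <- 0L
    for (step in seq_len(params$n_steps)) {
      t_next <- step * dt
      v <- v + 0.5 * dt * ev$force / m
      x <- x + 0.5 * dt * v
      if (kT > 0) {
        v <- c1 * v + (c2 / sqrt(m)) * stats::rnorm(dim)
      } else {
        v <- c1 * v
      }
      x <- x + 0.5 * dt * v
      ev <- eval_all(x, t_next)
      if (is.null(ev) || !all(is.finite(x)))
        stopf("integration blow-up at step %d", step)
      v <- v + 0.5 * dt * ev$force / m
      if (step %% params$stride == 0L) {
        rec <- rec + 1L
        conf[rec, ] <- x
        series[rec, ] <- c(ev$vals, ev$bias_energy)
        steps_rec[rec] <- step
      }
    }
  })
  series <- as.data.frame(series)
  names(series) <- c(cv_names, "bias_energy")
  series <- cbind(step = steps_rec, time = steps_rec * dt, series)
  structure(list(configurations = conf, series = series,
                 final = as.numeric(conf[nrow(conf), ]),
                 cv_names = cv_names, params = params, seed = params$seed),
            class = "langevin_trajectory")
}

#' @export
print.langevin_trajectory <- function(x, ...) {
  cat(sprintf("<langevin_trajectory> %d steps (%d recorded), dim %d, seed %d\n",
              x$params$n_steps, nrow(x$configurations),
              ncol(x$configurations), x$seed))
  invisible(x)
}

#' Write a CV time series as TSV
#'
#' Columns: step, time, one column per CV, bias energy.
#' @param run a `langevin_trajectory`; `path` output file.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv_series <- function(run, path) {
  utils::write.table(run$series, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Trajectory frames of a run
#'
#' @param run a `langevin_trajectory`; `system` the system it was run on.
#' @param system the owning system.
#' @return list of [frame()]s, one per recorded configuration.
#' @export
trajectory_frames <- function(run, system) {
  lapply(seq_len(nrow(run$configurations)), function(i)
    sys_frame(system, run$configurations[i, ]))
}
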