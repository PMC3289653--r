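# Collective variables as biasable quantities and the restraint forms used
# in steered and umbrella simulations: static harmonic, moving harmonic, and
# a one-sided quartic upper wall.

#' Collective variables
#'
#' Constructors for the biasable quantities:
#' * `cv_coordinate(index)` — one raw free coordinate of the system;
#' * `cv_distance(i, j)` — interparticle distance (A) on a charged cluster;
#' * `cv_s(path)` / `cv_z(path)` — the path variables over a
#'   [reference_path()]. S/Z pairs built from `pcv_pair()` share one
#'   evaluation cache so biasing both costs one path scan per step.
#'
#' @param index free-coordinate index (1-based).
#' @param i,j particle indices on the owning cluster.
#' @param path a `reference_path`.
#' @param label optional display label.
#' @return object of class `collective_variable` with fields `kind`, `label`
#'   and an `eval(system, x)` function returning `list(value, gradient)` in
#'   free-coordinate layout.
#' @name collective_variable
NULL

new_cv <- function(kind, label, eval_fn, extra = list()) {
  structure(c(list(kind = kind, label = label, eval = eval_fn), extra),
            class = "collective_variable")
}

#' @export
print.collective_variable <- function(x, ...) {
  cat(sprintf("<collective_variable> %s (%s)\n", x$label, x$kind))
  invisible(x)
}

#' @rdname collective_variable
#' @export
cv_coordinate <- function(index, label = sprintf("x%d", index)) {
  index <- as.integer(index)
  new_cv("raw-coordinate", label, function(system, x) {
    g <- numeric(length(x))
    g[index] <- 1
    list(value = x[index], gradient = g)
  })
}

#' @rdname collective_variable
#' @export
cv_distance <- function(i, j, label = sprintf("d(%d,%d)", i, j)) {
  i <- as.integer(i); j <- as.integer(j)
  new_cv("interparticle-distance", label, function(system, x) {
    pos <- cluster_positions(system, x)
    dvec <- pos[i, ] - pos[j, ]
    r <- sqrt(sum(dvec^2))
    if (r == 0) stopf("degenerate distance CV: coincident particles")
    gfull <- matrix(0, nrow(pos), 3L)
    gfull[i, ] <- dvec / r
    gfull[j, ] <- -dvec / r
    list(value = r,
         gradient = as.numeric(t(gfull[!system$fixed, , drop = FALSE])))
  })
}

# Convert a gradient over frame coordinates (column-major, all points) into
# free-coordinate layout for the owning system.
frame_grad_to_free <- function(system, g) {
  if (inherits(system, "potential_surface")) return(as.numeric(g))
  n <- length(system$charges)
  mobile <- which(!system$fixed)
  out <- numeric(3L * length(mobile))
  for (m in seq_along(mobile)) {
    i <- mobile[m]
    out[(3L * (m - 1L) + 1L):(3L * m)] <- g[c(i, i + n, i + 2L * n)]
  }
  out
}

#' @rdname collective_variable
#' @export
pcv_pair <- function(path) {
  cache <- new.env(parent = emptyenv())
  cache$x <- NULL
  fast <- nrow(path$frames[[1L]]$coords) == 1L
  shared_eval <- function(system, x) {
    if (!is.null(cache$x) && length(cache$x) == length(x) &&
        all(cache$x == x)) return(cache$res)
    res <- if (fast && inherits(system, "potential_surface"))
      pcv_eval_vec(path, x) else pcv_eval(path, sys_frame(system, x))
    cache$x <- x
    cache$res <- res
    res
  }
  list(
    s = new_cv("pcv-S", "S", function(system, x) {
      r <- shared_eval(system, x)
      list(value = r$s, gradient = frame_grad_to_free(system, r$ds))
    }, extra = list(path = path)),
    z = new_cv("pcv-Z", "Z", function(system, x) {
      r <- shared_eval(system, x)
      list(value = r$z, gradient = frame_grad_to_free(system, r$dz))
    }, extra = list(path = path)))
}

#' @rdname collective_variable
#' @export
cv_s <- function(path, label = "S") pcv_pair(path)$s

#' @rdname collective_variable
#' @export
cv_z <- function(path, label = "Z") pcv_pair(path)$z

#' Evaluate a collective variable
#'
#' @param cv a `collective_variable`.
#' @param system the owning system.
#' @param x free-coordinate configuration vector.
#' @return scalar value (`cv_value`) or gradient vector (`cv_gradient_vec`).
#' @export
cv_value <- function(cv, system, x) cv$eval(system, x)$value

#' @rdname cv_value
#' @export
cv_gradient_vec <- function(cv, system, x) cv$eval(system, x)$gradient

# ---- bias specifications ---------------------------------------------------

#' Define a bias restraint on a collective variable
#'
#' Three forms, with the half-k harmonic convention so quoted force constants
#' map directly onto `k`:
#' * `"harmonic"`: `U = k/2 (cv - center)^2`;
#' * `"moving-harmonic"`: the same with a time-dependent center
#'   `c(t) = from + rate * t`, clamped at `to`;
#' * `"quartic-wall"`: one-sided upper wall `U = k (cv - limit)^4` for
#'   `cv > limit`, exactly 0 below it.
#'
#' @param cv a `collective_variable`.
#' @param form restraint form.
#' @param k force constant (kcal/mol per cv-unit^2 for harmonic forms, per
#'   cv-unit^4 for the wall); non-negative.
#' @param center static harmonic center.
#' @param from,to,rate moving-harmonic schedule: the center moves from `from`
#'   toward `to` at `rate` cv-units per ps (sign inferred).
#' @param limit quartic-wall upper limit.
#' @return object of class `bias_spec`.
#' @export
bias_spec <- function(cv, form = c("harmonic", "moving-harmonic", "quartic-wall"),
                      k, center = NULL, from = NULL, to = NULL, rate = NULL,
                      limit = NULL) {
  form <- match.arg(form)
  if (k < 0) stopf("force constant must be non-negative")
  spec <- list(cv = cv, form = form, k = as.numeric(k))
  if (form == "harmonic") {
    if (is.null(center)) stopf("harmonic bias needs a center")
    spec$center <- as.numeric(center)
  } else if (form == "moving-harmonic") {
    if (is.null(from) || is.null(to) || is.null(rate))
      stopf("moving-harmonic bias needs from, to and rate")
    if (rate <= 0) stopf("pull rate must be positive")
    spec$from <- as.numeric(from); spec$to <- as.numeric(to)
    spec$rate <- as.numeric(rate)
    spec$duration <- abs(to - from) / rate
  } else {
    if (is.null(limit)) stopf("quartic wall needs a limit")
    spec$limit <- as.numeric(limit)
  }
  structure(spec, class = "bias_spec")
}

#' @export
print.bias_spec <- function(x, ...) {
  desc <- switch(x$form,
    "harmonic" = sprintf("center %.4g", x$center),
    "moving-harmonic" = sprintf("%.4g -> %.4g at %.4g /ps", x$from, x$to, x$rate),
    "quartic-wall" = sprintf("limit %.4g", x$limit))
  cat(sprintf("<bias_spec> %s on %s, k = %.4g, %s\n",
              x$form, x$cv$label, x$k, desc))
  invisible(x)
}

# Instantaneous center of a (possibly moving) harmonic at time t (ps).
bias_center <- function(spec, t) {
  switch(spec$form,
    "harmonic" = spec$center,
    "moving-harmonic" = {
      s <- sign(spec$to - spec$from)
      c0 <- spec$from + s * spec$rate * t
      if (s >= 0) min(c0, spec$to) else max(c0, spec$to)
    },
    stopf("bias form '%s' has no center", spec$form))
}

#' Bias energy and force at a configuration
#'
#' @param spec a [bias_spec()].
#' @param system the owning system.
#' @param x configuration vector.
#' @param t simulation time in ps (matters for moving restraints).
#' @return `bias_energy`: energy in kcal/mol (always >= 0; a wall whose CV is
#'   below the limit contributes exactly 0). `bias_force`: the force vector
#'   `-(dU/dcv) * grad(cv)` in free-coordinate layout.
#' @export
bias_energy <- function(spec, system, x, t = 0) {
  v <- cv_value(spec$cv, system, x)
  bias_energy_value(spec, v, t)
}

# energy as a function of the cv value alone (used by WHAM on grids)
bias_energy_value <- function(spec, v, t = 0) {
  switch(spec$form,
    "harmonic" = 0.5 * spec$k * (v - spec$center)^2,
    "moving-harmonic" = 0.5 * spec$k * (v - bias_center(spec, t))^2,
    "quartic-wall" = if (v > spec$limit) spec$k * (v - spec$limit)^4 else 0)
}

# dU/dcv at cv value v
bias_dudcv <- function(spec, v, t = 0) {
  switch(spec$form,
    "harmonic" = spec$k * (v - spec$center),
    "moving-harmonic" = spec$k * (v - bias_center(spec, t)),
    "quartic-wall" = if (v > spec$limit) 4 * spec$k * (v - spec$limit)^3 else 0)
}

#' @rdname bias_energy
#' @export
bias_force <- function(spec, system, x, t = 0) {
  ev <- spec$cv$eval(system, x)
  -bias_dudcv(spec, ev$value, t) * ev$gradient
}

#' Accumulated external work of a moving restraint
#'
#' For a moving harmonic, the external work is
#' `W(t) = integral (dU/dc) (dc/dt') dt'` with
#' `dU/dc = -k (cv - c)`, accumulated by the trapezoid rule at the sampling
#' stride. A static schedule gives identically zero work; for a stiff, slow
#' pull the final work converges from above to the free-energy difference.
#'
#' @param spec a moving-harmonic [bias_spec()].
#' @param times sampling times (ps), strictly increasing.
#' @param cv_values CV samples at those times.
#' @return data.frame with `time`, `center`, `cv`, `work` (kcal/mol,
#'   `work[1] = 0`).
#' @export
accumulate_work <- function(spec, times, cv_values) {
  if (spec$form != "moving-harmonic")
    stopf("work accounting requires a moving-harmonic bias")
  if (length(times) != length(cv_values)) stopf("times and cv_values differ in length")
  if (any(diff(times) <= 0)) stopf("time stamps must be strictly increasing")
  centers <- vapply(times, function(t) bias_center(spec, t), numeric(1))
  # dU/dc = -k (cv - c); integrate against dc/dt
  integrand <- -spec$k * (cv_values - centers)
  dc <- diff(centers)
  incr <- 0.5 * (integrand[-1] + integrand[-length(integrand)]) * dc
  data.frame(time = times, center = centers, cv = cv_values,
             work = c(0, cumsum(incr)))
}
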