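# Composite procedures: guess-path generation by sequential steering on
# simple reaction coordinates, steering along S under a quartic Z wall,
# iterative path refinement, and umbrella-sampling campaigns.

# Deterministic child seed for stage/window w of a campaign seeded with seed.
child_seed <- function(seed, w) {
  as.integer((as.numeric(seed) %% 2147483647) * 7919 + w * 104729) %% 2147483647L
}

#' Generate a guess reaction path by sequential steering
#'
#' Divides a reaction into consecutive stages, each pulling one simple
#' reaction coordinate from its current value to a target with a moving
#' harmonic restraint, starting every stage from the previous stage's final
#' configuration. The concatenated trajectory is the guess path later handed
#' to [reparameterize()] and [optimize_path()].
#'
#' @param system the system to steer.
#' @param stages list of stages, each a list with `cv` (a
#'   `collective_variable`), `target`, `k` (kcal/mol per cv-unit^2) and
#'   `duration` (ps).
#' @param params a [langevin_params()] supplying kT, friction, timestep and
#'   the campaign seed; its `n_steps` is ignored (each stage's duration sets
#'   its step count).
#' @param x0 starting configuration.
#' @param hold if `TRUE` (default) every completed stage keeps a static
#'   harmonic at its target while later stages run, so sequential targets are
#'   reached jointly rather than traded off.
#' @return object of class `guess_path_run`: `configurations` (matrix),
#'   `series` (stacked CV series with a `stage` column), `stage_bounds`
#'   (first row index of each stage), `final`.
#' @export
generate_guess_path <- function(system, stages, params, x0 = NULL, hold = TRUE) {
  x <- as.numeric(x0 %||% sys_start(system))
  conf_all <- NULL
  series_all <- NULL
  bounds <- integer(0)
  holds <- list()
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    if (!is.finite(st$target)) stopf("stage %d target must be finite", si)
    v0 <- cv_value(st$cv, system, x)
    dur <- st$duration
    n_steps <- max(1L, ceiling(dur / params$timestep))
    rate <- max(abs(st$target - v0), 1e-12) / dur
    spec <- bias_spec(st$cv, "moving-harmonic", k = st$k,
                      from = v0, to = st$target, rate = rate)
    p <- params
    p$n_steps <- n_steps
    p$seed <- child_seed(params$seed, si)
    run <- tryCatch(langevin_run(system, c(list(spec), holds), p, x0 = x),
                    error = function(e) stopf("stage %d: %s", si, conditionMessage(e)))
    if (hold)
      holds <- c(holds, list(bias_spec(st$cv, "harmonic", k = st$k,
                                       center = st$target)))
    x <- run$final
    sr <- run$series
    names(sr)[3L] <- st$cv$label
    sr$stage <- si
    bounds <- c(bounds, (if (is.null(conf_all)) 0L else nrow(conf_all)) + 1L)
    conf_all <- rbind(conf_all, run$configurations)
    keep <- c("step", "time", st$cv$label, "bias_energy", "stage")
    series_all <- c(series_all, list(sr[keep]))
  }
  structure(list(configurations = conf_all, series = series_all,
                 stage_bounds = bounds, final = x, seed = params$seed),
            class = "guess_path_run")
}

#' Steer a system along a reference path
#'
#' Applies a moving harmonic on the path progress variable S, pulled from 1
#' (reactants) to N (products) at a fixed speed, while a one-sided quartic
#' wall on Z keeps the system near the reactive tube yet free to relax. The
#' external work is accumulated along the pull.
#'
#' @param system system comparable with the path frames.
#' @param path a [reference_path()].
#' @param params a [langevin_params()]; `n_steps` is derived from the pull
#'   duration `(N-1)/speed`.
#' @param k_s force constant on S, kcal/mol per S-unit^2 (default 300).
#' @param speed pull speed in S-units per ps (default 0.5).
#' @param z_limit,z_k quartic upper wall on Z: limit in A^2 (default 0.005)
#'   and constant in kcal/mol A^-8 (default 200).
#' @param x0 starting configuration (defaults to the first path frame's
#'   coordinates for analytic surfaces).
#' @return object of class `steer_result`: the `run`, a `work` data.frame
#'   (`time`, `center`, `cv`, `work`), `s`, `z` series and a [work_profile()].
#' @export
steer_along_path <- function(system, path, params, k_s = 300, speed = 0.5,
                             z_limit = 0.005, z_k = 200, x0 = NULL) {
  N <- path_n(path)
  pair <- pcv_pair(path)
  if (is.null(x0)) {
    x0 <- if (inherits(system, "potential_surface"))
      as.numeric(path$frames[[1L]]$coords) else sys_start(system)
  }
  pull <- bias_spec(pair$s, "moving-harmonic", k = k_s, from = 1, to = N,
                    rate = speed)
  wall <- bias_spec(pair$z, "quartic-wall", k = z_k, limit = z_limit)
  p <- params
  p$n_steps <- ceiling((N - 1) / speed / params$timestep)
  run <- langevin_run(system, list(pull, wall), p, x0 = x0)
  w <- accumulate_work(pull, run$series$time, run$series$S)
  sigma <- sqrt(max(p$kT, 1e-12) / k_s)
  final_s <- run$series$S[nrow(run$series)]
  if (abs(final_s - N) > 3 * sigma + 0.2)
    warning(sprintf("final S = %.3f did not reach the path end N = %d", final_s, N),
            call. = FALSE)
  structure(list(run = run, work = w,
                 s = run$series$S, z = run$series$Z,
                 profile = work_profile(s = run$series$S, work = w$work,
                                        speed = speed, seed = p$seed),
                 k_s = k_s, speed = speed, path = path),
            class = "steer_result")
}

#' Iteratively refine a reaction path by steered runs
#'
#' Loop: reparameterize the current trajectory into N equally spaced frames,
#' steer the system along the resulting path variables, and extract the new
#' trajectory, until the mean frame-wise difference between successive paths
#' drops below `tolerance` or `max_iterations` is reached. Non-convergence is
#' a flagged result (with the full difference series), not an error.
#'
#' @param system the system.
#' @param guess_trajectory list of frames (or a `guess_path_run`) connecting
#'   the reactant to the product basin.
#' @param N number of path frames.
#' @param params a [langevin_params()] (per-iteration seeds derive from its
#'   seed).
#' @param tolerance convergence threshold on [path_difference()] (coordinate
#'   units).
#' @param max_iterations refinement cap.
#' @param min_iterations iterations to run before the stopping rule may
#'   trigger (default 1). Channel discovery is stochastic: a path in the
#'   higher channel is locally self-consistent, so a floor of a few
#'   iterations gives the replicate steers enough attempts to find the
#'   competing channel before convergence is declared.
#' @param metric msd metric for the paths.
#' @param lambda optional fixed smoothing parameter (default: re-chosen per
#'   iteration by [choose_lambda()]).
#' @param lambda_scale multiplier applied to the automatically chosen lambda
#'   each iteration (robustness studies); ignored when `lambda` is given.
#' @param relax update damping: the new path is `relax * extracted +
#'   (1 - relax) * previous` frame-wise before respacing (1 = undamped).
#'   Damping suppresses the trajectory-to-trajectory noise of single
#'   stochastic steers while leaving the drift toward the preferred channel
#'   intact.
#' @param steers_per_iteration independent replicate steers per iteration.
#'   The replicate with the lowest work barrier defines the route (the
#'   lowest-work route is the best current estimate of the minimum
#'   free-energy channel); replicates whose work barriers lie within
#'   `work_window` of it are treated as the same channel and their extracted
#'   paths averaged frame-wise, which cuts the stochastic path noise without
#'   ever averaging across competing channels.
#' @param work_window work-barrier window (kcal/mol) within which replicate
#'   steers count as the same route (default 2).
#' @param basins optional endpoint check: list with `reactant`, `product`
#'   (configuration vectors) and `radius`; the guess trajectory must start
#'   and end within `radius` of them.
#' @param ... passed to [steer_along_path()] (`k_s`, `speed`, `z_limit`, `z_k`).
#' @return object of class `path_refinement`: `paths` (all iterates),
#'   `differences`, `converged`, `steers`, `final` (the last path).
#' @export
optimize_path <- function(system, guess_trajectory, N, params,
                          tolerance = 0.05, max_iterations = 6L,
                          min_iterations = 1L,
                          metric = "plain", lambda = NULL, lambda_scale = 1,
                          relax = 1, steers_per_iteration = 1L,
                          work_window = 2, basins = NULL, ...) {
  traj <- if (inherits(guess_trajectory, "guess_path_run")) {
    lapply(seq_len(nrow(guess_trajectory$configurations)), function(i)
      sys_frame(system, guess_trajectory$configurations[i, ]))
  } else guess_trajectory
  if (!is.null(basins)) {
    ends <- list(traj[[1L]], traj[[length(traj)]])
    tg <- list(basins$reactant, basins$product)
    for (k in 1:2) {
      dd <- sqrt(sum((as.numeric(ends[[k]]$coords) - tg[[k]])^2))
      if (dd > basins$radius)
        stopf("guess trajectory endpoint %d is %.3f from its basin (radius %.3f)",
              k, dd, basins$radius)
    }
  }
  paths <- list()
  steers <- list()
  diffs <- numeric(0)
  prev <- NULL
  converged <- FALSE
  extract_path <- function(frames, it) {
    reparameterize(frames, N, metric = metric, lambda = lambda,
                   provenance = list(iteration = it), smooth = "auto")
  }
  for (it in seq_len(max_iterations)) {
    path <- extract_path(traj, it)
    if (!is.null(prev) && relax < 1) {
      blended <- lapply(seq_len(N), function(i)
        frame(relax * path$frames[[i]]$coords +
                (1 - relax) * prev$frames[[i]]$coords,
              labels = path$frames[[i]]$labels,
              weights = path$frames[[i]]$weights))
      path <- reparameterize(blended, N, metric = metric, lambda = lambda,
                             provenance = list(iteration = it))
    }
    if (is.null(lambda) && lambda_scale != 1)
      path$lambda <- path$lambda * lambda_scale
    paths[[it]] <- path
    if (!is.null(prev)) {
      diffs[it - 1L] <- path_difference(prev, path)
      if (diffs[it - 1L] < tolerance && it > min_iterations) {
        converged <- TRUE
        break
      }
    }
    its <- lapply(seq_len(steers_per_iteration), function(r) {
      p <- params
      p$seed <- child_seed(params$seed, (it - 1L) * steers_per_iteration + r)
      steer_along_path(system, path, p, ...)
    })
    wb <- vapply(its, function(st) work_barrier(st$profile)$barrier,
                 numeric(1))
    same_route <- which(wb - min(wb) <= work_window)
    steers[[it]] <- if (steers_per_iteration == 1L) its[[1L]] else its
    if (length(same_route) == 1L) {
      traj <- trajectory_frames(its[[same_route]]$run, system)
    } else {
      cands <- lapply(same_route, function(r)
        extract_path(trajectory_frames(its[[r]]$run, system), it))
      f1 <- cands[[1L]]$frames[[1L]]
      traj <- lapply(seq_len(N), function(i)
        frame(Reduce(`+`, lapply(cands, function(p) p$frames[[i]]$coords)) /
                length(cands),
              labels = f1$labels, weights = f1$weights))
    }
    prev <- path
  }
  structure(list(paths = paths, differences = diffs, converged = converged,
                 steers = steers, final = paths[[length(paths)]],
                 iterations = length(paths)),
            class = "path_refinement")
}

#' @export
print.path_refinement <- function(x, ...) {
  cat(sprintf("<path_refinement> %d iteration(s), %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$differences))
    cat("  successive path differences:",
        paste(sprintf("%.4g", x$differences), collapse = ", "), "\n")
  invisible(x)
}

#' Zero-point-charge mutant scan by steered pulls
#'
#' Pulls the fixture's mobile particle along its reaction coordinate with a
#' stiff moving harmonic, for the wild type and every requested zero-point-
#' charge mutant, with `replicates` independent seeds each, and tabulates the
#' work barriers and their shifts versus wild type.
#'
#' @param fixture result of [make_mutant_cluster()] (or a compatible list).
#' @param params a [langevin_params()] template; per-run seeds derive from
#'   its seed.
#' @param speed pull speed in A/ps.
#' @param k pull force constant, kcal/mol/A^2 (default 300).
#' @param replicates independent pulls per system.
#' @param mutants site names to scan (default: all fixture sites).
#' @return list with `profiles` (all [work_profile()]s), `table` (the
#'   [compare_mutant_barriers()] output) and `oracle_deltas` from the
#'   fixture.
#' @export
mutant_scan <- function(fixture, params, speed = 0.2, k = 300,
                        replicates = 3L, mutants = NULL) {
  mutants <- mutants %||% fixture$mutants
  systems <- c(list(wt = fixture$system),
               stats::setNames(lapply(mutants, function(m)
                 zero_point_charge_mutant(fixture$system, m)), mutants))
  duration <- abs(fixture$pull_to - fixture$pull_from) / speed
  n_steps <- ceiling(duration / params$timestep)
  profiles <- list()
  run_id <- 0L
  for (lbl in names(systems)) {
    for (rep in seq_len(replicates)) {
      run_id <- run_id + 1L
      spec <- bias_spec(fixture$pull_cv, "moving-harmonic", k = k,
                        from = fixture$pull_from, to = fixture$pull_to,
                        rate = speed)
      p <- params
      p$n_steps <- n_steps
      p$seed <- child_seed(params$seed, run_id)
      run <- langevin_run(systems[[lbl]], list(spec), p)
      w <- accumulate_work(spec, run$series$time, run$series$xB)
      profiles[[run_id]] <- work_profile(
        s = fixture$pull_from - w$center, work = w$work,
        speed = speed, seed = p$seed, label = lbl)
    }
  }
  list(profiles = profiles,
       table = compare_mutant_barriers(profiles, reference = "wt"),
       oracle_deltas = fixture$oracle$deltas)
}

# ---- umbrella sampling -----------------------------------------------------

#' Declare an umbrella-sampling campaign
#'
#' @param cv the windowed `collective_variable`.
#' @param centers strictly monotone window centers.
#' @param k harmonic force constant per window (kcal/mol per cv-unit^2).
#' @param steps_per_window integration steps in each window.
#' @param discard fraction of each window's samples discarded as
#'   equilibration, in \[0, 1) (default 0.5).
#' @param chained if `TRUE` (default) each window starts from the previous
#'   window's final configuration.
#' @param seed campaign seed; per-window seeds derive from `(seed, window)`.
#' @param extra_biases list of additional static [bias_spec()]s applied in
#'   every window (e.g. the harmonic Z restraint of a 2D path campaign).
#' @param stride recording stride within windows.
#' @param x0 starting configuration for the first window.
#' @return object of class `umbrella_campaign`.
#' @export
umbrella_campaign <- function(cv, centers, k, steps_per_window, seed,
                              discard = 0.5, chained = TRUE,
                              extra_biases = list(), stride = 1L, x0 = NULL) {
  centers <- as.numeric(centers)
  if (length(centers) < 2L) stopf("need at least 2 windows for reconstruction")
  dc <- diff(centers)
  if (!(all(dc > 0) || all(dc < 0))) stopf("window centers must be strictly monotone")
  if (discard < 0 || discard >= 1) stopf("discard fraction must be in [0, 1)")
  structure(list(cv = cv, centers = centers, k = k,
                 steps_per_window = as.integer(steps_per_window),
                 discard = discard, chained = chained,
                 seed = as.integer(seed), extra_biases = extra_biases,
                 stride = as.integer(stride), x0 = x0),
            class = "umbrella_campaign")
}

#' Run an umbrella-sampling campaign
#'
#' One biased Langevin run per window; each window's post-discard samples of
#' every biased CV become a `window_dataset` carrying its full bias
#' specification for WHAM.
#'
#' @param system the system.
#' @param campaign an [umbrella_campaign()].
#' @param params a [langevin_params()] template (its `n_steps`/`seed`/`stride`
#'   are overridden per window).
#' @return list of `window_dataset` objects.
#' @export
run_umbrella <- function(system, campaign, params) {
  x <- as.numeric(campaign$x0 %||% sys_start(system))
  out <- vector("list", length(campaign$centers))
  for (w in seq_along(campaign$centers)) {
    bias <- bias_spec(campaign$cv, "harmonic", k = campaign$k,
                      center = campaign$centers[w])
    biases <- c(list(bias), campaign$extra_biases)
    p <- params
    p$n_steps <- campaign$steps_per_window
    p$stride <- campaign$stride
    p$seed <- child_seed(campaign$seed, w)
    run <- tryCatch(langevin_run(system, biases, p, x0 = x),
                    error = function(e)
                      stopf("window %d: %s", w, conditionMessage(e)))
    if (campaign$chained) x <- run$final
    # the step-0 record is the inherited start; only produced samples count
    series <- run$series[-1L, , drop = FALSE]
    n <- nrow(series)
    keep <- seq_len(n) > floor(campaign$discard * n)
    if (!any(keep)) stopf("window %d: no samples survive the discard", w)
    samples <- as.matrix(series[keep, run$cv_names, drop = FALSE])
    rownames(samples) <- NULL
    out[[w]] <- window_dataset(samples = samples, biases = biases,
                               kT = p$kT, seed = p$seed, index = w)
  }
  out
}

#' Construct a window dataset
#'
#' @param samples matrix of post-discard CV samples (columns named by CV).
#' @param biases list of [bias_spec()]s active in the window.
#' @param kT thermal energy, kcal/mol.
#' @param seed RNG seed of the window run.
#' @param index window index within its campaign.
#' @return object of class `window_dataset`.
#' @export
window_dataset <- function(samples, biases, kT, seed = NA_integer_,
                           index = NA_integer_) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stopf("a window dataset needs at least one sample")
  structure(list(samples = samples, biases = biases, kT = kT,
                 seed = seed, index = index),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d samples of (%s), %d bias(es), kT = %.4g\n",
              nrow(x$samples), paste(colnames(x$samples), collapse = ", "),
              length(x$biases), x$kT))
  invisible(x)
}

#' Write/read window datasets
#'
#' Each window becomes `window_<i>.tsv` (samples) plus `window_<i>.json`
#' (bias forms, constants, centers, kT, seed), so WHAM can run as a separate
#' step.
#'
#' @param windows list of `window_dataset`s.
#' @param dir output directory (created if needed).
#' @return the directory (write) or a list of `window_dataset`s (read).
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in seq_along(windows)) {
    wd <- windows[[w]]
    utils::write.table(wd$samples, file.path(dir, sprintf("window_%03d.tsv", w)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meta <- list(kT = wd$kT, seed = wd$seed, index = wd$index,
                 biases = lapply(wd$biases, function(b) {
                   m <- list(form = b$form, k = b$k, cv = b$cv$label)
                   if (!is.null(b$center)) m$center <- b$center
                   if (!is.null(b$limit)) m$limit <- b$limit
                   m
                 }))
    jsonlite::write_json(meta, file.path(dir, sprintf("window_%03d.json", w)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_windows
#' @export
read_windows <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "^window_\\d+\\.tsv$", full.names = TRUE))
  if (!length(tsvs)) stopf("no window files in %s", dir)
  lapply(tsvs, function(tsv) {
    meta <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv), simplifyVector = FALSE)
    samples <- as.matrix(utils::read.table(tsv, sep = "\t", header = TRUE,
                                           check.names = FALSE))
    biases <- lapply(meta$biases, function(m) {
      cv <- new_cv("deserialized", m$cv, function(system, x)
        stopf("deserialized CV '%s' cannot be re-evaluated", m$cv))
      if (m$form == "harmonic")
        bias_spec(cv, "harmonic", k = m$k, center = m$center)
      else if (m$form == "quartic-wall")
        bias_spec(cv, "quartic-wall", k = m$k, limit = m$limit)
      else stopf("cannot deserialize bias form '%s'", m$form)
    })
    window_dataset(samples, biases, kT = meta$kT,
                   seed = meta$seed %||% NA_integer_,
                   index = meta$index %||% NA_integer_)
  })
}
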