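# Simulation systems: pluggable analytic potential-energy surfaces and
# charged clusters. These desk-scale systems stand in for a full molecular
# Hamiltonian while keeping every free energy oracle-verifiable.

#' Define an analytic potential-energy surface
#'
#' @param dim dimensionality of the configuration space.
#' @param energy function of a length-`dim` numeric vector returning energy in
#'   kcal/mol.
#' @param gradient function returning the length-`dim` gradient in kcal/mol
#'   per coordinate unit.
#' @param params named list describing the surface (kept for provenance).
#' @param start default starting configuration.
#' @param name human-readable label.
#' @return object of class `potential_surface`.
#' @export
potential_surface <- function(dim, energy, gradient, params = list(),
                              start = rep(0, dim), name = "surface") {
  stopifnot(is.function(energy), is.function(gradient), dim >= 1L)
  structure(list(dim = as.integer(dim), energy = energy, gradient = gradient,
                 params = params, start = as.numeric(start), name = name),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> '%s', dimension %d\n", x$name, x$dim))
  invisible(x)
}

# ---- generic system interface ----------------------------------------------

#' Number of free coordinates of a system
#' @param system a `potential_surface` or `charged_cluster`.
#' @return integer count of integrated degrees of freedom.
#' @export
sys_dim <- function(system) UseMethod("sys_dim")
#' @export
sys_dim.potential_surface <- function(system) system$dim
#' @export
sys_dim.charged_cluster <- function(system) 3L * sum(!system$fixed)

#' Potential energy of a system at a configuration
#' @param system system object; `x` free-coordinate vector.
#' @param x numeric configuration vector of length `sys_dim(system)`.
#' @return energy in kcal/mol.
#' @export
sys_energy <- function(system, x) UseMethod("sys_energy")
#' @export
sys_energy.potential_surface <- function(system, x) system$energy(x)

#' Gradient of the potential energy
#' @inheritParams sys_energy
#' @return gradient vector, kcal/mol per coordinate unit.
#' @export
sys_gradient <- function(system, x) UseMethod("sys_gradient")
#' @export
sys_gradient.potential_surface <- function(system, x) system$gradient(x)

#' Default starting configuration
#' @param system system object.
#' @return free-coordinate vector.
#' @export
sys_start <- function(system) UseMethod("sys_start")
#' @export
sys_start.potential_surface <- function(system) system$start

#' View a configuration as a frame
#'
#' Analytic surfaces become single-point frames of dimension D (alignment is
#' meaningless and always off for them); charged clusters become one labeled
#' 3D point per particle, with fixed particles at their stored positions.
#'
#' @param system system object; `x` free-coordinate vector.
#' @param x numeric configuration vector.
#' @return a [frame()].
#' @export
sys_frame <- function(system, x) UseMethod("sys_frame")
#' @export
sys_frame.potential_surface <- function(system, x) frame(matrix(x, nrow = 1L))

#' Verify that a system's gradient matches finite differences
#'
#' @param system system object.
#' @param x configuration at which to test (default: the start).
#' @param step central-difference step.
#' @return maximum relative deviation over coordinates (invisible); errors if
#'   above `tol`.
#' @param tol relative tolerance (default 1e-5).
#' @export
check_gradient <- function(system, x = sys_start(system), step = 1e-5, tol = 1e-5) {
  g <- sys_gradient(system, x)
  fd <- vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + step; xm[i] <- xm[i] - step
    (sys_energy(system, xp) - sys_energy(system, xm)) / (2 * step)
  }, numeric(1))
  scale <- max(abs(g), abs(fd), 1e-8)
  rel <- max(abs(g - fd)) / scale
  if (rel > tol) stopf("gradient check failed: relative deviation %.3g", rel)
  invisible(rel)
}

# ---- double well -----------------------------------------------------------

#' Quartic double-well surface with exact analytic landmarks
#'
#' `V(x) = h (u^2-1)^2 + (tilt/4)(3u - u^3) + tilt/2` with `u = x/a`,
#' `a = separation/2`. The cubic tilt term keeps the stationary points at
#' exactly `x = -a, x_ts, +a`, so the minima, the barrier top and both barrier
#' heights are closed-form. In one dimension the free energy along x equals
#' V(x) up to an additive constant, which makes this the reference fixture for
#' umbrella sampling + WHAM (it emulates a two-state proton-transfer profile).
#'
#' @param barrier barrier height h of the untilted well, kcal/mol (> 0).
#' @param separation distance between the two minima (default 0.7, matching a
#'   proton-transfer-scale coordinate in Angstrom).
#' @param tilt energy offset of the right minimum relative to the left,
#'   kcal/mol; must satisfy `|3*tilt/(16*barrier)| < 1` so both wells survive.
#' @return a `potential_surface` whose `$analytic` entry records minima,
#'   transition-state position and forward/reverse barriers.
#' @examples
#' dw <- make_double_well(barrier = 3, separation = 0.7, tilt = 1)
#' dw$analytic$barrier_forward
#' @export
make_double_well <- function(barrier, separation = 0.7, tilt = 0) {
  if (barrier <= 0) stopf("barrier must be positive")
  a <- separation / 2
  if (a <= 0) stopf("separation must be positive")
  u_ts <- 3 * tilt / (16 * barrier)
  if (abs(u_ts) >= 1) stopf("tilt too large: wells merge")
  V <- function(x) {
    u <- x / a
    barrier * (u^2 - 1)^2 + (tilt / 4) * (3 * u - u^3) + tilt / 2
  }
  G <- function(x) {
    u <- x / a
    (1 / a) * (4 * barrier * u * (u^2 - 1) - (3 * tilt / 4) * (u^2 - 1))
  }
  e_min_left <- V(-a); e_min_right <- V(a); e_ts <- V(a * u_ts)
  surf <- potential_surface(
    dim = 1L, energy = function(x) V(x[1]), gradient = function(x) G(x[1]),
    params = list(barrier = barrier, separation = separation, tilt = tilt),
    start = -a, name = "double_well")
  surf$analytic <- list(
    x_min = c(-a, a), x_ts = a * u_ts,
    e_min = c(e_min_left, e_min_right), e_ts = e_ts,
    barrier_forward = e_ts - e_min_left,
    barrier_reverse = e_ts - e_min_right,
    delta = e_min_right - e_min_left,
    potential = V)
  surf
}

# ---- two-channel reactive surface ------------------------------------------

#' Two-channel 2D reactive surface with a grid-search oracle
#'
#' A 2D surface over an attack coordinate x and a proton coordinate y built
#' from Gaussian wells at the reactant and product basins, a Gaussian ridge
#' along the barrier line `x + y = 1`, and two Gaussian "gates" lowering the
#' ridge: one concerted (near the diagonal, attack and protonation together)
#' and one stepwise (attack leading). It emulates the mechanistic competition
#' between a stepwise and a concerted nucleophilic-attack/proton-transfer
#' channel. Construction runs a dense-grid minimax search and attaches an
#' oracle report: basin minima, both channel saddles (energies relative to the
#' reactant minimum) and a channel classifier.
#'
#' @param spec named list overriding defaults: `reactant`, `product` (basin
#'   centers), `well_depth`, `well_sigma`, `ridge_height`, `ridge_sigma`,
#'   `gate_concerted`/`gate_stepwise` (lists with `center`, `depth`, `sigma`),
#'   `confine_k` (quartic confinement, kcal/mol per unit^4),
#'   `channel_halfwidth` (|x - y| cut separating channels at the ridge),
#'   `grid_n` (oracle grid resolution), `require_concerted_lower`.
#' @return a `potential_surface` with an `$oracle` report.
#' @export
make_two_channel_surface <- function(spec = list()) {
  d <- list(
    reactant = c(0, 0), product = c(1, 1),
    well_depth = 8, well_sigma = 0.2,
    ridge_height = 12, ridge_sigma = 0.12,
    gate_concerted = list(center = c(0.5, 0.5), depth = 9, sigma = 0.16),
    gate_stepwise = list(center = c(0.78, 0.22), depth = 4.5, sigma = 0.12),
    confine_k = 25, channel_halfwidth = 0.3,
    grid_n = 161L, require_concerted_lower = TRUE)
  d[names(spec)] <- spec
  gauss <- function(p, c0, sig) exp(-sum((p - c0)^2) / (2 * sig^2))
  V1 <- function(p) {
    ctr <- (d$reactant + d$product) / 2
    d$confine_k * sum((p - ctr)^4) -
      d$well_depth * (gauss(p, d$reactant, d$well_sigma) +
                      gauss(p, d$product, d$well_sigma)) +
      d$ridge_height * exp(-(p[1] + p[2] - 1)^2 / (2 * d$ridge_sigma^2)) -
      d$gate_concerted$depth * gauss(p, d$gate_concerted$center, d$gate_concerted$sigma) -
      d$gate_stepwise$depth * gauss(p, d$gate_stepwise$center, d$gate_stepwise$sigma)
  }
  G1 <- function(p) {
    ctr <- (d$reactant + d$product) / 2
    g <- 4 * d$confine_k * (p - ctr)^3
    for (w in list(list(c0 = d$reactant, A = -d$well_depth, s = d$well_sigma),
                   list(c0 = d$product, A = -d$well_depth, s = d$well_sigma),
                   list(c0 = d$gate_concerted$center, A = -d$gate_concerted$depth,
                        s = d$gate_concerted$sigma),
                   list(c0 = d$gate_stepwise$center, A = -d$gate_stepwise$depth,
                        s = d$gate_stepwise$sigma))) {
      e <- exp(-sum((p - w$c0)^2) / (2 * w$s^2))
      g <- g + w$A * e * (-(p - w$c0) / w$s^2)
    }
    er <- exp(-(p[1] + p[2] - 1)^2 / (2 * d$ridge_sigma^2))
    g <- g + d$ridge_height * er * (-(p[1] + p[2] - 1) / d$ridge_sigma^2) * c(1, 1)
    g
  }
  surf <- potential_surface(dim = 2L, energy = V1, gradient = G1, params = d,
                            start = d$reactant, name = "two_channel")
  surf$oracle <- two_channel_oracle(surf, d)
  if (d$require_concerted_lower &&
      surf$oracle$saddle_stepwise$value <= surf$oracle$saddle_concerted$value)
    stopf("fixture validation: concerted saddle is not below stepwise saddle")
  surf
}

# Dense-grid minimax analysis of the two-channel surface.
two_channel_oracle <- function(surf, d) {
  lo <- min(d$reactant, d$product) - 0.35
  hi <- max(d$reactant, d$product) + 0.35
  n <- d$grid_n
  xs <- seq(lo, hi, length.out = n)
  ys <- xs
  Fm <- outer(seq_along(xs), seq_along(ys),
              Vectorize(function(i, j) surf$energy(c(xs[i], ys[j]))))
  # refine basin minima from the stated centers
  min_r <- stats::optim(d$reactant, surf$energy, gr = surf$gradient, method = "BFGS")
  min_p <- stats::optim(d$product, surf$energy, gr = surf$gradient, method = "BFGS")
  if (sqrt(sum((min_r$par - min_p$par)^2)) < 0.2)
    stopf("fixture validation: basins merged into a single minimum")
  idx_of <- function(p) {
    i <- which.min(abs(xs - p[1])); j <- which.min(abs(ys - p[2]))
    (j - 1L) * n + i
  }
  start <- idx_of(min_r$par); end <- idx_of(min_p$par)
  ridge_band <- 1.5 * d$ridge_sigma
  diag_dev <- outer(xs, ys, function(x, y) x - y)
  on_ridge <- abs(outer(xs, ys, function(x, y) x + y - 1)) < ridge_band
  mask_channel <- function(which) {
    # block the *other* channel's ridge crossing
    blocked <- on_ridge & (if (which == "concerted")
      abs(diag_dev) > d$channel_halfwidth else
      abs(diag_dev) <= d$channel_halfwidth)
    Fb <- Fm
    Fb[blocked] <- NA
    Fb
  }
  sad_c <- tryCatch(
    grid_minimax(mask_channel("concerted"), start, end, return_path = TRUE),
    error = function(e)
      stopf("fixture validation: basins merged or concerted channel unavailable (%s)",
            conditionMessage(e)))
  sad_s <- tryCatch(
    grid_minimax(mask_channel("stepwise"), start, end, return_path = TRUE),
    error = function(e)
      stopf("fixture validation: basins merged or stepwise channel unavailable (%s)",
            conditionMessage(e)))
  e0 <- min_r$value
  loc_of <- function(F, s) {
    k <- which(abs(F - s) < 1e-12)
    k <- k[1]
    c(xs[((k - 1L) %% n) + 1L], ys[((k - 1L) %/% n) + 1L])
  }
  classify <- function(p) {
    if (abs(p[1] + p[2] - 1) >= ridge_band) return("basin")
    if (abs(p[1] - p[2]) <= d$channel_halfwidth) "concerted"
    else if (p[1] - p[2] > d$channel_halfwidth) "stepwise"
    else "inverse"
  }
  list(
    minimum_reactant = list(location = min_r$par, energy = min_r$value),
    minimum_product = list(location = min_p$par, energy = min_p$value),
    saddle_concerted = list(value = sad_c$saddle - e0,
                            location = loc_of(mask_channel("concerted"), sad_c$saddle)),
    saddle_stepwise = list(value = sad_s$saddle - e0,
                           location = loc_of(mask_channel("stepwise"), sad_s$saddle)),
    channel_halfwidth = d$channel_halfwidth,
    ridge_band = ridge_band,
    classify = classify,
    grid = list(x = xs, y = ys, energy = Fm))
}

# ---- mutant-scan fixture ---------------------------------------------------

#' Charged-cluster fixture for the zero-point-charge mutant scan
#'
#' One mobile "nucleophile" particle approaches a fixed charged scaffold
#' along the x axis (stiff transverse restraints keep it on-axis). The
#' scaffold carries three mutable sites: `stab` (a positive charge that
#' stabilizes the close-approach geometry; zeroing it raises the barrier),
#' `mid` (placed equidistant from the start and end geometries, so its
#' deletion barely moves the barrier) and `destab` (a like charge whose
#' deletion lowers the barrier). Because the path is a straight on-axis line,
#' the energy profile and every mutant's barrier shift are closed-form
#' Coulomb sums: the attached oracle evaluates them on a dense grid.
#'
#' @param pull_from,pull_to start and end x of the mobile particle (A).
#' @param restraint_k transverse (y, z) restraint on the mobile particle,
#'   kcal/mol/A^2.
#' @return list with `system` (a [charged_cluster()]), `pull_cv`
#'   (the x coordinate of the mobile particle), `pull_from`, `pull_to`,
#'   `mutants` (site names), and `oracle`: `energy_on_axis(x)`,
#'   per-system analytic barriers and `deltas` versus wild type.
#' @export
make_mutant_cluster <- function(pull_from = 4, pull_to = 1, restraint_k = 500) {
  pos <- rbind(c(0, 0, 0),      # target anchor
               c(pull_from, 0, 0),  # mobile nucleophile
               c(0.5, 1.5, 0),  # stab site
               c(2.5, 3.0, 0),  # mid site (on the x = 2.5 midplane)
               c(0.0, 2.5, 0))  # destab site
  q <- c(-0.25, -0.25, +0.25, +0.25, -0.25)
  sys <- charged_cluster(
    positions = pos, charges = q,
    labels = c("A", "B", "stab", "mid", "destab"),
    fixed = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    restraints = list(list(index = 2L, ref = c(0, 0, 0),
                           k = c(0, restraint_k, restraint_k))),
    sites = list(stab = 3L, mid = 4L, destab = 5L))
  mutants <- c("stab", "mid", "destab")
  energy_on_axis <- function(x, charges = q) {
    scaffold <- c(1L, 3L, 4L, 5L)
    vapply(x, function(xi) {
      r <- sqrt((xi - pos[scaffold, 1])^2 + pos[scaffold, 2]^2 +
                  pos[scaffold, 3]^2)
      sum(COULOMB_KCAL * charges[2L] * charges[scaffold] / r)
    }, numeric(1))
  }
  xs <- seq(pull_from, pull_to, length.out = 2001L)
  analytic_barrier <- function(charges) {
    W <- energy_on_axis(xs, charges) - energy_on_axis(pull_from, charges)
    work_barrier(work_profile(s = pull_from - xs, work = W))$barrier
  }
  barriers <- c(wt = analytic_barrier(q),
                vapply(mutants, function(m) {
                  qm <- q; qm[sys$sites[[m]]] <- 0
                  analytic_barrier(qm)
                }, numeric(1)))
  list(system = sys, pull_cv = cv_coordinate(1L, label = "xB"),
       pull_from = pull_from, pull_to = pull_to, mutants = mutants,
       oracle = list(energy_on_axis = energy_on_axis,
                     barriers = barriers,
                     deltas = barriers[mutants] - barriers[["wt"]]))
}

# ---- charged cluster -------------------------------------------------------

#' Build a charged cluster
#'
#' Point particles with partial charges interacting through Coulomb's law
#' (constant 332.06 kcal A / (mol e^2)) plus harmonic bonds and optional
#' per-axis harmonic position restraints. Particles can be fixed (scaffold);
#' only non-fixed particles are integrated. Named particle groups (`sites`)
#' support the zero-point-charge mutation protocol.
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param charges length-n partial charges, e.
#' @param labels particle labels.
#' @param bonds data.frame with columns `i`, `j`, `k` (kcal/mol/A^2) and `r0`
#'   (A); may be empty.
#' @param restraints list of lists with `index`, `ref` (length-3) and `k`
#'   (scalar or per-axis length-3, kcal/mol/A^2).
#' @param fixed logical length-n; fixed particles are excluded from dynamics.
#' @param sites named list of particle-index vectors (mutable charge groups).
#' @return object of class `charged_cluster`.
#' @export
charged_cluster <- function(positions, charges, labels = NULL, bonds = NULL,
                            restraints = list(), fixed = NULL, sites = list()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (ncol(positions) != 3L) stopf("positions must be n x 3")
  charges <- as.numeric(charges)
  if (length(charges) != n || !all(is.finite(charges)))
    stopf("need %d finite charges", n)
  if (is.null(labels)) labels <- paste0("q", seq_len(n))
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          k = numeric(), r0 = numeric())
  for (s in sites) if (any(s < 1 | s > n)) stopf("site index out of range")
  restraints <- lapply(restraints, function(r) {
    r$k <- rep(as.numeric(r$k), length.out = 3L)
    r$ref <- as.numeric(r$ref)
    r
  })
  structure(list(positions = positions, charges = charges, labels = labels,
                 bonds = bonds, restraints = restraints, fixed = fixed,
                 sites = sites),
            class = "charged_cluster")
}

#' @export
print.charged_cluster <- function(x, ...) {
  cat(sprintf("<charged_cluster> %d particles (%d mobile), %d bonds, sites: %s\n",
              length(x$charges), sum(!x$fixed), nrow(x$bonds),
              if (length(x$sites)) paste(names(x$sites), collapse = ", ") else "none"))
  invisible(x)
}

cluster_positions <- function(system, x) {
  pos <- system$positions
  if (length(x)) pos[!system$fixed, ] <- matrix(x, ncol = 3L, byrow = TRUE)
  pos
}

#' @export
sys_start.charged_cluster <- function(system)
  as.numeric(t(system$positions[!system$fixed, , drop = FALSE]))

#' @export
sys_frame.charged_cluster <- function(system, x)
  frame(cluster_positions(system, x), labels = system$labels)

#' @export
sys_energy.charged_cluster <- function(system, x) {
  pos <- cluster_positions(system, x)
  e <- 0
  b <- system$bonds
  if (nrow(b)) {
    dvec <- pos[b$i, , drop = FALSE] - pos[b$j, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    e <- e + sum(0.5 * b$k * (r - b$r0)^2)
  }
  q <- system$charges
  n <- length(q)
  if (n > 1L) {
    pr <- utils::combn(n, 2L)
    dd <- pos[pr[1, ], , drop = FALSE] - pos[pr[2, ], , drop = FALSE]
    r <- sqrt(rowSums(dd^2))
    e <- e + sum(COULOMB_KCAL * q[pr[1, ]] * q[pr[2, ]] / r)
  }
  for (rs in system$restraints)
    e <- e + sum(0.5 * rs$k * (pos[rs$index, ] - rs$ref)^2)
  e
}

#' @export
sys_gradient.charged_cluster <- function(system, x) {
  pos <- cluster_positions(system, x)
  g <- matrix(0, nrow(pos), 3L)
  b <- system$bonds
  if (nrow(b)) {
    for (m in seq_len(nrow(b))) {
      dvec <- pos[b$i[m], ] - pos[b$j[m], ]
      r <- sqrt(sum(dvec^2))
      f <- b$k[m] * (r - b$r0[m]) * dvec / r
      g[b$i[m], ] <- g[b$i[m], ] + f
      g[b$j[m], ] <- g[b$j[m], ] - f
    }
  }
  q <- system$charges
  n <- length(q)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (q[i] == 0 || q[j] == 0) next
      dvec <- pos[i, ] - pos[j, ]
      r2 <- sum(dvec^2)
      f <- -COULOMB_KCAL * q[i] * q[j] / (r2^1.5) * dvec
      g[i, ] <- g[i, ] + f
      g[j, ] <- g[j, ] - f
    }
  }
  for (rs in system$restraints)
    g[rs$index, ] <- g[rs$index, ] + rs$k * (pos[rs$index, ] - rs$ref)
  as.numeric(t(g[!system$fixed, , drop = FALSE]))
}

#' Zero-point-charge mutation of a charged cluster
#'
#' Returns a copy of the cluster with all partial charges of the named site
#' set to 0 e, leaving geometry, bonds and restraints untouched — the
#' computational-mutagenesis protocol for probing a group's electrostatic
#' contribution to a barrier.
#'
#' @param system a `charged_cluster` with named `sites`.
#' @param site site name (or integer vector of particle indices).
#' @return mutated `charged_cluster`.
#' @export
zero_point_charge_mutant <- function(system, site) {
  idx <- if (is.character(site)) {
    if (!site %in% names(system$sites)) stopf("unknown site '%s'", site)
    system$sites[[site]]
  } else as.integer(site)
  if (any(idx < 1 | idx > length(system$charges))) stopf("site index out of range")
  out <- system
  out$charges[idx] <- 0
  out
}
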