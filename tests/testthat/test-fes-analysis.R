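# FES analysis: minimax path versus exhaustive threshold search, projection
# quadrature, binned observables, work barriers, gradient projections and
# mutant tables.

grid_from_matrix <- function(F, counts = NULL, kT = 0.6) {
  counts <- counts %||% (F * 0 + 10)
  fes_grid(axes = list(S = seq_len(nrow(F)), Z = seq_len(ncol(F))),
           F = F - min(F), counts = counts, kT = kT)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("minimax MFEP agrees exactly with exhaustive threshold search on random grids", {
  set.seed(5)
  for (rep in 1:4) {
    n <- if (rep <= 2) 8 else 20
    F <- matrix(runif(n * n, 0, 10), n, n)
    F[1, 1] <- 0; F[n, n] <- 0.5
    g <- grid_from_matrix(F)
    res <- minimum_free_energy_path(g, start = c(1, 1), end = c(n, n))
    oracle <- threshold_saddle_oracle(g$F, c(1, 1), c(n, n))
    expect_equal(res$saddle, oracle, tolerance = 1e-12)
    # the returned path attains the saddle and never exceeds it
    pvals <- g$F[cbind(res$path[, 1], res$path[, 2])]
    expect_equal(max(pvals), res$saddle)
  }
})

test_that("MFEP follows a single valley and reports its maximum", {
  # monotone 1D-like valley: V-shaped profile replicated over columns
  prof <- c(0, 1, 3, 5, 3, 2, 0.5)
  F <- outer(prof, rep(1, 5)) + outer(rep(0, 7), seq(0, 4)) +
       outer(rep(1, 7), (seq(0, 4) - 2)^2)
  g <- grid_from_matrix(F)
  res <- minimum_free_energy_path(g, start = c(1, 3), end = c(7, 3))
  expect_equal(res$saddle, max(prof) + 0, tolerance = 1e-12)
  # the bottleneck bin sits on the valley floor (middle column)
  expect_equal(res$saddle_bin[2], 3)
  expect_equal(res$barrier, 5)
})

test_that("disconnected endpoints raise a connectivity error", {
  F <- matrix(1, 5, 5)
  counts <- matrix(10, 5, 5)
  counts[3, ] <- 0  # unoccupied wall
  g <- fes_grid(axes = list(S = 1:5, Z = 1:5), F = F - 1, counts = counts,
                kT = 0.6)
  expect_error(minimum_free_energy_path(g, start = c(1, 1), end = c(5, 5)),
               "not connected|unoccupied")
})

test_that("projection onto S matches the separable quadrature oracle", {
  kT <- 0.6
  s <- seq(1, 10, length.out = 30)
  z <- seq(-0.2, 0.2, length.out = 20)
  f <- function(si) (si - 4)^2 / 8
  gz <- function(zi) 40 * zi^2
  F2 <- outer(f(s), gz(z), `+`)
  g <- fes_grid(axes = list(S = s, Z = z), F = F2 - min(F2),
                counts = F2 * 0 + 25, kT = kT)
  proj <- project_to_s(g)
  expected <- f(s) - min(f(s))
  expect_equal(as.numeric(proj$F - min(proj$F)), expected, tolerance = 1e-9)
  # constant-in-Z surface: projection equals any slice up to a constant
  Fc <- outer(f(s), rep(0, 20), `+`)
  gc <- fes_grid(axes = list(S = s, Z = z), F = Fc - min(Fc),
                 counts = Fc * 0 + 5, kT = kT)
  pc <- project_to_s(gc)
  expect_equal(as.numeric(pc$F - min(pc$F)), expected, tolerance = 1e-9)
  # single occupied Z bin per column: projection equals that bin's F
  cnt <- Fc * 0; cnt[, 7] <- 10
  gs <- fes_grid(axes = list(S = s, Z = z), F = F2 - min(F2[, 7]), counts = cnt,
                 kT = kT)
  ps <- project_to_s(gs)
  col <- F2[, 7] - min(F2[, 7])
  expect_equal(as.numeric(ps$F - min(ps$F)), col - min(col), tolerance = 1e-9)
})

test_that("observables bin correctly along S", {
  set.seed(3)
  s <- runif(500, 1, 9)
  edges <- seq(1, 9, by = 1)
  const <- observables_along_s(s, rep(2.5, 500), edges)
  expect_true(all(abs(const$mean[const$n > 0] - 2.5) < 1e-12))
  expect_true(all(const$sd[const$n > 0] == 0))
  own <- observables_along_s(s, s, edges)
  occ <- own$n > 0
  expect_true(all(own$mean[occ] >= edges[-length(edges)][occ] - 1e-9))
  expect_true(all(own$mean[occ] <= edges[-1][occ] + 1e-9))
  # affine observable: binned mean is linear in the bin center
  obs <- 3 * s - 1
  lin <- observables_along_s(s, obs, edges)
  fit <- stats::lm(lin$mean[occ] ~ lin$s[occ])
  expect_equal(unname(stats::coef(fit)[2]), 3, tolerance = 0.05)
  expect_error(observables_along_s(s[0], numeric(0), edges), "no samples")
})

test_that("work_barrier equals the exhaustive ordered-pair scan", {
  flat <- work_profile(s = 1:10, work = rep(0, 10))
  expect_equal(work_barrier(flat)$barrier, 0)
  ramp <- work_profile(s = 1:10, work = c(0, cumsum(rep(0.5, 9))))
  expect_equal(work_barrier(ramp)$barrier, 4.5)
  set.seed(11)
  for (rep in 1:5) {
    w <- c(0, cumsum(rnorm(60, 0.05, 0.4)))
    prof <- work_profile(s = seq_along(w), work = w)
    got <- work_barrier(prof)$barrier
    # brute-force scan over ordered pairs (i <= j), i before the global max
    jmax <- which.max(w)
    oracle <- max(sapply(seq_len(jmax), function(i)
      max(w[seq(i, jmax)] - w[i])))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("gradient projections match direct vector algebra and are bounded", {
  # a path that is purely a symmetric stretch of the 1-2 distance: that
  # distance carries the whole gradient, an orthogonal coordinate none of it
  fs <- lapply(seq(2, 3, length.out = 5), function(d)
    frame(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0), c(0, 5, 0), c(0, 5, 2))))
  path <- reference_path(fs)
  R <- frame(rbind(c(-1.2, 0, 0), c(1.2, 0, 0), c(0, 5, 0), c(0, 5, 2)))
  gp <- gradient_projection(path, R, list(c(1, 2), c(3, 4), c(1, 2)))
  expect_equal(gp$projection[1], 1, tolerance = 1e-8)
  expect_equal(gp$projection[2], 0, tolerance = 1e-8)
  expect_equal(gp$projection[1], gp$projection[3])
  expect_true(all(gp$projection >= 0 & gp$projection <= 1))
  # random case: direct evaluation from assembled gradients
  set.seed(9)
  fs2 <- lapply(1:4, function(i) random_frame(3))
  p2 <- reference_path(fs2)
  R2 <- random_frame(3)
  out <- gradient_projection(p2, R2, list(c(1, 2)))
  ev <- pcv_gradients(p2, R2)
  dvec <- R2$coords[1, ] - R2$coords[2, ]
  gd <- matrix(0, 3, 3); gd[1, ] <- dvec / sqrt(sum(dvec^2))
  gd[2, ] <- -dvec / sqrt(sum(dvec^2))
  expected <- abs(sum(ev$ds * as.numeric(gd))) /
    (sqrt(sum(ev$ds^2)) * sqrt(sum(gd^2)))
  expect_equal(out$projection[1], expected, tolerance = 1e-10)
})

test_that("squared projections over an orthonormal complete set sum to one", {
  # 2-particle system in 1D-like arrangement: x-displacement basis
  fs <- lapply(seq(0, 1, length.out = 4), function(t)
    frame(rbind(c(t, 0, 0), c(2 + 0.5 * t, 0.3 * t, 0))))
  path <- reference_path(fs)
  R <- frame(rbind(c(0.4, 0, 0), c(2.2, 0.1, 0)))
  ev <- pcv_gradients(path, R)
  g <- ev$ds / sqrt(sum(ev$ds^2))
  # orthonormal basis of the 6-dim space: coordinate unit vectors
  sumsq <- sum(sapply(seq_len(6), function(i) g[i]^2))
  expect_equal(sumsq, 1, tolerance = 1e-12)
})

test_that("mutant barrier table references wild type and checks protocols", {
  mk <- function(label, shift, speed = 0.2, seed = 1) {
    set.seed(seed)
    w <- c(0, cumsum(abs(rnorm(50, 0.2, 0.02)))) + 0
    work_profile(s = seq(0, 5, length.out = 51), work = w * (1 + shift),
                 speed = speed, seed = seed, label = label)
  }
  profs <- list(mk("wt", 0, seed = 1), mk("wt", 0, seed = 2),
                mk("m1", 0.3, seed = 3), mk("m1", 0.32, seed = 4),
                mk("m2", -0.2, seed = 5))
  tab <- compare_mutant_barriers(profs)
  expect_equal(tab$delta[tab$label == "wt"], 0)
  expect_gt(tab$delta[tab$label == "m1"], 0)
  expect_lt(tab$delta[tab$label == "m2"], 0)
  expect_equal(tab$n[tab$label == "m1"], 2)
  bad <- c(profs, list(mk("m3", 0, speed = 0.5)))
  expect_error(compare_mutant_barriers(bad), "mismatch")
  expect_error(compare_mutant_barriers(profs, reference = "zz"), "no profile")
})

test_that("gradient projections tabulate over a set of frames along S", {
  fs <- lapply(seq(2, 3, length.out = 4), function(d)
    frame(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0), c(0, 5, 0))))
  path <- reference_path(fs)
  tab <- gradient_projection(path, fs, list(c(1, 2), c(1, 3)))
  expect_equal(nrow(tab), 8)
  expect_true(all(c("frame", "s", "coordinate", "projection") %in% names(tab)))
  expect_true(all(diff(tab$s[tab$coordinate == "d(1,2)"]) > 0))
  expect_true(all(tab$projection >= 0 & tab$projection <= 1))
})
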