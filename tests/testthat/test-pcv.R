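# Path variable values against naive high-precision summation, limits,
# gradients against finite differences, and reparameterization geometry.

line_path <- function(xs, lambda = NULL) {
  reference_path(lapply(xs, function(x) frame(x)), lambda = lambda)
}

naive_sz <- function(centers, r, lambda) {
  d <- (r - centers)^2
  w <- exp(-lambda * d)
  list(s = sum(seq_along(centers) * w) / sum(w),
       z = -log(sum(w)) / lambda)
}

test_that("S and Z match naive summation on 1D paths", {
  xs <- c(0, 0.13, 0.31, 0.42, 0.58)
  path <- line_path(xs, lambda = 2)
  set.seed(4)
  for (r in c(0.05, 0.2, 0.5, runif(3))) {
    ref <- naive_sz(xs, r, 2)
    R <- frame(r)
    expect_equal(s_value(path, R), ref$s, tolerance = 1e-12)
    expect_equal(z_value(path, R), ref$z, tolerance = 1e-12)
  }
})

test_that("S hits the frame index in the large-lambda limit and respects bounds", {
  xs <- seq(0, 1, length.out = 6)
  path <- line_path(xs, lambda = 5000)
  for (j in c(1, 3, 6)) {
    expect_equal(s_value(path, frame(xs[j])), j, tolerance = 1e-3)
    expect_lt(abs(z_value(path, frame(xs[j]))), 1e-6)
  }
  # midpoint of a 2-frame path: exact symmetry
  p2 <- line_path(c(0, 1), lambda = 3)
  expect_equal(s_value(p2, frame(0.5)), 1.5, tolerance = 1e-12)
  # bounds: S in [1, N], Z >= min d - ln(N)/lambda, Z <= min d
  set.seed(8)
  p <- line_path(runif(7), lambda = 11)
  for (r in runif(10, -1, 2)) {
    s <- s_value(p, frame(r)); z <- z_value(p, frame(r))
    dmin <- min((r - sapply(p$frames, function(f) f$coords[1]))^2)
    expect_gte(s, 1); expect_lte(s, 7)
    expect_gte(z, dmin - log(7) / p$lambda - 1e-12)
    expect_lte(z, dmin + 1e-12)
  }
})

test_that("far from the path Z approaches the minimum msd", {
  path <- line_path(seq(0, 1, 0.25), lambda = 10)
  z <- z_value(path, frame(4))
  expect_lt(abs(z - 9), log(5) / 10 + 1e-9)
})

test_that("log-sum-exp stabilization survives extreme lambda", {
  path <- line_path(c(0, 1), lambda = 1e6)
  expect_equal(s_value(path, frame(0.001)), 1, tolerance = 1e-6)
  expect_true(is.finite(z_value(path, frame(10))))
})

test_that("analytic PCV gradients match central finite differences", {
  set.seed(14)
  fs <- lapply(1:5, function(i) random_frame(3, d = 2))
  path <- reference_path(fs, metric = "plain")
  R <- random_frame(3, d = 2)
  gr <- pcv_gradients(path, R)
  x0 <- as.numeric(R$coords)
  h <- 1e-6
  for (i in seq_along(x0)) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    Rp <- frame(matrix(xp, 3, 2)); Rm <- frame(matrix(xm, 3, 2))
    fd_s <- (s_value(path, Rp) - s_value(path, Rm)) / (2 * h)
    fd_z <- (z_value(path, Rp) - z_value(path, Rm)) / (2 * h)
    expect_equal(gr$ds[i], fd_s, tolerance = 1e-6 * max(1, abs(fd_s)))
    expect_equal(gr$dz[i], fd_z, tolerance = 1e-6 * max(1, abs(fd_z)))
  }
})

test_that("S increases along the path tangent at interior frames", {
  xs <- seq(0, 1, length.out = 5)
  path <- line_path(xs)
  for (j in 2:4) {
    g <- pcv_gradients(path, frame(xs[j] + 1e-9))
    expect_gt(g$ds[1], 0)
  }
})

test_that("aligned-metric S and Z are rigid-motion invariant and gradients rotate covariantly", {
  set.seed(31)
  fs <- lapply(1:4, function(i) random_frame(5))
  path <- reference_path(fs, metric = "aligned")
  R0 <- random_frame(5)
  Rot <- random_rotation3()
  moved <- transform_frame(R0, Rot, c(1, -2, 0.5))
  expect_equal(s_value(path, moved), s_value(path, R0), tolerance = 1e-8)
  expect_equal(z_value(path, moved), z_value(path, R0), tolerance = 1e-8)
  g0 <- pcv_gradients(path, R0)
  g1 <- pcv_gradients(path, moved)
  # gradient transforms as dS/dR' = dS/dR %*% t(Rot) per point
  G0 <- matrix(g0$ds, 5, 3)
  G1 <- matrix(g1$ds, 5, 3)
  expect_equal(G1, G0 %*% t(Rot), tolerance = 1e-6)
})

test_that("S and Z are continuous under small perturbations", {
  set.seed(77)
  path <- line_path(sort(runif(6)))
  r <- runif(1)
  base_s <- s_value(path, frame(r)); base_z <- z_value(path, frame(r))
  for (eps in c(1e-5, -1e-5)) {
    expect_lt(abs(s_value(path, frame(r + eps)) - base_s), 1e-2)
    expect_lt(abs(z_value(path, frame(r + eps)) - base_z), 1e-3)
  }
})

test_that("choose_lambda follows the 2.3/msd rule and guards degeneracy", {
  xs <- seq(0, 0.4, by = 0.1)  # spacing 0.1, msd 0.01
  path <- line_path(xs, lambda = 1)
  expect_equal(choose_lambda(path)$lambda, 230, tolerance = 1e-9)
  same <- lapply(1:3, function(i) frame(1))
  expect_error(reference_path(same), "degenerate|identical")
})

test_that("reparameterization puts frames at equal arc length", {
  traj <- lapply(seq(0, 1, length.out = 50), function(x) frame(x))
  path <- reparameterize(traj, 5)
  xs <- sapply(path$frames, function(f) f$coords[1])
  expect_equal(xs, seq(0, 1, by = 0.25), tolerance = 1e-9)
  # idempotence on already equally spaced input of length N
  evenly <- lapply(seq(0, 1, by = 0.25), function(x) frame(x))
  back <- reparameterize(evenly, 5)
  expect_equal(sapply(back$frames, function(f) f$coords[1]),
               seq(0, 1, by = 0.25), tolerance = 1e-9)
})

test_that("reparameterization of a smooth random curve is near-uniform and preserves arc length", {
  set.seed(123)
  t <- seq(0, 1, length.out = 400)
  curve <- cbind(t + 0.1 * sin(3 * pi * t), 0.5 * cos(2 * pi * t))
  traj <- lapply(seq_len(nrow(curve)), function(i) frame(curve[i, , drop = FALSE]))
  path <- reparameterize(traj, 12)
  adj <- sqrt(sapply(1:11, function(i)
    msd(path$frames[[i + 1]], path$frames[[i]])))
  expect_lte(stats::sd(adj) / mean(adj), 0.2)
  # dense-resampling oracle for the arc length
  dense_arc <- sum(sqrt(rowSums(diff(curve)^2)))
  expect_lt(abs(sum(adj) - dense_arc) / dense_arc, 0.05)
  expect_error(reparameterize(lapply(1:10, function(i) frame(c(1, 1))), 4),
               "zero total arc length")
})

test_that("path_difference is a metric-zero for rigidly moved copies", {
  set.seed(6)
  fs <- lapply(1:4, function(i) random_frame(5))
  a <- reference_path(fs, metric = "aligned")
  expect_equal(path_difference(a, a), 0)
  Rot <- random_rotation3()
  moved <- reference_path(lapply(fs, transform_frame, rotation = Rot,
                                 translation = c(1, 2, 3)),
                          metric = "aligned")
  expect_lt(path_difference(a, moved), 1e-8)
  # two 1D paths offset by delta differ by exactly delta
  p1 <- line_path(seq(0, 1, 0.25))
  p2 <- line_path(seq(0, 1, 0.25) + 0.3)
  expect_equal(path_difference(p1, p2), 0.3, tolerance = 1e-12)
})

test_that("reference paths round-trip through disk with metadata", {
  set.seed(2)
  fs <- lapply(1:4, function(i) random_frame(3, d = 2))
  path <- reference_path(fs, lambda = 17, provenance = list(iteration = 2L))
  file <- file.path(tempdir(), "path_test.tsv")
  write_reference_path(path, file)
  back <- read_reference_path(file)
  expect_equal(back$lambda, 17)
  expect_equal(back$metric, path$metric)
  expect_equal(back$frames[[3]]$coords, fs[[3]]$coords, tolerance = 1e-9)
  expect_equal(back$provenance$iteration, 2L)
  # 3D paths serialize as multi-model XYZ
  fs3 <- lapply(1:3, function(i) random_frame(4, seed = i))
  p3 <- reference_path(fs3)
  f3 <- file.path(tempdir(), "path_test.xyz")
  write_reference_path(p3, f3)
  b3 <- read_reference_path(f3)
  expect_equal(b3$frames[[2]]$coords, fs3[[2]]$coords, tolerance = 1e-9)
})
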