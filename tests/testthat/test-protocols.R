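# Composite procedures: guess-path staging, steering along a path, umbrella
# campaigns and their datasets.

test_that("a single stage pulled to its current value stays put", {
  dw <- make_double_well(3, 0.7)
  params <- quick_params(0, seed = 3)
  stages <- list(list(cv = cv_coordinate(1, "x"), target = -0.35, k = 300,
                      duration = 2))
  gp <- generate_guess_path(dw, stages, params, x0 = -0.35)
  sigma <- sqrt(0.6 / 300)
  expect_lt(abs(gp$final + 0.35), 3 * sigma + 0.05)
  expect_equal(gp$stage_bounds, 1L)
})

test_that("two orthogonal stages on a flat surface land at both targets", {
  flat <- potential_surface(2, function(x) 0, function(x) c(0, 0))
  params <- quick_params(0, seed = 4)
  stages <- list(
    list(cv = cv_coordinate(1, "x"), target = 1, k = 300, duration = 2),
    list(cv = cv_coordinate(2, "y"), target = -0.5, k = 300, duration = 2))
  gp <- generate_guess_path(flat, stages, params, x0 = c(0, 0))
  sigma <- sqrt(0.6 / 300)
  expect_lt(abs(gp$final[1] - 1), 4 * sigma)
  expect_lt(abs(gp$final[2] + 0.5), 4 * sigma)
  expect_error(generate_guess_path(flat, list(list(cv = cv_coordinate(1),
                                                   target = Inf, k = 1,
                                                   duration = 1)), params),
               "finite")
})

test_that("a stepwise stage order threads the stepwise channel", {
  tc <- make_two_channel_surface()
  params <- langevin_params(n_steps = 0, seed = 5, kT = kT_kcal(300),
                            friction = 5, timestep = 0.002)
  stages <- list(
    list(cv = cv_coordinate(1, "x"), target = 1, k = 300, duration = 3),
    list(cv = cv_coordinate(2, "y"), target = 1, k = 300, duration = 3))
  gp <- generate_guess_path(tc, stages, params,
                            x0 = tc$oracle$minimum_reactant$location)
  # where the trajectory crosses the ridge, the attack coordinate leads
  xy <- gp$configurations
  on_ridge <- abs(rowSums(xy) - 1) < tc$oracle$ridge_band
  expect_true(any(on_ridge))
  lead <- xy[on_ridge, 1] - xy[on_ridge, 2]
  expect_gt(stats::median(lead), tc$oracle$channel_halfwidth)
  # end point reaches the product basin
  expect_lt(sum((gp$final - tc$oracle$minimum_product$location)^2), 0.05)
})

test_that("steering a straight flat path accumulates ~zero work and reaches the end", {
  flat <- potential_surface(2, function(x) 0, function(x) c(0, 0))
  fs <- lapply(seq(0, 1, length.out = 8), function(t) frame(c(t, 0.2 * t)))
  path <- reference_path(fs)
  # dF = 0 on a flat surface; the mean final work over seeds reduces to the
  # small friction + endpoint dissipation of the finite-speed pull
  wf <- sapply(6:8, function(seed) {
    params <- langevin_params(n_steps = 0, seed = seed, kT = 0.3,
                              friction = 5, timestep = 0.001)
    st <- steer_along_path(flat, path, params, k_s = 30, speed = 0.25)
    expect_lt(abs(st$s[length(st$s)] - 8), 0.5)
    expect_s3_class(st$profile, "work_profile")
    st$work$work[nrow(st$work)]
  })
  expect_lt(abs(mean(wf)), 2)
  # degenerate path of identical frames is rejected upstream
  expect_error(reference_path(lapply(1:5, function(i) frame(c(1, 1)))),
               "degenerate")
})

test_that("umbrella campaigns validate their design", {
  cv <- cv_coordinate(1, "x")
  expect_error(umbrella_campaign(cv, centers = 1, k = 1,
                                 steps_per_window = 10, seed = 1),
               "at least 2")
  expect_error(umbrella_campaign(cv, centers = c(1, 3, 2), k = 1,
                                 steps_per_window = 10, seed = 1),
               "monotone")
  expect_error(umbrella_campaign(cv, centers = 1:3, k = 1, discard = 1,
                                 steps_per_window = 10, seed = 1),
               "discard")
})

test_that("window sample counts follow the discard arithmetic", {
  dw <- make_double_well(2, 0.7)
  params <- quick_params(0, seed = 7)
  camp <- umbrella_campaign(cv_coordinate(1, "x"), centers = c(-0.3, -0.25),
                            k = 300, steps_per_window = 1000, seed = 7,
                            discard = 0.5, stride = 1L, x0 = -0.35)
  wins <- run_umbrella(dw, camp, params)
  expect_length(wins, 2)
  expect_equal(nrow(wins[[1]]$samples), 500)
  expect_equal(nrow(wins[[2]]$samples), 500)
  # identical seeds give identical datasets
  wins2 <- run_umbrella(dw, camp, params)
  expect_identical(wins[[2]]$samples, wins2[[2]]$samples)
})

test_that("chained windows on a tilted harmonic match the Gaussian closed form", {
  k0 <- 40; b <- 8
  tilted <- potential_surface(1, function(x) 0.5 * k0 * x[1]^2 + b * x[1],
                              function(x) k0 * x[1] + b)
  kT <- 0.6; k <- 150
  params <- langevin_params(n_steps = 0, seed = 11, kT = kT, friction = 5,
                            timestep = 0.002)
  centers <- seq(-0.4, 0.4, by = 0.1)
  camp <- umbrella_campaign(cv_coordinate(1, "x"), centers = centers, k = k,
                            steps_per_window = 6000, seed = 11, discard = 0.5,
                            stride = 2L, x0 = -b / k0)
  wins <- run_umbrella(tilted, camp, params)
  for (w in seq_along(wins)) {
    mu <- (k * centers[w] - b) / (k0 + k)
    sd_x <- sqrt(kT / (k0 + k))
    m <- mean(wins[[w]]$samples[, 1])
    n_eff <- nrow(wins[[w]]$samples) / 15
    expect_lt(abs(m - mu), 3 * sd_x / sqrt(n_eff) + 0.01)
  }
})

test_that("window datasets round-trip through TSV + JSON", {
  dw <- make_double_well(2, 0.7)
  params <- quick_params(0, seed = 9)
  camp <- umbrella_campaign(cv_coordinate(1, "x"), centers = c(-0.32, -0.28),
                            k = 300, steps_per_window = 800, seed = 9,
                            x0 = -0.35)
  wins <- run_umbrella(dw, camp, params)
  dir <- file.path(tempdir(), "windows_test")
  write_windows(wins, dir)
  back <- read_windows(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$samples, wins[[1]]$samples, tolerance = 1e-12)
  expect_equal(back[[2]]$kT, wins[[2]]$kT)
  expect_equal(back[[2]]$biases[[1]]$center, wins[[2]]$biases[[1]]$center)
  # deserialized windows feed WHAM identically
  g1 <- wham_solve(wins, bins = 20)
  g2 <- wham_solve(back, bins = 20)
  expect_equal(g1$F, g2$F, tolerance = 1e-9)
})

test_that("adjacent umbrella windows share histogram support", {
  dw <- make_double_well(2.5, 0.7, tilt = 1)
  params <- quick_params(0, seed = 13)
  camp <- umbrella_campaign(cv_coordinate(1, "x"),
                            centers = seq(-0.525, 0.525, by = 0.05), k = 300,
                            steps_per_window = 1500, seed = 13, discard = 0.5,
                            stride = 3L, x0 = -0.35)
  wins <- run_umbrella(dw, camp, params)
  ranges <- t(sapply(wins, function(w) range(w$samples[, 1])))
  for (w in seq_len(nrow(ranges) - 1))
    expect_gt(min(ranges[w, 2], ranges[w + 1, 2]) -
                max(ranges[w, 1], ranges[w + 1, 1]), 0)
})
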