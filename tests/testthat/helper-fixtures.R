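# Shared helpers: random frames, rotation utilities, quadrature oracles.

random_frame <- function(n = 5, d = 3, seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frame(matrix(rnorm(n * d), n, d), labels = labels)
}

random_rotation3 <- function() {
  # QR of a random Gaussian matrix, determinant fixed to +1
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Brute-force weighted RMSD minimum over a rotation grid (independent oracle
# for the closed-form superposition).
grid_rmsd_oracle <- function(mobile, reference, n_grid = 24) {
  w <- mobile$weights / sum(mobile$weights)
  cm <- colSums(mobile$coords * w)
  cr <- colSums(reference$coords * w)
  A <- sweep(mobile$coords, 2, cm)
  B <- sweep(reference$coords, 2, cr)
  best <- Inf
  as_ <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  bs <- seq(0, pi, length.out = n_grid %/% 2 + 1)
  for (a in as_) for (b in bs) for (cc in as_) {
    R <- euler_rotation(a, b, cc)
    v <- sum(w * rowSums((A %*% t(R) - B)^2))
    if (v < best) best <- v
  }
  sqrt(best)
}

# 1D Boltzmann quadrature over a potential surface.
boltzmann_moment <- function(V, kT, lower, upper, moment = 0) {
  z <- stats::integrate(function(x) sapply(x, function(xi) exp(-V(xi) / kT)),
                        lower, upper, rel.tol = 1e-9)$value
  if (moment == 0) return(z)
  stats::integrate(function(x)
    sapply(x, function(xi) xi^moment * exp(-V(xi) / kT)),
    lower, upper, rel.tol = 1e-9)$value / z
}

# default Langevin parameters for quick test runs
quick_params <- function(n_steps, seed, kT = 0.6, dt = 0.002, friction = 5,
                         stride = 1L) {
  langevin_params(n_steps = n_steps, seed = seed, kT = kT,
                  friction = friction, timestep = dt, stride = stride)
}

# Independent minimax oracle: smallest threshold t such that start and end
# are connected through cells with F <= t (flood fill via igraph components).
threshold_saddle_oracle <- function(F, start, end) {
  nr <- nrow(F); nc <- ncol(F)
  idx <- function(i, j) (j - 1L) * nr + i
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  edges <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
    ii <- ij$i + off$di[k]; jj <- ij$j + off$dj[k]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    cbind(idx(ij$i[ok], ij$j[ok]), idx(ii[ok], jj[ok]))
  }))
  s_idx <- idx(start[1], start[2]); e_idx <- idx(end[1], end[2])
  for (t in sort(unique(as.numeric(F[!is.na(F)])))) {
    keep <- which(!is.na(F) & F <= t)
    if (!(s_idx %in% keep && e_idx %in% keep)) next
    sub <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(as.character(sub), ncol = 2),
                                     directed = FALSE)
    g <- igraph::add_vertices(g,
      length(setdiff(as.character(keep), igraph::V(g)$name)),
      name = setdiff(as.character(keep), igraph::V(g)$name))
    comp <- igraph::components(g)
    mem <- comp$membership
    if (mem[as.character(s_idx)] == mem[as.character(e_idx)]) return(t)
  }
  NA_real_
}

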