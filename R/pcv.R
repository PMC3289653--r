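# Path collective variables: progress along (S) and squared distance from (Z)
# a reference path of frames,
#   S(R) = sum_i i exp(-lambda D(R, R(i))) / sum_i exp(-lambda D(R, R(i)))
#   Z(R) = -(1/lambda) ln sum_i exp(-lambda D(R, R(i)))
# with D the (optionally aligned) mean square displacement. S runs 1..N
# inclusive; Z is in the squared units of the coordinates (Angstrom^2 for
# Cartesian frames).

#' Create a reference path
#'
#' @param frames ordered list of at least 2 mutually comparable [frame()]s.
#' @param metric `"plain"` (raw msd) or `"aligned"` (msd after optimal
#'   superposition; single-point frames always fall back to plain).
#' @param lambda smoothing parameter in inverse squared coordinate units
#'   (A^-2); default from [choose_lambda()].
#' @param provenance free-form list (source trajectory, refinement iteration).
#' @return object of class `reference_path`.
#' @export
reference_path <- function(frames, metric = c("plain", "aligned"),
                           lambda = NULL, provenance = list()) {
  metric <- match.arg(metric)
  if (length(frames) < 2L) stopf("a reference path needs at least 2 frames")
  for (k in seq_along(frames)[-1L]) check_comparable(frames[[k]], frames[[1L]])
  adj <- adjacent_msd(frames, metric)
  if (any(adj <= 0)) stopf("degenerate path: adjacent frames are identical")
  path <- structure(list(frames = frames, metric = metric,
                         lambda = NA_real_, provenance = provenance),
                    class = "reference_path")
  path$lambda <- if (is.null(lambda)) choose_lambda(path)$lambda else as.numeric(lambda)
  if (path$lambda <= 0) stopf("lambda must be positive")
  # flat coordinate cache for fast msd evaluation
  path$coord_matrix <- do.call(rbind, lapply(frames, function(f) as.numeric(f$coords)))
  path$weights <- frames[[1L]]$weights / sum(frames[[1L]]$weights)
  path
}

#' @export
print.reference_path <- function(x, ...) {
  adj <- adjacent_msd(x$frames, x$metric)
  cat(sprintf("<reference_path> N = %d frames, metric = %s, lambda = %.4g\n",
              length(x$frames), x$metric, x$lambda))
  cat(sprintf("  adjacent RMSD: mean %.4g, CV %.3f\n",
              mean(sqrt(adj)), stats::sd(sqrt(adj)) / mean(sqrt(adj))))
  invisible(x)
}

path_n <- function(path) length(path$frames)

adjacent_msd <- function(frames, metric) {
  n <- length(frames)
  multi <- nrow(frames[[1L]]$coords) > 1L
  if (metric == "aligned" && multi) {
    return(vapply(seq_len(n - 1L), function(i)
      msd(frames[[i + 1L]], frames[[i]], align = TRUE), numeric(1)))
  }
  nc <- length(frames[[1L]]$coords)
  co <- vapply(frames, function(f) as.numeric(f$coords), numeric(nc))
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
  w <- frames[[1L]]$weights / sum(frames[[1L]]$weights)
  wrep <- rep(w, ncol(frames[[1L]]$coords))
  d <- co[, -1L, drop = FALSE] - co[, -n, drop = FALSE]
  as.numeric(wrep %*% d^2)
}

# msd of frame R against every path frame, plus displacement vectors needed
# for gradients. For the aligned metric each reference frame is superposed
# onto R first (rotation derivative omitted: it vanishes at the optimum).
path_msds <- function(path, R) {
  n_pts <- nrow(R$coords)
  if (path$metric == "plain" || n_pts == 1L) {
    x <- as.numeric(R$coords)
    P <- path$coord_matrix
    diff <- P - rep(x, each = nrow(P))                # N x (n*D), ref - R
    wrep <- rep(path$weights, ncol(R$coords))
    d <- as.numeric((diff^2) %*% wrep)
    disp <- -diff                                      # R - ref
    list(d = d, disp = disp, wrep = wrep)
  } else {
    N <- path_n(path)
    D <- ncol(R$coords)
    disp <- matrix(0, N, n_pts * D)
    d <- numeric(N)
    w <- path$weights
    for (i in seq_len(N)) {
      sp <- superpose(path$frames[[i]], R)
      d[i] <- sp$rmsd^2
      disp[i, ] <- as.numeric(R$coords - sp$transformed$coords)
    }
    list(d = d, disp = disp, wrep = rep(w, D))
  }
}

# Fast path for abstract single-point frames: works directly on the bare
# configuration vector, skipping frame construction and comparability checks
# (used by the sampling engine, where this is the per-step hot path).
pcv_eval_vec <- function(path, x) {
  P <- path$coord_matrix
  N <- nrow(P)
  diff <- P - rep(x, each = N)
  d <- .rowSums(diff * diff, N, ncol(P))
  lam <- path$lambda
  a <- -lam * d
  m <- max(a)
  e <- exp(a - m)
  se <- sum(e)
  p <- e / se
  idx <- seq_len(N)
  S <- sum(idx * p)
  Z <- -(m + log(se)) / lam
  gd <- -2 * diff
  dS <- -lam * as.numeric(crossprod(gd, (idx - S) * p))
  dZ <- as.numeric(crossprod(gd, p))
  list(s = S, z = Z, ds = dS, dz = dZ)
}

# One-pass evaluation of S, Z and their gradients with log-sum-exp
# stabilization; gradient layout matches as.numeric(R$coords).
pcv_eval <- function(path, R) {
  check_comparable(R, path$frames[[1L]])
  if (nrow(R$coords) == 1L) return(pcv_eval_vec(path, as.numeric(R$coords)))
  pm <- path_msds(path, R)
  lam <- path$lambda
  N <- path_n(path)
  a <- -lam * pm$d
  m <- max(a)
  e <- exp(a - m)
  se <- sum(e)
  p <- e / se
  idx <- seq_len(N)
  S <- sum(idx * p)
  Z <- -(m + log(se)) / lam
  # grad d_i = 2 * w_k * (R_k - ref_k) (column-wise weights)
  gd <- 2 * sweep(pm$disp, 2L, pm$wrep, "*")
  dS <- -lam * as.numeric(crossprod(gd, (idx - S) * p))
  dZ <- as.numeric(crossprod(gd, p))
  list(s = S, z = Z, ds = dS, dz = dZ)
}

#' Progress along a reference path
#'
#' @param path a [reference_path()].
#' @param R a frame comparable with the path frames.
#' @return dimensionless progress in \[1, N\].
#' @export
s_value <- function(path, R) pcv_eval(path, R)$s

#' Squared distance from a reference path
#'
#' @inheritParams s_value
#' @return distance-from-path in squared coordinate units (A^2); bounded by
#'   `min_i D - ln(N)/lambda <= Z <= min_i D(R, R(i))`.
#' @export
z_value <- function(path, R) pcv_eval(path, R)$z

#' Analytic gradients of S and Z
#'
#' Chain-rule gradients with respect to the coordinates of `R` (layout
#' `as.numeric(R$coords)`: points vary fastest within each dimension). For the
#' aligned metric the per-frame msd gradient uses the optimally superposed
#' reference; the derivative of the optimal rotation is omitted (it vanishes
#' at the superposition optimum).
#'
#' @inheritParams s_value
#' @return list with `ds` and `dz` numeric vectors.
#' @export
pcv_gradients <- function(path, R) pcv_eval(path, R)[c("ds", "dz")]

#' Smoothing parameter from path spacing
#'
#' The standard prescription `lambda = 2.3 / <adjacent-frame msd>`, which
#' makes neighbouring frames distinguishable (lambda * D ~ 2.3) without
#' starving distant ones.
#'
#' @param path a `reference_path`, or a bare list of comparable frames.
#' @param metric msd metric used when a bare frame list is given.
#' @return list with `lambda` (A^-2), `mean_msd` and the per-pair msds.
#' @export
choose_lambda <- function(path, metric = "plain") {
  frames <- if (inherits(path, "reference_path")) path$frames else path
  metric <- if (inherits(path, "reference_path")) path$metric else metric
  adj <- adjacent_msd(frames, metric)
  if (mean(adj) <= 0) stopf("degenerate path: identical adjacent frames")
  list(lambda = 2.3 / mean(adj), mean_msd = mean(adj), adjacent_msd = adj)
}

# Select N frames at equal cumulative-RMSD arc length along a frame list,
# interpolating linearly between frames; endpoints preserved exactly.
equal_arc_select <- function(frames, N, metric) {
  seg <- sqrt(adjacent_msd(frames, metric))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stopf("degenerate trajectory: zero total arc length")
  targets <- seq(0, total, length.out = N)
  f1 <- frames[[1L]]
  out <- vector("list", N)
  out[[1L]] <- f1
  out[[N]] <- frames[[length(frames)]]
  for (k in seq(2L, N - 1L)) {
    t <- targets[k]
    j <- findInterval(t, arc, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(frames) - 1L)
    u <- if (seg[j] > 0) (t - arc[j]) / seg[j] else 0
    co <- (1 - u) * frames[[j]]$coords + u * frames[[j + 1L]]$coords
    out[[k]] <- frame(co, labels = f1$labels, weights = f1$weights)
  }
  list(frames = out, arc_length = total)
}

# Moving-average smoothing of a trajectory (window in frames, centered);
# endpoints are kept exact. Vectorized via cumulative sums per coordinate.
smooth_trajectory <- function(trajectory, window) {
  n <- length(trajectory)
  if (window <= 1L || n < 3L) return(trajectory)
  h <- window %/% 2L
  f1 <- trajectory[[1L]]
  nc <- length(f1$coords)
  co <- t(vapply(trajectory, function(f) as.numeric(f$coords), numeric(nc)))
  cs <- apply(co, 2L, cumsum)
  cs <- rbind(0, cs)
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  sm[1L, ] <- co[1L, ]
  sm[n, ] <- co[n, ]
  lapply(i, function(k)
    frame(matrix(sm[k, ], nrow = nrow(f1$coords)), labels = f1$labels,
          weights = f1$weights))
}

#' Reparameterize a trajectory into equally spaced path frames
#'
#' Selects N frames along a trajectory so that cumulative RMSD arc length is
#' divided into N-1 equal segments, interpolating linearly between trajectory
#' frames; endpoints are preserved exactly. For thermally noisy trajectories
#' a moving-average `smooth` window removes the fluctuation arc length, and
#' the selection is then iterated on the reduced polyline (densely resampled)
#' until adjacent-frame RMSDs are near-uniform.
#'
#' @param trajectory list of comparable frames (length >= 2).
#' @param N number of output frames (>= 2).
#' @param metric `"plain"` or `"aligned"` RMSD metric for arc length.
#' @param lambda optional smoothing parameter override for the returned path.
#' @param provenance provenance list stored on the returned path.
#' @param smooth moving-average window (frames) applied before selection;
#'   0 disables (default), `"auto"` uses `length(trajectory)/(2 N)`.
#' @param equalize iterate equal-arc selection on the reduced polyline until
#'   the adjacent-RMSD coefficient of variation is <= 0.1 (default TRUE).
#' @return a [reference_path()] whose adjacent RMSDs are near-uniform; its
#'   provenance records the arc length and spacing diagnostics.
#' @export
reparameterize <- function(trajectory, N, metric = c("plain", "aligned"),
                           lambda = NULL, provenance = list(), smooth = 0L,
                           equalize = TRUE) {
  metric <- match.arg(metric)
  N <- as.integer(N)
  if (N < 2L) stopf("need N >= 2 output frames")
  if (length(trajectory) < 2L) stopf("trajectory too short")
  if (length(trajectory) > 4000L) {
    keep <- unique(round(seq(1L, length(trajectory), length.out = 4000L)))
    trajectory <- trajectory[keep]
  }
  if (identical(smooth, "auto"))
    smooth <- max(1L, length(trajectory) %/% (2L * N))
  traj <- smooth_trajectory(trajectory, as.integer(smooth))
  sel <- equal_arc_select(traj, N, metric)
  out <- sel$frames
  if (equalize) {
    f1 <- out[[1L]]
    for (it in seq_len(20L)) {
      adj <- sqrt(adjacent_msd(out, metric))
      if (stats::sd(adj) / mean(adj) <= 0.1) break
      # densely resample the current polyline, then re-select
      M <- 16L
      dense <- list(out[[1L]])
      for (j in seq_len(N - 1L)) {
        for (m in seq_len(M)) {
          u <- m / M
          co <- (1 - u) * out[[j]]$coords + u * out[[j + 1L]]$coords
          dense[[length(dense) + 1L]] <- frame(co, labels = f1$labels,
                                               weights = f1$weights)
        }
      }
      out <- equal_arc_select(dense, N, metric)$frames
    }
  }
  path <- reference_path(out, metric = metric, lambda = lambda,
                         provenance = c(provenance,
                                        list(arc_length = sel$arc_length,
                                             n_input_frames = length(trajectory),
                                             smooth_window = as.integer(smooth))))
  adj <- sqrt(adjacent_msd(out, metric))
  cv <- stats::sd(adj) / mean(adj)
  if (cv > 0.2)
    warning(sprintf("reparameterized path spacing CV %.3f exceeds 0.2", cv),
            call. = FALSE)
  path$provenance$adjacent_rmsd_mean <- mean(adj)
  path$provenance$adjacent_rmsd_cv <- cv
  path
}

#' Mean frame-wise distance between two reference paths
#'
#' The convergence metric for iterative path refinement: the mean over i of
#' the RMSD between corresponding frames (aligned when the paths use the
#' aligned metric), zero iff the paths are frame-wise identical up to rigid
#' motion under that metric.
#'
#' @param a,b reference paths with equal N and comparable frames.
#' @return mean RMSD in coordinate units (A).
#' @export
path_difference <- function(a, b) {
  if (path_n(a) != path_n(b)) stopf("paths have different frame counts")
  align <- a$metric == "aligned"
  mean(vapply(seq_len(path_n(a)), function(i)
    sqrt(msd(a$frames[[i]], b$frames[[i]], align = align)), numeric(1)))
}

#' Write a reference path to disk
#'
#' Frames go to a multi-model XYZ (3D frames) or a plain TSV of coordinates
#' (abstract frames); N, lambda, metric and provenance go to a JSON sidecar
#' `<path>.json`.
#'
#' @param path a `reference_path`; `file` the frame file to write.
#' @param file output file (`.xyz` for 3D molecular paths, `.tsv` otherwise).
#' @return `file`, invisibly.
#' @export
write_reference_path <- function(path, file) {
  d <- ncol(path$frames[[1L]]$coords)
  n_pts <- nrow(path$frames[[1L]]$coords)
  if (d == 3L && n_pts >= 1L && grepl("\\.xyz$", file)) {
    write_xyz(path$frames, file)
  } else {
    utils::write.table(path$coord_matrix, file, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  meta <- list(n = path_n(path), lambda = path$lambda, metric = path$metric,
               dim = d, n_points = n_pts,
               labels = path$frames[[1L]]$labels,
               weights = path$frames[[1L]]$weights,
               provenance = path$provenance)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a reference path written by [write_reference_path()]
#'
#' @param file the frame file written earlier (sidecar `<file>.json` must
#'   exist); invariants are validated on load.
#' @return a `reference_path`.
#' @export
read_reference_path <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  frames <- if (grepl("\\.xyz$", file)) {
    lapply(read_xyz(file), function(f)
      frame(f$coords, labels = meta$labels, weights = meta$weights))
  } else {
    cm <- as.matrix(utils::read.table(file, sep = "\t"))
    lapply(seq_len(nrow(cm)), function(i)
      frame(matrix(cm[i, ], ncol = meta$dim),
            labels = meta$labels, weights = meta$weights))
  }
  reference_path(frames, metric = meta$metric, lambda = meta$lambda,
                 provenance = as.list(meta$provenance))
}
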