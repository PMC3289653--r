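# Weighted histogram analysis: reconstruction of 1D profiles and 2D surfaces
# from umbrella windows. The self-consistent equations
#   P(b) = sum_w n_w(b) / sum_w N_w exp[(f_w - U_w(b))/kT]
#   f_w  = -kT ln sum_b P(b) exp[-U_w(b)/kT]
# are solved by minimizing the equivalent convex objective (BFGS on the
# window free energies), then polished by direct sweeps until the stated
# tolerance on max |delta f_w| is met.

#' Construct a free-energy grid
#'
#' @param axes list of bin-center vectors, one per dimension (named by CV).
#' @param F free energy per bin (kcal/mol), min-shifted to 0 over occupied
#'   bins; unoccupied bins are `NA`, never zero-filled.
#' @param counts per-bin occupancy counts.
#' @param kT thermal energy, kcal/mol.
#' @param error per-bin error estimate (same shape as `F`), or `NULL`.
#' @param meta free-form metadata list.
#' @return object of class `fes_grid`.
#' @export
fes_grid <- function(axes, F, counts, kT, error = NULL, meta = list()) {
  F <- as.array(F); counts <- as.array(counts)
  occ <- counts > 0
  if (!any(occ)) stopf("free-energy grid has no occupied bins")
  if (abs(min(F[occ], na.rm = TRUE)) > 1e-9)
    stopf("free energy must be min-shifted to 0 over occupied bins")
  if (!is.null(error) && any(error[!is.na(error)] < 0))
    stopf("errors must be non-negative")
  structure(list(axes = axes, F = F, counts = counts, kT = kT,
                 error = error, meta = meta),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  dims <- paste(vapply(x$axes, length, integer(1)), collapse = " x ")
  occ <- sum(x$counts > 0)
  cat(sprintf("<fes_grid> %s bins over (%s), %d occupied, kT = %.4g kcal/mol\n",
              dims, paste(names(x$axes), collapse = ", "), occ, x$kT))
  cat(sprintf("  F range: 0 .. %.3f kcal/mol%s\n", max(x$F, na.rm = TRUE),
              if (!is.null(x$error))
                sprintf("; mean error %.3f", mean(x$error[x$counts > 0], na.rm = TRUE))
              else ""))
  if (!is.null(x$meta$iterations))
    cat(sprintf("  WHAM: %d polish sweeps, residual %.3g\n",
                x$meta$iterations, x$meta$residual))
  invisible(x)
}

# Shared histogram/bias scaffolding for a window list.
wham_setup <- function(windows, bins = NULL, range = NULL) {
  if (!length(windows)) stopf("no windows given")
  cvn <- colnames(windows[[1]]$samples)
  dims <- length(cvn)
  if (dims < 1L || dims > 2L) stopf("WHAM supports 1D and 2D grids")
  kT <- windows[[1]]$kT
  for (w in windows) {
    if (!identical(colnames(w$samples), cvn)) stopf("windows sample different CVs")
    if (abs(w$kT - kT) > 1e-9)
      stopf("mixed-temperature windows are not supported")
  }
  if (is.null(bins)) bins <- if (dims == 1L) 100L else c(60L, 60L)
  bins <- rep(as.integer(bins), length.out = dims)
  all_s <- do.call(rbind, lapply(windows, function(w) w$samples))
  if (is.null(range))
    range <- lapply(seq_len(dims), function(d) {
      r <- range(all_s[, d])
      pad <- 1e-9 * max(diff(r), 1)
      c(r[1] - pad, r[2] + pad)
    })
  edges <- lapply(seq_len(dims), function(d)
    seq(range[[d]][1], range[[d]][2], length.out = bins[d] + 1L))
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  names(centers) <- cvn
  bin_of <- function(samples) {
    idx <- lapply(seq_len(dims), function(d) {
      i <- findInterval(samples[, d], edges[[d]], rightmost.closed = TRUE)
      pmin(pmax(i, 1L), bins[d])
    })
    if (dims == 1L) idx[[1]] else (idx[[2]] - 1L) * bins[1] + idx[[1]]
  }
  n_bins <- prod(bins)
  # per-window counts and totals
  counts_w <- vapply(windows, function(w)
    tabulate(bin_of(w$samples), n_bins), numeric(n_bins))
  n_b <- rowSums(counts_w)
  N_w <- vapply(windows, function(w) nrow(w$samples), numeric(1))
  # bias energy at bin centers, per window
  grid_vals <- if (dims == 1L) matrix(centers[[1]], ncol = 1L) else
    cbind(rep(centers[[1]], bins[2]), rep(centers[[2]], each = bins[1]))
  colnames(grid_vals) <- cvn
  U <- vapply(windows, function(w) {
    u <- numeric(n_bins)
    for (b in w$biases) {
      col <- match(b$cv$label, cvn)
      if (is.na(col))
        stopf("bias on '%s' has no matching sampled CV column", b$cv$label)
      v <- grid_vals[, col]
      u <- u + vapply(v, function(vi) bias_energy_value(b, vi), numeric(1))
    }
    u
  }, numeric(n_bins))
  list(cvn = cvn, dims = dims, bins = bins, edges = edges, centers = centers,
       kT = kT, n_b = n_b, N_w = N_w, U = U, counts_w = counts_w,
       bin_of = bin_of)
}

# Core solve given a setup and per-window counts; returns log-probabilities,
# window free energies, polish iteration count and residual.
wham_core <- function(su, n_b, tolerance, max_iterations, f_init = NULL) {
  kT <- su$kT
  occ <- n_b > 0
  if (!any(occ)) stopf("histogram is empty")
  # connectivity of histogram support through windows: every occupied bin
  # must receive non-negligible weight from the window chain; detect gaps as
  # empty stretches between occupied bins in 1D.
  U <- su$U[occ, , drop = FALSE] / kT
  logN <- log(su$N_w)
  lognb <- log(n_b[occ])
  nw <- ncol(U)
  obj <- function(g) {
    A <- sweep(-U, 2L, g + logN, "+")
    sum(n_b[occ] * logsumexp_rows(A)) - sum(su$N_w * g)
  }
  grad <- function(g) {
    A <- sweep(-U, 2L, g + logN, "+")
    den <- logsumexp_rows(A)
    W <- exp(sweep(A, 1L, den, "-"))
    colSums(n_b[occ] * W) - su$N_w
  }
  if (is.null(f_init)) {
    fit <- stats::optim(numeric(nw), obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    g <- fit$par
  } else {
    # warm start (bootstrap replicates): direct sweeps converge quickly
    g <- f_init / kT
  }
  # polish with direct sweeps to the stated tolerance on max |delta f|
  iter <- 0L
  repeat {
    A <- sweep(-U, 2L, g + logN, "+")
    logp <- lognb - logsumexp_rows(A)
    logp <- logp - logsumexp(logp)
    g_new <- -vapply(seq_len(nw), function(w) logsumexp(logp - U[, w]),
                     numeric(1))
    g_new <- g_new - g_new[1L] + 0  # gauge: f_1 relative scale kept finite
    delta <- max(abs(g_new - (g - g[1L]))) * kT
    g <- g_new
    iter <- iter + 1L
    if (delta < tolerance || iter >= max_iterations) break
  }
  converged <- delta < tolerance
  A <- sweep(-U, 2L, g + logN, "+")
  logp_occ <- lognb - logsumexp_rows(A)
  logp_occ <- logp_occ - logsumexp(logp_occ)
  logp <- rep(NA_real_, length(n_b))
  logp[occ] <- logp_occ
  list(logp = logp, f = g * kT, iterations = iter, residual = delta,
       converged = converged)
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' @param windows list of [window_dataset()]s sampling the same CVs at one
#'   temperature; at least 2 for a nontrivial solve (a single unbiased window
#'   degenerates to `-kT ln(histogram)`).
#' @param bins bin count per dimension (defaults 100 in 1D, 60 x 60 in 2D).
#' @param tolerance convergence threshold on `max |delta f_w|` between
#'   sweeps, kcal/mol.
#' @param max_iterations cap on polish sweeps.
#' @param range optional list of per-dimension c(min, max) histogram ranges.
#' @return a [fes_grid()]; its `meta` records the window free energies,
#'   iteration count, residual and a `converged` flag (non-convergence is
#'   flagged, not thrown).
#' @export
wham_solve <- function(windows, bins = NULL, tolerance = 1e-6,
                       max_iterations = 5000L, range = NULL) {
  su <- wham_setup(windows, bins, range)
  check_window_overlap(su)
  sol <- wham_core(su, su$n_b, tolerance, max_iterations)
  F <- -su$kT * sol$logp
  F <- F - min(F, na.rm = TRUE)
  dimshape <- if (su$dims == 1L) length(su$centers[[1]]) else
    c(length(su$centers[[1]]), length(su$centers[[2]]))
  fes_grid(axes = su$centers,
           F = array(F, dimshape),
           counts = array(su$n_b, dimshape),
           kT = su$kT,
           meta = list(f_windows = sol$f, iterations = sol$iterations,
                       residual = sol$residual, converged = sol$converged,
                       edges = su$edges))
}

# Adjacent windows must share histogram support, otherwise the solve is
# disconnected; checked on the 1D ordering of window centers.
check_window_overlap <- function(su) {
  nw <- ncol(su$counts_w)
  if (nw < 2L) return(invisible(TRUE))
  occ_list <- lapply(seq_len(nw), function(w) which(su$counts_w[, w] > 0))
  # union-find over windows sharing at least one occupied bin
  parent <- seq_len(nw)
  for (a in seq_len(nw - 1L)) for (b in (a + 1L):nw) {
    if (length(intersect(occ_list[[a]], occ_list[[b]]))) {
      ra <- uf_find(parent, a); rb <- uf_find(parent, b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nw), function(w) uf_find(parent, w), integer(1))
  if (length(unique(roots)) > 1L) {
    grp <- split(seq_len(nw), roots)
    stopf("windows do not overlap: disconnected groups {%s}",
          paste(vapply(grp, function(g) paste(g, collapse = ","), character(1)),
                collapse = "} {"))
  }
  invisible(TRUE)
}

#' Block-bootstrap errors for a WHAM solve
#'
#' Resamples each window's sample series in contiguous blocks (block length =
#' 1/10 of the series) with replacement, re-solves WHAM warm-started from the
#' full-data solution, and reports the per-bin standard deviation of the
#' min-shifted free energy. Deterministic for a fixed seed.
#'
#' @param windows list of [window_dataset()]s.
#' @param n_boot number of bootstrap replicates (>= 20).
#' @param seed RNG seed.
#' @param bins,range,tolerance,max_iterations as in [wham_solve()].
#' @return a [fes_grid()] identical to the full solve but with `error` filled
#'   in (per-bin bootstrap standard deviation, kcal/mol).
#' @export
bootstrap_errors <- function(windows, n_boot = 50L, seed = 1L, bins = NULL,
                             tolerance = 1e-6, max_iterations = 5000L,
                             range = NULL) {
  if (n_boot < 20L) stopf("n_boot must be at least 20")
  su <- wham_setup(windows, bins, range)
  check_window_overlap(su)
  sol <- wham_core(su, su$n_b, tolerance, max_iterations)
  n_bins <- length(su$n_b)
  block_rows <- function(n) {
    L <- max(1L, floor(n / 10))
    if (n < 2L * L) stopf("window series too short for block bootstrap")
    starts <- sample.int(n - L + 1L, ceiling(n / L), replace = TRUE)
    idx <- unlist(lapply(starts, function(s) s:(s + L - 1L)))
    idx[seq_len(n)]
  }
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(bb) {
      counts <- vapply(seq_along(windows), function(w) {
        s <- windows[[w]]$samples
        rows <- block_rows(nrow(s))
        tabulate(su$bin_of(s[rows, , drop = FALSE]), n_bins)
      }, numeric(n_bins))
      nb <- rowSums(counts)
      sb <- wham_core(su, nb, tolerance, max_iterations, f_init = sol$f)
      Fb <- -su$kT * sb$logp
      Fb - min(Fb, na.rm = TRUE)
    }, numeric(n_bins))
  })
  err <- apply(boots, 1L, stats::sd, na.rm = TRUE)
  err[rowSums(!is.na(boots)) < 2L] <- NA_real_
  F <- -su$kT * sol$logp
  F <- F - min(F, na.rm = TRUE)
  dimshape <- if (su$dims == 1L) length(su$centers[[1]]) else
    c(length(su$centers[[1]]), length(su$centers[[2]]))
  fes_grid(axes = su$centers,
           F = array(F, dimshape),
           counts = array(su$n_b, dimshape),
           kT = su$kT,
           error = array(err, dimshape),
           meta = list(f_windows = sol$f, iterations = sol$iterations,
                       residual = sol$residual, converged = sol$converged,
                       n_boot = n_boot, boot_seed = seed, edges = su$edges))
}

#' Write a free-energy grid as TSV plus JSON metadata
#'
#' TSV columns: bin centers (one per axis), `F`, `error`, `count`.
#'
#' @param grid a [fes_grid()]; `file` the TSV path (metadata goes to
#'   `<file>.json`).
#' @param file output TSV path.
#' @return `file`, invisibly.
#' @export
write_fes <- function(grid, file) {
  dims <- length(grid$axes)
  coords <- if (dims == 1L) data.frame(grid$axes[[1]]) else
    expand.grid(grid$axes[[1]], grid$axes[[2]], KEEP.OUT.ATTRS = FALSE)
  names(coords) <- names(grid$axes)
  df <- cbind(coords, F = as.numeric(grid$F),
              error = if (is.null(grid$error)) NA_real_ else as.numeric(grid$error),
              count = as.numeric(grid$counts))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- grid$meta
  meta$kT <- grid$kT
  meta$axes <- names(grid$axes)
  meta$bins <- vapply(grid$axes, length, integer(1))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_fes
#' @export
read_fes <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  axes <- lapply(meta$axes, function(a) sort(unique(df[[a]])))
  names(axes) <- meta$axes
  shape <- unname(vapply(axes, length, integer(1)))
  ord <- do.call(order, rev(as.list(df[, meta$axes, drop = FALSE])))
  df <- df[ord, ]
  err <- if (all(is.na(df$error))) NULL else array(df$error, shape)
  fes_grid(axes = axes, F = array(df$F, shape),
           counts = array(df$count, shape), kT = meta$kT, error = err,
           meta = meta[setdiff(names(meta), c("kT", "axes", "bins"))])
}

#' Plot a free-energy grid
#'
#' 1D grids get a profile with an error band; 2D grids a filled heat map,
#' optionally with the minimax minimum-free-energy path overlaid.
#'
#' @param x a [fes_grid()].
#' @param mfep optional result of [minimum_free_energy_path()] to overlay.
#' @param ... passed to the underlying plot function.
#' @export
plot.fes_grid <- function(x, mfep = NULL, ...) {
  if (length(x$axes) == 1L) {
    s <- x$axes[[1]]
    graphics::plot(s, x$F, type = "l", xlab = names(x$axes)[1],
                   ylab = "F (kcal/mol)", ...)
    if (!is.null(x$error)) {
      graphics::arrows(s, x$F - x$error, s, x$F + x$error,
                       angle = 90, code = 3, length = 0.02,
                       col = "grey60")
    }
  } else {
    graphics::image(x$axes[[1]], x$axes[[2]], x$F,
                    xlab = names(x$axes)[1], ylab = names(x$axes)[2],
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::contour(x$axes[[1]], x$axes[[2]], x$F, add = TRUE,
                      col = "grey30", lwd = 0.5)
    if (!is.null(mfep)) {
      graphics::lines(x$axes[[1]][mfep$path[, 1]],
                      x$axes[[2]][mfep$path[, 2]], lwd = 2)
    }
  }
  invisible(x)
}
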