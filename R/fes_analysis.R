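# Downstream analysis of free-energy surfaces and steered-work profiles:
# minimax minimum free energy paths, 1D projection, observables binned along
# the progress variable, work-profile barriers, gradient-projection
# diagnostics and zero-point-charge mutant comparisons.

#' Construct a steered-work profile
#'
#' @param s progress values along the pull schedule (monotone non-decreasing
#'   in the schedule; the recorded CV may fluctuate).
#' @param work accumulated external work, kcal/mol (`work[1]` must be 0).
#' @param speed pulling speed (cv-units per ps).
#' @param seed RNG seed of the run.
#' @param label system label (e.g. `"wt"` or a mutant id).
#' @return object of class `work_profile`.
#' @export
work_profile <- function(s, work, speed = NA_real_, seed = NA_integer_,
                         label = "wt") {
  if (length(s) != length(work)) stopf("s and work differ in length")
  if (length(work) && abs(work[1]) > 1e-9) stopf("work must start at 0")
  structure(list(s = as.numeric(s), work = as.numeric(work),
                 speed = speed, seed = seed, label = label),
            class = "work_profile")
}

#' @export
print.work_profile <- function(x, ...) {
  cat(sprintf("<work_profile> '%s': %d points, W(final) = %.3f kcal/mol, speed %.3g\n",
              x$label, length(x$work), x$work[length(x$work)], x$speed))
  invisible(x)
}

#' @export
plot.work_profile <- function(x, ...) {
  graphics::plot(x$s, x$work, type = "l", xlab = "S",
                 ylab = "W (kcal/mol)", main = x$label, ...)
  invisible(x)
}

#' Minimax minimum free energy path across a 2D FES
#'
#' Finds the path between two occupied bins, over 8-connected occupied bins,
#' that minimizes the maximum free energy along it (the bottleneck-optimal
#' path). Its maximum is the saddle estimate; the barrier is the saddle
#' minus the free energy at the start bin (pass the start-basin minimum bin).
#'
#' @param grid a 2D [fes_grid()].
#' @param start,end bin indices, each `c(i, j)` into the grid axes; defaults:
#'   the occupied minimum-F bin in the first and last thirds of the first
#'   axis.
#' @return list with `path` (matrix of bin indices), `saddle` (kcal/mol),
#'   `saddle_bin`, `barrier` (= saddle - F\[start\]), `start`, `end`.
#' @export
minimum_free_energy_path <- function(grid, start = NULL, end = NULL) {
  if (length(grid$axes) != 2L) stopf("MFEP requires a 2D grid")
  F <- grid$F
  F[grid$counts == 0] <- NA
  nr <- nrow(F); nc <- ncol(F)
  auto_bin <- function(cols) {
    sub <- F
    sub[setdiff(seq_len(nr), cols), ] <- NA
    k <- which.min(sub)
    c(((k - 1L) %% nr) + 1L, ((k - 1L) %/% nr) + 1L)
  }
  if (is.null(start)) start <- auto_bin(seq_len(max(1L, nr %/% 3L)))
  if (is.null(end)) end <- auto_bin(seq(nr - max(1L, nr %/% 3L) + 1L, nr))
  si <- (start[2] - 1L) * nr + start[1]
  ei <- (end[2] - 1L) * nr + end[1]
  if (is.na(F[si]) || is.na(F[ei])) stopf("start or end bin is unoccupied")
  mm <- grid_minimax(F, si, ei, return_path = TRUE)
  path <- cbind(((mm$path - 1L) %% nr) + 1L, ((mm$path - 1L) %/% nr) + 1L)
  colnames(path) <- names(grid$axes)
  k_sad <- mm$path[which.max(F[mm$path])]
  list(path = path, saddle = mm$saddle,
       saddle_bin = c(((k_sad - 1L) %% nr) + 1L, ((k_sad - 1L) %/% nr) + 1L),
       barrier = mm$saddle - F[si],
       start = start, end = end)
}

#' Project a 2D free-energy surface onto its first axis
#'
#' `F(S) = -kT ln sum_Z exp(-F(S,Z)/kT) dZ` over occupied bins, min-shifted;
#' columns with no occupied bins are `NA`-flagged.
#'
#' @param grid a 2D [fes_grid()] with the progress variable on the first
#'   axis.
#' @return a 1D [fes_grid()] over the first axis.
#' @export
project_to_s <- function(grid) {
  if (length(grid$axes) != 2L) stopf("projection requires a 2D grid")
  kT <- grid$kT
  dz <- if (length(grid$axes[[2]]) > 1L) diff(grid$axes[[2]][1:2]) else 1
  F <- grid$F
  F[grid$counts == 0] <- NA
  prof <- apply(F, 1L, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    -kT * (logsumexp(-col[ok] / kT) + log(dz))
  })
  cnt <- rowSums(grid$counts)
  occ <- cnt > 0 & !is.na(prof)
  prof <- prof - min(prof[occ])
  err <- NULL
  if (!is.null(grid$error)) {
    # propagate as the Boltzmann-weighted mean of per-bin errors
    err <- vapply(seq_len(nrow(F)), function(i) {
      col <- F[i, ]; e <- grid$error[i, ]
      ok <- !is.na(col) & !is.na(e)
      if (!any(ok)) return(NA_real_)
      w <- exp(-(col[ok] - min(col[ok])) / kT)
      sum(w * e[ok]) / sum(w)
    }, numeric(1))
  }
  fes_grid(axes = grid$axes[1L], F = prof, counts = cnt, kT = kT,
           error = err,
           meta = list(projected_from = "2D", dz = dz))
}

#' Bin an observable along the progress variable
#'
#' Unweighted per-bin mean and standard deviation of an observable over all
#' post-discard umbrella samples whose S value falls in the bin (the
#' along-path observable panels of a path-variable study).
#'
#' @param s vector of S values, one per sample.
#' @param observable vector of observable values, same length.
#' @param edges bin edges over S.
#' @return data.frame with `s` (bin centers), `mean`, `sd`, `n`; empty bins
#'   carry `NA` and `n = 0`.
#' @export
observables_along_s <- function(s, observable, edges) {
  if (length(s) != length(observable)) stopf("s and observable differ in length")
  if (!length(s)) stopf("no samples given")
  bin <- findInterval(s, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  inside <- bin >= 1L & bin <= nb
  if (!any(inside)) stopf("no samples fall within the bin range")
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(s = centers, mean = NA_real_, sd = NA_real_, n = 0L)
  for (b in unique(bin[inside])) {
    v <- observable[inside & bin == b]
    out$mean[b] <- mean(v)
    out$sd[b] <- if (length(v) > 1L) stats::sd(v) else 0
    out$n[b] <- length(v)
  }
  out
}

#' Barrier height from a steered-work profile
#'
#' The largest forward rise of the work curve: `max_S W(S) - min W` over the
#' segment preceding the maximum, reported with the S location of the
#' maximum. Equals the full scan over ordered pairs (i <= j, i before the
#' global maximum) of `W(j) - W(i)`.
#'
#' @param profile a [work_profile()].
#' @return list with `barrier` (kcal/mol), `s_max`, `s_ref` (location of the
#'   pre-maximum minimum).
#' @export
work_barrier <- function(profile) {
  W <- profile$work
  if (!length(W)) stopf("empty work profile")
  j <- which.max(W)
  i <- which.min(W[seq_len(j)])
  list(barrier = W[j] - W[i], s_max = profile$s[j], s_ref = profile$s[i])
}

#' Projection of the S gradient onto internal-coordinate gradients
#'
#' For each listed interparticle distance d, the normalized cosine
#' `|grad S . grad d| / (|grad S| |grad d|)` in \[0, 1\]; values near 1 mark
#' distances that carry the mean force along the reaction progress.
#'
#' @param path a [reference_path()].
#' @param R a frame comparable with the path (evaluation point), or a list
#'   of such frames (e.g. the path frames themselves) for a table along S.
#' @param coordinates list of `c(i, j)` particle-index pairs defining the
#'   distances.
#' @return data.frame with `coordinate`, `projection`, a `flat` flag set
#'   when `grad S` vanishes at the point (flagged, not thrown), and — for a
#'   list of evaluation frames — the frame index and its S value.
#' @export
gradient_projection <- function(path, R, coordinates) {
  if (!is_frame(R) && is.list(R)) {
    tabs <- lapply(seq_along(R), function(k) {
      tab <- gradient_projection(path, R[[k]], coordinates)
      cbind(frame = k, s = s_value(path, R[[k]]), tab)
    })
    return(do.call(rbind, tabs))
  }
  ev <- pcv_eval(path, R)
  gS <- ev$ds
  nS <- sqrt(sum(gS^2))
  n_pts <- nrow(R$coords)
  D <- ncol(R$coords)
  out <- data.frame(coordinate = character(0), projection = numeric(0),
                    flat = logical(0))
  for (co in coordinates) {
    i <- co[1]; j <- co[2]
    dvec <- R$coords[i, ] - R$coords[j, ]
    r <- sqrt(sum(dvec^2))
    if (r == 0) stopf("degenerate coordinate: coincident particles %d,%d", i, j)
    gd <- matrix(0, n_pts, D)
    gd[i, ] <- dvec / r
    gd[j, ] <- -dvec / r
    gd <- as.numeric(gd)
    proj <- if (nS == 0) NA_real_ else
      abs(sum(gS * gd)) / (nS * sqrt(sum(gd^2)))
    out <- rbind(out, data.frame(coordinate = sprintf("d(%d,%d)", i, j),
                                 projection = proj, flat = nS == 0))
  }
  out
}

#' Compare steered-work barriers across mutants
#'
#' Computes the work barrier of every profile, referenced to the profile(s)
#' labeled `reference`; replicate profiles (same label, different seeds)
#' are averaged with a standard deviation. All profiles must share the
#' pulling speed.
#'
#' @param profiles list of [work_profile()]s; exactly one label must equal
#'   `reference`.
#' @param reference the reference label (default `"wt"`).
#' @return data.frame with `label`, `barrier`, `sd`, `n`, `delta`
#'   (barrier - reference barrier) and `delta_sd`.
#' @export
compare_mutant_barriers <- function(profiles, reference = "wt") {
  labels <- vapply(profiles, function(p) p$label, character(1))
  if (!reference %in% labels) stopf("no profile labeled '%s'", reference)
  speeds <- vapply(profiles, function(p) p$speed, numeric(1))
  if (any(is.finite(speeds)) &&
      diff(range(speeds[is.finite(speeds)])) > 1e-9 * max(abs(speeds)))
    stopf("protocol mismatch: pulling speeds differ across profiles")
  barr <- vapply(profiles, function(p) work_barrier(p)$barrier, numeric(1))
  agg <- do.call(rbind, lapply(unique(labels), function(l) {
    b <- barr[labels == l]
    data.frame(label = l, barrier = mean(b),
               sd = if (length(b) > 1L) stats::sd(b) else NA_real_,
               n = length(b))
  }))
  ref <- agg[agg$label == reference, ]
  agg$delta <- agg$barrier - ref$barrier
  agg$delta_sd <- sqrt(ifelse(is.na(agg$sd), 0, agg$sd^2 / agg$n) +
                         ifelse(is.na(ref$sd), 0, ref$sd^2 / ref$n))
  agg$delta_sd[agg$label == reference] <- NA_real_
  rownames(agg) <- NULL
  agg
}
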