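# Bottleneck (minimax) path search on a 2D grid of energies.
# Cells are activated in order of increasing energy and merged with activated
# 8-connected neighbours (union-find); the energy at which start and end join
# is exactly the minimax saddle. A path attaining it is recovered by breadth-
# first search restricted to cells at or below the saddle.

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

neighbors8 <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  rr <- r + dr
  cc <- c + dc
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  (cc[ok] - 1L) * nr + rr[ok]
}

# F: numeric matrix (NA = unavailable cell); start/end: linear indices.
# Returns list(saddle, path (linear indices), reached).
grid_minimax <- function(F, start, end, return_path = TRUE) {
  nr <- nrow(F); nc <- ncol(F)
  if (is.na(F[start]) || is.na(F[end]))
    stopf("start or end cell is unoccupied")
  ord <- order(F, na.last = NA)
  parent <- seq_len(nr * nc)
  active <- logical(nr * nc)
  saddle <- NA_real_
  for (idx in ord) {
    active[idx] <- TRUE
    for (nb in neighbors8(idx, nr, nc)) {
      if (active[nb]) {
        ra <- uf_find(parent, idx); rb <- uf_find(parent, nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (active[start] && active[end] &&
        uf_find(parent, start) == uf_find(parent, end)) {
      saddle <- F[idx]
      break
    }
  }
  if (is.na(saddle))
    stopf("endpoints are not connected through occupied cells")
  path <- NULL
  if (return_path) {
    # shortest path through the sub-level set F <= saddle
    ok <- !is.na(F) & F <= saddle
    prev <- integer(nr * nc)
    seen <- logical(nr * nc)
    queue <- integer(nr * nc)
    queue[1L] <- start; head <- 1L; tail <- 1L
    seen[start] <- TRUE
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      if (cur == end) break
      for (nb in neighbors8(cur, nr, nc)) {
        if (ok[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          prev[nb] <- cur
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
    if (!seen[end]) stopf("internal error: sub-level set does not connect endpoints")
    path <- end
    while (path[[1]] != start) path <- c(prev[path[[1]]], path)
  }
  list(saddle = saddle, path = path)
}
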