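# Frames: ordered labeled point sets with weights, the unit of geometry
# on which the path collective variables are defined.

#' Create a frame
#'
#' A frame is an ordered set of labeled points with D-dimensional coordinates
#' (Angstrom for Cartesian molecular systems, arbitrary units for abstract
#' configuration spaces) and non-negative per-point weights. Two frames are
#' comparable only when their labels agree in order and count.
#'
#' @param coords numeric matrix, one row per point, D columns; or a numeric
#'   vector, interpreted as a single point (an abstract configuration).
#' @param labels character vector of point identifiers; defaults to
#'   `"p1" ... "pn"`.
#' @param weights non-negative numeric weights with positive sum; default
#'   uniform.
#' @return an object of class `frame`.
#' @examples
#' f <- frame(rbind(c(0, 0, 0), c(1, 0, 0)), labels = c("S", "C"))
#' geom_distance(f, 1, 2)
#' @export
frame <- function(coords, labels = NULL, weights = NULL) {
  if (is.null(dim(coords))) coords <- matrix(as.numeric(coords), nrow = 1L)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 1L) stopf("a frame needs at least one point")
  if (!all(is.finite(coords))) stopf("frame coordinates must be finite")
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stopf("got %d labels for %d points", length(labels), n)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be non-negative with positive sum")
  structure(list(labels = labels, coords = coords, weights = weights),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d point(s), dimension %d\n", nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

is_frame <- function(x) inherits(x, "frame")

#' Test whether two frames are comparable
#'
#' @param a,b frames.
#' @return `TRUE` when labels match in order and count and dimensions agree.
#' @export
frames_comparable <- function(a, b) {
  is_frame(a) && is_frame(b) &&
    nrow(a$coords) == nrow(b$coords) &&
    ncol(a$coords) == ncol(b$coords) &&
    all(a$labels == b$labels)
}

check_comparable <- function(a, b) {
  if (!frames_comparable(a, b))
    stopf("frames are not comparable: labels/dimensions must match in order and count")
  invisible(TRUE)
}

weighted_centroid <- function(f) {
  w <- f$weights / sum(f$weights)
  drop(crossprod(f$coords, w))
}

#' Optimal rigid superposition of two frames
#'
#' Computes the proper rotation and translation minimizing the weighted RMSD
#' of `mobile` onto `reference` (covariance/SVD construction with determinant
#' correction, i.e. the Kabsch solution). Weights are used both for centering
#' and in the minimized objective.
#'
#' @param mobile,reference comparable frames with at least 3 points in 3D (or
#'   at least D non-degenerate points in dimension D) for a unique rotation.
#' @return a list with `rotation` (D x D proper rotation), `translation`
#'   (length-D vector; the transform is `coords %*% t(R) + t`), `rmsd`
#'   (Angstrom) and `transformed` (the superposed mobile frame).
#' @export
superpose <- function(mobile, reference) {
  check_comparable(mobile, reference)
  D <- ncol(mobile$coords)
  # the mobile frame's weights define the objective; both centroids use them
  w <- mobile$weights / sum(mobile$weights)
  cm <- drop(crossprod(mobile$coords, w))
  cr <- drop(crossprod(reference$coords, w))
  A <- sweep(mobile$coords, 2L, cm)
  B <- sweep(reference$coords, 2L, cr)
  # weighted covariance of centered coordinates
  H <- crossprod(A * w, B)
  sv <- svd(H)
  # degenerate if the two smallest singular values vanish (collinear/coincident)
  tol <- 1e-10 * max(sv$d, 1e-30)
  if (D > 1L && sort(sv$d)[min(2L, D)] <= tol && nrow(mobile$coords) > 1L)
    stopf("degenerate superposition: points are collinear or coincident")
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(rep(1, D - 1L), d), D)
  R <- sv$v %*% S %*% t(sv$u)
  tr <- cr - drop(R %*% cm)
  new_coords <- mobile$coords %*% t(R) + matrix(tr, nrow(mobile$coords), D, byrow = TRUE)
  moved <- frame(new_coords, labels = mobile$labels, weights = mobile$weights)
  msd_val <- sum(w * rowSums((new_coords - reference$coords)^2))
  list(rotation = R, translation = tr, rmsd = sqrt(max(msd_val, 0)),
       transformed = moved)
}

#' Weighted mean square displacement between two frames
#'
#' @param a,b comparable frames.
#' @param align if `TRUE`, `a` is optimally superposed onto `b` first;
#'   single-point frames are never aligned (no rotation is defined).
#' @return mean square displacement in Angstrom^2; equals `superpose()$rmsd^2`
#'   when `align = TRUE`.
#' @export
msd <- function(a, b, align = FALSE) {
  check_comparable(a, b)
  if (align && nrow(a$coords) > 1L) return(superpose(a, b)$rmsd^2)
  w <- a$weights / sum(a$weights)
  sum(w * rowSums((a$coords - b$coords)^2))
}

#' Interatomic distance within a frame
#'
#' @param f frame.
#' @param i,j distinct point indices.
#' @return Euclidean distance in Angstrom.
#' @export
geom_distance <- function(f, i, j) {
  check_indices(f, c(i, j))
  sqrt(sum((f$coords[i, ] - f$coords[j, ])^2))
}

#' Angle at vertex j
#'
#' @param f frame.
#' @param i,j,k distinct point indices; the angle is measured at `j`.
#' @return angle in degrees, in \[0, 180\].
#' @export
geom_angle <- function(f, i, j, k) {
  check_indices(f, c(i, j, k))
  u <- f$coords[i, ] - f$coords[j, ]
  v <- f$coords[k, ] - f$coords[j, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("degenerate angle: coincident defining points")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Improper torsion (signed dihedral)
#'
#' Signed dihedral between the planes (i, j, k) and (j, k, l), sign by the
#' right-hand rule about the j-k axis, in (-180, 180]. Four coplanar points
#' give 0 degrees (the planar amide limit); pyramidalization shows up as a
#' departure from 0.
#'
#' @param f frame; `i,j,k,l` distinct point indices.
#' @return torsion in degrees.
#' @export
geom_improper <- function(f, i, j, k, l) {
  check_indices(f, c(i, j, k, l))
  b1 <- f$coords[j, ] - f$coords[i, ]
  b2 <- f$coords[k, ] - f$coords[j, ]
  b3 <- f$coords[l, ] - f$coords[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) == 0 || sum(n2^2) == 0)
    stopf("degenerate torsion: collinear defining points")
  # sign by the right-hand rule about the j->k axis: sin ~ (n1 x n2) . b2hat
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

check_indices <- function(f, idx) {
  n <- nrow(f$coords)
  if (any(idx < 1 | idx > n)) stopf("point index out of range 1..%d", n)
  if (anyDuplicated(idx)) stopf("point indices must be distinct")
  invisible(TRUE)
}

#' Apply a rigid motion to a frame
#'
#' @param f frame; `rotation` D x D matrix; `translation` length-D vector.
#' @return transformed frame.
#' @export
transform_frame <- function(f, rotation = NULL, translation = NULL) {
  co <- f$coords
  if (!is.null(rotation)) co <- co %*% t(rotation)
  if (!is.null(translation)) co <- sweep(co, 2L, -as.numeric(translation))
  frame(co, labels = f$labels, weights = f$weights)
}
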