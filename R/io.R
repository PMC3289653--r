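# Multi-model XYZ and PDB readers/writers for frame sequences.

#' Read a multi-model XYZ file into a list of frames
#'
#' Standard XYZ: an atom count line, a comment line, then one `label x y z`
#' line per atom; models are concatenated. Coordinates in Angstrom.
#'
#' @param path file path.
#' @return list of [frame()] objects, all mutually comparable.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stopf("malformed XYZ: expected atom count at line %d", i)
    if (i + 1L + n > length(lines)) stopf("malformed XYZ: truncated model at line %d", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[[`, "", 1L)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (!all(is.finite(co))) stopf("malformed XYZ coordinates near line %d", i + 2L)
    frames[[length(frames) + 1L]] <- frame(co, labels = lab)
    i <- i + 2L + n
  }
  if (!length(frames)) stopf("no models found in %s", path)
  frames
}

#' Write frames to a multi-model XYZ file
#'
#' @param frames a single frame or list of comparable 3D frames.
#' @param path output file path.
#' @param comments optional per-model comment lines.
#' @export
write_xyz <- function(frames, path, comments = NULL) {
  if (is_frame(frames)) frames <- list(frames)
  out <- character(0)
  for (m in seq_along(frames)) {
    f <- frames[[m]]
    if (ncol(f$coords) != 3L) stopf("XYZ output requires 3D frames")
    cm <- if (is.null(comments)) sprintf("model %d", m) else comments[[m]]
    body <- sprintf("%-4s %18.10f %18.10f %18.10f",
                    f$labels, f$coords[, 1], f$coords[, 2], f$coords[, 3])
    out <- c(out, as.character(nrow(f$coords)), cm, body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a (multi-MODEL) PDB file into a list of frames
#'
#' Parsing follows the fixed-column PDB standard via bio3d; atom names become
#' frame labels. Coordinates in Angstrom.
#'
#' @param path file path.
#' @return list of [frame()] objects.
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  lab <- trimws(pdb$atom$elety)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(m)
    frame(matrix(xyz[m, ], ncol = 3L, byrow = TRUE), labels = lab))
}

#' Write frames as a multi-MODEL PDB file
#'
#' @param frames a single frame or list of comparable 3D frames.
#' @param path output file path.
#' @export
write_pdb_frames <- function(frames, path) {
  if (is_frame(frames)) frames <- list(frames)
  f1 <- frames[[1]]
  if (ncol(f1$coords) != 3L) stopf("PDB output requires 3D frames")
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f$coords))))
  n <- nrow(f1$coords)
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   type = rep("ATOM", n),
                   eleno = seq_len(n),
                   elety = f1$labels,
                   resid = rep("MOL", n),
                   resno = rep(1L, n),
                   chain = rep("A", n))
  invisible(path)
}
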