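#' Construct a triangular mesh
#'
#' A `tri_mesh` is the package's container for a triangular surface
#' M = (V, F): a matrix of 3D vertex positions and a matrix of vertex-index
#' triples. Face indices are 1-based internally (the R convention); the
#' file-format readers and writers convert at the boundary.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), one row per
#'   vertex, in the scanner's length units (typically mm). Coordinates must
#'   be finite.
#' @param faces integer matrix with 3 columns, one row per triangle; each
#'   row holds three distinct 1-based vertex indices.
#' @param label optional tooth-type identifier (character scalar).
#' @param source_id optional provenance string (subject/tooth/variant).
#' @return an object of class `tri_mesh`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'               matrix(c(1L, 2L, 3L), 1))
#' n_faces(m)
#' @export
tri_mesh <- function(vertices, faces, label = NULL, source_id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(
    list(vertices = vertices, faces = faces,
         label = label, source_id = source_id),
    class = "tri_mesh")
  validate_mesh(m)
  m
}

#' Validate a triangular mesh
#'
#' Checks the `tri_mesh` invariants: at least 3 vertices and 1 face, finite
#' coordinates, all face indices in range, and three distinct indices per
#' face. Errors (naming the first offending face where relevant) on
#' violation; returns the mesh invisibly otherwise.
#'
#' @param mesh a `tri_mesh`.
#' @return `mesh`, invisibly.
#' @export
validate_mesh <- function(mesh) {
  if (!inherits(mesh, "tri_mesh"))
    stop("not a tri_mesh object")
  v <- mesh$vertices; f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L)
    stop("vertices must be an n x 3 matrix")
  if (!is.matrix(f) || ncol(f) != 3L)
    stop("faces must be an m x 3 integer matrix")
  if (nrow(v) < 3L) stop("mesh must have at least 3 vertices")
  if (nrow(f) < 1L) stop("mesh must have at least 1 face")
  if (!all(is.finite(v)))
    stop("vertex coordinates contain NaN or infinite values")
  bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("face %d references vertex index %d outside [1, %d]",
                 bad[1L, 1L], f[bad[1L, 1L], bad[1L, 2L]], nrow(v)))
  dup <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
  if (any(dup))
    stop(sprintf("face %d has repeated vertex indices", which(dup)[1L]))
  invisible(mesh)
}

#' Number of faces / vertices of a mesh
#' @param mesh a `tri_mesh`.
#' @return integer count.
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname n_faces
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Triangle centroids
#'
#' The centroid (arithmetic mean of the three corner vertices) of every
#' face, in face order.
#'
#' @param mesh a `tri_mesh`.
#' @return an m x 3 numeric matrix.
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] +
   v[f[, 2L], , drop = FALSE] +
   v[f[, 3L], , drop = FALSE]) / 3
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              n_vertices(x), n_faces(x)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$source_id)) cat("  source_id:", x$source_id, "\n")
  invisible(x)
}
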