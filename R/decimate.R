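#' Simplify a mesh to an exact triangle budget
#'
#' Reduces a dense triangular mesh to exactly `target_faces` triangles using
#' quadric-error-metric (QEM) edge collapse: each candidate edge is scored by
#' the quadric error of its optimal collapse position and collapses proceed
#' in increasing-error order until the face count reaches the budget. If
#' boundary collapses overshoot (leaving the count one short), the longest
#' boundary edge is split to restore the exact count. The result always has
#' exactly `target_faces` faces; a mesh already at the budget is returned
#' unchanged. Decimation is deterministic: identical input gives identical
#' output.
#'
#' Intraoral-scanner tooth surfaces typically carry 1e5 or more triangles;
#' the downstream feature encoder requires a fixed budget (default 900), so
#' this is the pipeline's first preprocessing stage.
#'
#' @param mesh a [tri_mesh()].
#' @param target_faces positive integer, the exact output face count
#'   (default 900).
#' @param on_underflow what to do when the input has fewer faces than the
#'   budget: `"error"` (default) or `"passthrough"` (return the mesh
#'   unchanged).
#' @return a [tri_mesh()] with exactly `target_faces` faces; `label` and
#'   `source_id` are preserved.
#' @examples
#' sph <- generate_tooth(tooth_class_specs()[["Canine (L)"]],
#'                       dense_faces = 2000, seed = 1)
#' n_faces(decimate_mesh(sph, 300))
#' @export
decimate_mesh <- function(mesh, target_faces = 900L,
                          on_underflow = c("error", "passthrough")) {
  validate_mesh(mesh)
  on_underflow <- match.arg(on_underflow)
  target_faces <- as.integer(target_faces)
  if (target_faces < 1L) stop("target_faces must be positive")
  nf <- n_faces(mesh)
  if (nf == target_faces) return(mesh)
  if (nf < target_faces) {
    if (on_underflow == "passthrough") return(mesh)
    stop(sprintf(paste0(
      "mesh has %d faces, fewer than the %d-face budget; subdivide it ",
      "first or use on_underflow = \"passthrough\""), nf, target_faces))
  }
  res <- qem_decimate(mesh$vertices, mesh$faces - 1L, target_faces)
  tri_mesh(res$vertices, res$faces + 1L,
           label = mesh$label, source_id = mesh$source_id)
}
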