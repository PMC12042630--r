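#' Rotation specification for mesh augmentation
#'
#' The augmentation rotation operator is parameterized by angles in degrees.
#' In `"single"` mode one shared angle drives a fixed trigonometric matrix
#' (see [rotation_matrix()]); this matrix is exactly the extrinsic Euler
#' composition `Rz(a) %*% Ry(a) %*% Rx(a)` with equal angles. `"triple"`
#' mode composes three independent axis rotations extrinsically as
#' `Rz(az) %*% Ry(ay) %*% Rx(ax)`.
#'
#' @param alpha rotation angle in degrees; wrapped into `[0, 360)`.
#' @param mode `"single"` (one shared angle) or `"triple"` (independent
#'   angles per axis).
#' @param angles_xyz numeric length-3 vector of degrees, used in triple
#'   mode; defaults to `c(alpha, alpha, alpha)`.
#' @return an object of class `rotation_spec`.
#' @export
rotation_spec <- function(alpha = 0, mode = c("single", "triple"),
                          angles_xyz = NULL) {
  mode <- match.arg(mode)
  alpha <- as.numeric(alpha) %% 360
  if (is.null(angles_xyz)) angles_xyz <- rep(alpha, 3L)
  angles_xyz <- as.numeric(angles_xyz) %% 360
  if (length(angles_xyz) != 3L) stop("angles_xyz must have length 3")
  if (mode == "single") angles_xyz <- rep(alpha, 3L)
  structure(list(alpha = alpha, mode = mode, angles_xyz = angles_xyz),
            class = "rotation_spec")
}

#' Translation specification for mesh augmentation
#'
#' @param t numeric length-3 translation vector `(tx, ty, tz)`. The
#'   augmentation policy samples each component uniformly from `[0, 90]`
#'   (scanner length units); arbitrary values are allowed when supplied
#'   directly.
#' @return an object of class `translation_spec`.
#' @export
translation_spec <- function(t = c(0, 0, 0)) {
  t <- as.numeric(t)
  if (length(t) != 3L || !all(is.finite(t)))
    stop("t must be a finite length-3 vector")
  structure(list(t = t), class = "translation_spec")
}

#' Dataset augmentation policy
#'
#' Controls how many variants are emitted per original mesh and how the
#' random rigid transforms are sampled. `variants_per_original` counts
#' every emitted object, including the untransformed identity copy
#' (variant 0), so the default of 6 expands 448 originals to 2688 objects.
#'
#' @param variants_per_original positive integer (default 6).
#' @param angle_range length-2 numeric, degrees (default `c(0, 360)`,
#'   sampled half-open).
#' @param translation_range length-2 numeric (default `c(0, 90)`).
#' @param seed integer seed; the sampling stream is documented: for each
#'   mesh in input order, for each non-identity variant, rotation angles are
#'   drawn before translation components.
#' @param rotation_mode `"single"` or `"triple"` (see [rotation_spec()]).
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(variants_per_original = 6L,
                                angle_range = c(0, 360),
                                translation_range = c(0, 90),
                                seed = 1L,
                                rotation_mode = c("single", "triple")) {
  rotation_mode <- match.arg(rotation_mode)
  variants_per_original <- as.integer(variants_per_original)
  if (variants_per_original < 1L)
    stop("variants_per_original must be >= 1")
  structure(list(variants_per_original = variants_per_original,
                 angle_range = as.numeric(angle_range),
                 translation_range = as.numeric(translation_range),
                 seed = as.integer(seed),
                 rotation_mode = rotation_mode),
            class = "augmentation_policy")
}

#' Augmentation rotation matrix
#'
#' In single mode, the nine entries are computed from the fixed
#' trigonometric formulas in one shared angle a (degrees):
#' \deqn{R(a) = \begin{pmatrix}
#'   \cos^2 a & \cos a(\sin^2 a - \sin a) & \cos^2 a \sin a + \sin^2 a \\
#'   \cos a \sin a & \sin^3 a + \cos^2 a & \cos a(\sin^2 a - \sin a) \\
#'   -\sin a & \sin a \cos a & \cos^2 a \end{pmatrix}}
#' which equals the equal-angle extrinsic Euler composition
#' `Rz(a) Ry(a) Rx(a)` (an exact algebraic identity), hence is a proper
#' rotation. Triple mode returns `Rz(az) Ry(ay) Rx(ax)` for independent
#' angles.
#'
#' @param spec a [rotation_spec()].
#' @return a 3x3 orthogonal matrix with determinant 1.
#' @examples
#' rotation_matrix(rotation_spec(0))    # identity
#' rotation_matrix(rotation_spec(90))   # maps e1 -> -e3
#' @export
rotation_matrix <- function(spec) {
  stopifnot(inherits(spec, "rotation_spec"))
  if (spec$mode == "single") {
    a <- spec$alpha * pi / 180
    ca <- cos(a); sa <- sin(a)
    matrix(c(
      ca^2,       ca * (sa^2 - sa),  ca^2 * sa + sa^2,
      ca * sa,    sa^3 + ca^2,       ca * (sa^2 - sa),
      -sa,        sa * ca,           ca^2
    ), nrow = 3L, byrow = TRUE)
  } else {
    ang <- spec$angles_xyz * pi / 180
    axis_rotation(3L, ang[3L]) %*% axis_rotation(2L, ang[2L]) %*%
      axis_rotation(1L, ang[1L])
  }
}

# elementary rotation about coordinate axis 1, 2 or 3 (radians)
axis_rotation <- function(axis, theta) {
  ca <- cos(theta); sa <- sin(theta)
  R <- diag(3)
  i <- switch(axis, c(2L, 3L), c(1L, 3L), c(1L, 2L))
  R[i[1L], i[1L]] <- ca; R[i[2L], i[2L]] <- ca
  s <- if (axis == 2L) -sa else sa
  R[i[2L], i[1L]] <- s; R[i[1L], i[2L]] <- -s
  R
}

#' Apply a rotation to a mesh
#'
#' Vertices are treated as columns and left-multiplied by the rotation
#' matrix: `V' = t(R %*% t(V))`. Faces, label and source_id are unchanged;
#' the transform is a rigid isometry, so all pairwise vertex distances are
#' preserved.
#'
#' @param mesh a [tri_mesh()].
#' @param spec a [rotation_spec()].
#' @return the rotated [tri_mesh()].
#' @export
apply_rotation <- function(mesh, spec) {
  validate_mesh(mesh)
  R <- rotation_matrix(spec)
  tri_mesh(mesh$vertices %*% t(R), mesh$faces,
           label = mesh$label, source_id = mesh$source_id)
}

#' Apply a translation to a mesh
#'
#' Every vertex v maps to v + t, the affine action of the homogeneous
#' translation matrix. Faces are unchanged.
#'
#' @param mesh a [tri_mesh()].
#' @param spec a [translation_spec()].
#' @return the translated [tri_mesh()].
#' @export
apply_translation <- function(mesh, spec) {
  validate_mesh(mesh)
  stopifnot(inherits(spec, "translation_spec"))
  v <- sweep(mesh$vertices, 2L, spec$t, "+")
  tri_mesh(v, mesh$faces, label = mesh$label, source_id = mesh$source_id)
}

#' Expand a mesh dataset with random rigid transforms
#'
#' Emits exactly `variants_per_original` objects per input mesh: variant 0
#' is the untransformed original; each further variant applies one random
#' rotation followed by one random translation. Angles are drawn uniformly
#' from `angle_range` (degrees) and translation components uniformly from
#' `translation_range`, from a seeded generator with a fixed stream order
#' (per mesh in input order, per variant: rotation draws, then translation
#' draws), so the expansion is fully reproducible. Labels are inherited and
#' `source_id` is extended with the variant index. The default policy grows
#' the study-scale set of 448 originals to 2688 objects.
#'
#' @param meshes list of [tri_mesh()] objects.
#' @param policy an [augmentation_policy()].
#' @return a list of `length(meshes) * variants_per_original` meshes.
#' @export
augment_dataset <- function(meshes, policy = augmentation_policy()) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (length(meshes) == 0L) return(list())
  out <- vector("list", length(meshes) * policy$variants_per_original)
  k <- 0L
  with_seed(policy$seed, {
    for (m in meshes) {
      base_id <- if (is.null(m$source_id)) "mesh" else m$source_id
      for (vi in seq_len(policy$variants_per_original) - 1L) {
        k <- k + 1L
        if (vi == 0L) {
          mm <- m
        } else {
          if (policy$rotation_mode == "single") {
            alpha <- stats::runif(1L, policy$angle_range[1L],
                                  policy$angle_range[2L])
            rs <- rotation_spec(alpha, mode = "single")
          } else {
            ang <- stats::runif(3L, policy$angle_range[1L],
                                policy$angle_range[2L])
            rs <- rotation_spec(ang[1L], mode = "triple", angles_xyz = ang)
          }
          tv <- stats::runif(3L, policy$translation_range[1L],
                             policy$translation_range[2L])
          mm <- apply_translation(apply_rotation(m, rs), translation_spec(tv))
        }
        mm$source_id <- sprintf("%s#v%d", base_id, vi)
        out[[k]] <- mm
      }
    }
  })
  out
}

# evaluate `expr` under a temporary, seeded RNG state, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
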