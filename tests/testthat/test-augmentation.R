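test_that("rotation matrix reduces to identity at zero angle", {
  expect_equal(rotation_matrix(rotation_spec(0)), diag(3), tolerance = 1e-12)
  m <- random_mesh(seed = 1)
  expect_equal(apply_rotation(m, rotation_spec(0))$vertices, m$vertices,
               tolerance = 1e-12)
})

test_that("rotation matrix at 90 degrees matches hand-evaluated entries", {
  # evaluating the nine trigonometric entry formulas at cos a = 0, sin a = 1
  expect_equal(rotation_matrix(rotation_spec(90)),
               rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0)),
               tolerance = 1e-9)
})

test_that("single-angle matrix is orthogonal, proper, and equals the
           extrinsic Rz Ry Rx composition", {
  set.seed(11)
  rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  for (alpha in runif(100, 0, 360)) {
    R <- rotation_matrix(rotation_spec(alpha))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
    a <- alpha * pi / 180
    expect_lt(max(abs(R - rz(a) %*% ry(a) %*% rx(a))), 1e-9)
    # triple mode with equal angles must agree with single mode
    Rt <- rotation_matrix(rotation_spec(alpha, mode = "triple",
                                        angles_xyz = rep(alpha, 3)))
    expect_lt(max(abs(R - Rt)), 1e-9)
  }
})

test_that("rotation is an isometry on meshes", {
  m <- random_mesh(seed = 5, n_extra = 30)
  for (alpha in c(17.5, 211.4, 359.9)) {
    r <- apply_rotation(m, rotation_spec(alpha))
    expect_lt(max_pairwise_distance_dev(m, r), 1e-9)
    expect_identical(r$faces, m$faces)
  }
})

test_that("translation shifts every vertex by exactly t", {
  m <- random_mesh(seed = 2)
  expect_equal(apply_translation(m, translation_spec(c(0, 0, 0)))$vertices,
               m$vertices)
  one <- tri_mesh(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 10)),
                  matrix(1:3, 1L))
  tr <- apply_translation(one, translation_spec(c(10, 20, 30)))
  expect_equal(tr$vertices[1L, ], c(11, 22, 33))
  # centroid linearity
  t0 <- c(4.5, -2.25, 88)
  shifted <- apply_translation(m, translation_spec(t0))
  expect_equal(colMeans(shifted$vertices) - colMeans(m$vertices), t0,
               tolerance = 1e-12)
})

test_that("augment_dataset emits the contracted object counts", {
  small <- lapply(1:448, function(i) {
    m <- random_mesh(seed = i, n_extra = 0L)
    m$label <- "Canine (L)"
    m$source_id <- paste0("m", i)
    m
  })
  out <- augment_dataset(small, augmentation_policy(seed = 9))
  expect_length(out, 2688L)                       # 448 x 6, identity included
  expect_length(augment_dataset(list(), augmentation_policy()), 0L)
  out3 <- augment_dataset(small[1:5], augmentation_policy(
    variants_per_original = 3L, seed = 1))
  expect_length(out3, 15L)
})

test_that("augmented variants are congruent, labeled, and bookkept", {
  meshes <- lapply(1:3, function(i) {
    m <- random_mesh(seed = i, n_extra = 20L)
    m$label <- c("Canine (L)", "1st Molar (R)", "Central Incisor (L)")[i]
    m$source_id <- paste0("src", i)
    m
  })
  out <- augment_dataset(meshes, augmentation_policy(seed = 3))
  expect_length(out, 18L)
  for (i in seq_along(meshes)) {
    for (vi in 0:5) {
      a <- out[[(i - 1L) * 6L + vi + 1L]]
      expect_equal(a$label, meshes[[i]]$label)
      expect_equal(a$source_id, sprintf("src%d#v%d", i, vi))
      expect_equal(n_faces(a), n_faces(meshes[[i]]))
      expect_identical(a$faces, meshes[[i]]$faces)
      expect_lt(max_pairwise_distance_dev(meshes[[i]], a), 1e-9)
    }
    # variant 0 is the untransformed original
    expect_equal(out[[(i - 1L) * 6L + 1L]]$vertices, meshes[[i]]$vertices)
  }
})

test_that("augmentation is bitwise reproducible under a fixed seed", {
  meshes <- lapply(1:2, function(i) random_mesh(seed = i))
  a1 <- augment_dataset(meshes, augmentation_policy(seed = 77))
  a2 <- augment_dataset(meshes, augmentation_policy(seed = 77))
  for (k in seq_along(a1))
    expect_identical(a1[[k]]$vertices, a2[[k]]$vertices)
  # different seed moves the non-identity variants
  a3 <- augment_dataset(meshes, augmentation_policy(seed = 78))
  expect_false(identical(a1[[2L]]$vertices, a3[[2L]]$vertices))
})

test_that("sampled translations stay inside the policy range", {
  m <- random_mesh(seed = 4)
  m$source_id <- "m"
  out <- augment_dataset(list(m), augmentation_policy(
    variants_per_original = 50L, seed = 123))
  for (a in out[-1L]) {
    shift <- colMeans(a$vertices) - colMeans(m$vertices)
    # rotation moves the centroid too, but never beyond its norm; the
    # translation component is bounded by [0, 90] per axis by construction
    expect_true(all(abs(shift) <= 90 + sqrt(sum(colMeans(m$vertices)^2)) +
                      max(sqrt(rowSums(m$vertices^2)))))
  }
})
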