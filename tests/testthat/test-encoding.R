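test_that("single-triangle features follow the documented column layout", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(1:3, 1L))
  fm <- extract_features(m)
  expect_equal(dim(fm), c(1L, 12L))
  expect_equal(as.vector(fm),
               c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1 / 3, 1 / 3, 0))
})

test_that("feature subsets slice the combined matrix", {
  m <- decimate_mesh(generate_tooth(tooth_class_specs()[["Canine (R)"]],
                                    seed = 3, dense_faces = 2000), 300)
  both <- extract_features(m, "both", budget = 300)
  expect_equal(dim(both), c(300L, 12L))
  expect_equal(extract_features(m, "vertices"), both[, 1:9])
  expect_equal(extract_features(m, "centers"), both[, 10:12])
  # centroid columns are the row-wise mean of the vertex columns
  expect_lt(max(abs(both[, 10:12] -
                      (both[, 1:3] + both[, 4:6] + both[, 7:9]) / 3)), 1e-9)
})

test_that("face-count budget is enforced in strict mode and padded in
           lenient mode", {
  m <- random_mesh(seed = 1)  # 14 faces
  expect_error(extract_features(m, budget = 900), "14.*900|900.*14")
  expect_warning(fm <- extract_features(m, budget = 20, strict = FALSE),
                 "padding")
  expect_equal(dim(fm), c(20L, 12L))
  expect_true(all(fm[15:20, ] == 0))
  expect_warning(fm2 <- extract_features(m, budget = 10, strict = FALSE),
                 "truncating")
  expect_equal(nrow(fm2), 10L)
})

test_that("encoding is permutation-covariant in face order", {
  m <- random_mesh(seed = 8)
  perm <- sample(n_faces(m))
  mp <- tri_mesh(m$vertices, m$faces[perm, ])
  expect_equal(extract_features(mp), extract_features(m)[perm, ])
  # canonical ordering erases the permutation
  expect_equal(extract_features(mp, order = "canonical"),
               extract_features(m, order = "canonical"))
})

test_that("min-max image normalization matches forced arithmetic", {
  fm <- matrix(c(0, 5, 10, 5), 2L)
  img <- to_feature_image(fm)
  expect_equal(img$pixels, matrix(c(0, 0.5, 1, 0.5), 2L))
  expect_equal(img$norm_lo, 0)
  expect_equal(img$norm_hi, 10)
  # degenerate range -> all zeros
  expect_equal(to_feature_image(matrix(7, 3L, 4L))$pixels,
               matrix(0, 3L, 4L))
  expect_error(to_feature_image(matrix(c(1, NaN), 1L)), "NaN")
})

test_that("quantized images are 8-bit with full dynamic range", {
  set.seed(2)
  fm <- matrix(rnorm(120), 10L)
  img <- to_feature_image(fm, quantize_8bit = TRUE)
  expect_true(all(img$pixels == round(img$pixels)))
  expect_equal(min(img$pixels), 0L)
  expect_equal(max(img$pixels), 255L)
})

test_that("float images are exactly invertible", {
  set.seed(3)
  fm <- matrix(runif(900 * 12, -30, 45), 900L)
  img <- to_feature_image(fm)
  expect_equal(min(img$pixels), 0)
  expect_equal(max(img$pixels), 1)
  expect_lt(max(abs(from_feature_image(img) - fm)), 1e-9)
})

test_that("feature images round-trip through disk", {
  set.seed(4)
  fm <- matrix(runif(50 * 12), 50L)
  img <- to_feature_image(fm)
  p <- withr::local_tempfile(fileext = ".fimg")
  write_feature_image(img, p)
  r <- read_feature_image(p)
  expect_lt(max(abs(r$pixels - img$pixels)), 1e-7)
  expect_equal(r$norm_lo, img$norm_lo)
  expect_equal(r$norm_hi, img$norm_hi)
  # PNG round trip is exact for quantized images
  q <- to_feature_image(fm, quantize_8bit = TRUE)
  pq <- withr::local_tempfile(fileext = ".png")
  write_feature_image(q, pq)
  rq <- read_feature_image(pq)
  expect_identical(rq$pixels, q$pixels)
  expect_equal(dim(rq$pixels), c(50L, 12L))
})

test_that("budget-conforming meshes encode to the full-scale image shape", {
  m <- decimate_mesh(generate_tooth(tooth_class_specs()[["1st Molar (L)"]],
                                    seed = 6, dense_faces = 5000), 900)
  img <- encode_mesh(m, budget = 900)
  expect_equal(dim(img$pixels), c(900L, 12L))
})
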