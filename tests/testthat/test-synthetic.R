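test_that("tooth class specs cover 16 classes with distinct signatures", {
  specs <- tooth_class_specs()
  expect_length(specs, 16L)
  expect_setequal(names(specs), tooth_labels_16())
  sig <- vapply(specs, function(s)
    paste(s$cusp_count, paste(s$crown_aspect, collapse = ",")), character(1))
  # anatomical types (8 of them) have distinct signatures; sides share them
  expect_equal(length(unique(sig)), 8L)
})

test_that("generation is deterministic and mirrored classes reflect x", {
  specs <- tooth_class_specs()
  a <- generate_tooth(specs[["Canine (L)"]], seed = 4, dense_faces = 1000)
  b <- generate_tooth(specs[["Canine (L)"]], seed = 4, dense_faces = 1000)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  r <- generate_tooth(specs[["Canine (R)"]], seed = 4, dense_faces = 1000)
  expect_equal(r$vertices[, 1L], -a$vertices[, 1L], tolerance = 1e-12)
  expect_equal(r$vertices[, 2:3], a$vertices[, 2:3], tolerance = 1e-12)
})

test_that("occlusal peak counts separate molars from incisors", {
  specs <- tooth_class_specs()
  for (seed in c(2, 9)) {
    molar <- generate_tooth(specs[["1st Molar (L)"]], seed = seed,
                            dense_faces = 8000)
    incisor <- generate_tooth(specs[["Central Incisor (L)"]], seed = seed,
                              dense_faces = 8000)
    pm <- count_occlusal_peaks(molar)
    pi_ <- count_occlusal_peaks(incisor)
    expect_gte(pm, 3L)     # four cusps, allowing one grid-merge
    expect_lte(pi_, 1L)    # smooth dome
  }
})

test_that("dataset generation matches the configured census", {
  ds1 <- generate_dataset(synthetic_dataset_config(n_subjects = 1L,
                                                   dense_faces = 500L,
                                                   seed = 5L))
  expect_length(ds1$meshes, 16L)
  expect_setequal(ds1$labels$label16, tooth_labels_16())
  expect_equal(nrow(ds1$labels), 16L)
  ds0 <- generate_dataset(synthetic_dataset_config(n_subjects = 0L))
  expect_length(ds0$meshes, 0L)
  expect_equal(nrow(ds0$labels), 0L)
})

test_that("generated meshes validate, decimate to 900, and round-trip the
           label CSV through the pipeline reader", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_dataset_config(n_subjects = 1L,
                                                  dense_faces = 3000L,
                                                  seed = 8L),
                         out_dir = dir)
  for (m in ds$meshes) {
    expect_silent(validate_mesh(m))
    expect_equal(n_faces(decimate_mesh(m, 900L)), 900L)
  }
  lab <- read_labels(file.path(dir, "labels.csv"))
  expect_equal(lab, ds$labels)
  m1 <- read_mesh(file.path(dir, lab$file[1L]))
  expect_equal(n_vertices(m1), n_vertices(ds$meshes[[1L]]))
})

test_that("a trivial shape-feature classifier separates the 4 categories", {
  # bounding-box aspect + occlusal peak count must already be ~ diagnostic,
  # guaranteeing the learned benchmark is winnable
  ds <- generate_dataset(synthetic_dataset_config(n_subjects = 6L,
                                                  dense_faces = 4000L,
                                                  seed = 21L))
  scheme <- label_scheme(4L)
  truth <- collapse_labels(ds$labels$label16, scheme)
  pred <- vapply(ds$meshes, function(m) {
    peaks <- count_occlusal_peaks(m)
    bb <- apply(m$vertices, 2L, function(col) diff(range(col)))
    if (peaks >= 3L) "molars"
    else if (peaks == 2L) "premolars"
    else if (bb[2L] / bb[1L] < 0.68) "incisors"
    else "canines"
  }, character(1))
  expect_gte(mean(pred == truth), 0.90)
})
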