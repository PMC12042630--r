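test_that("minimal OBJ parses into a valid mesh", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p)
  m <- read_mesh(p)
  expect_equal(n_vertices(m), 3L)
  expect_equal(n_faces(m), 1L)
  expect_equal(m$faces, matrix(1:3, 1L))
})

test_that("quad faces are fan-triangulated (cube OBJ -> 12 triangles)", {
  p <- withr::local_tempfile(fileext = ".obj")
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  quads <- rbind(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6))
  writeLines(c(sprintf("v %d %d %d", v$x, v$y, v$z),
               sprintf("f %d %d %d %d", quads[, 1], quads[, 2],
                       quads[, 3], quads[, 4])), p)
  m <- read_mesh(p)
  expect_equal(n_faces(m), 12L)
  expect_equal(n_vertices(m), 8L)
})

test_that("save/load round-trips preserve geometry in all formats", {
  m <- random_mesh(seed = 42)
  for (fmt in c("obj", "ply")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, p)
    r <- read_mesh(p)
    expect_lt(max(abs(r$vertices - m$vertices)), 1e-6)
    expect_identical(r$faces, m$faces)
  }
  # binary PLY stores doubles: exact
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, p, binary = TRUE)
  r <- read_mesh(p)
  expect_identical(r$faces, m$faces)
  expect_equal(r$vertices, m$vertices, tolerance = 0)
  # STL re-indexes via exact welding; compare per-face corner coordinates
  for (bin in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".stl")
    write_mesh(m, p, format = "stl", binary = bin)
    r <- read_mesh(p)
    expect_equal(n_faces(r), n_faces(m))
    corners <- function(mm) cbind(mm$vertices[mm$faces[, 1], ],
                                  mm$vertices[mm$faces[, 2], ],
                                  mm$vertices[mm$faces[, 3], ])
    expect_lt(max(abs(corners(r) - corners(m))), 1e-6)
  }
})

test_that("STL welding reconstructs shared vertices exactly", {
  m <- random_mesh(seed = 7)
  p <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, p, binary = FALSE)   # ASCII keeps full precision
  r <- read_mesh(p)
  # every vertex referenced by >= 2 faces in the source must be welded back
  used <- table(as.vector(m$faces))
  expect_equal(n_vertices(r), length(used))
})

test_that("mesh validation rejects malformed inputs with precise messages", {
  v <- diag(3)
  expect_error(tri_mesh(v, matrix(c(1L, 2L, 5L), 1L)), "face 1")
  expect_error(tri_mesh(v, matrix(c(1L, 1L, 2L), 1L)), "repeated")
  expect_error(tri_mesh(v, matrix(integer(0), 0L, 3L)), "at least 1 face")
  expect_error(tri_mesh(v[1:2, ], matrix(c(1L, 2L, 1L), 1L)),
               "at least 3 vertices")
  vn <- v; vn[1L, 1L] <- NaN
  expect_error(tri_mesh(vn, matrix(1:3, 1L)), "NaN")
  # invalid mesh is rejected before any write
  bad <- random_mesh(seed = 1)
  bad$vertices[1L, 1L] <- Inf
  p <- withr::local_tempfile(fileext = ".obj")
  expect_error(write_mesh(bad, p), "NaN|infinite")
  expect_false(file.exists(p))
  expect_error(read_mesh(file.path(tempdir(), "does-not-exist.obj")),
               "cannot read")
})

test_that("written OBJ matches the documented v/f record layout", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(1:3, 1L))
  p <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "v ")), 3L)
  expect_equal(sum(startsWith(lines, "f ")), 1L)
})

test_that("label CSV round-trips", {
  lab <- data.frame(file = c("a.obj", "b.obj"),
                    label16 = c("Canine (L)", "1st Molar (R)"),
                    subject_id = c("S01", "S01"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_labels(lab, p)
  expect_equal(read_labels(p), lab)
})

test_that("independent mesh reader (python trimesh) agrees with the writers", {
  m <- decimate_mesh(icosphere(3), 200)
  py <- Sys.which("python")
  script <- paste(
    "import sys, json, trimesh",
    "m = trimesh.load(sys.argv[1], process=False)",
    "print(json.dumps({'nv': int(m.vertices.shape[0]),",
    "                  'nf': int(m.faces.shape[0]),",
    "                  'vsum': float(abs(m.vertices).sum())}))",
    sep = "\n")
  sp <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sp)
  # STL is a triangle soup: trimesh (process=FALSE) keeps one vertex per
  # face corner, so compare the per-corner coordinate mass there
  corner_sum <- sum(abs(m$vertices[as.vector(t(m$faces)), ]))
  for (fmt in c("obj", "ply", "stl")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, p)
    out <- system2(py, c(sp, p), stdout = TRUE, stderr = FALSE)
    res <- jsonlite::fromJSON(out[length(out)])
    expect_equal(res$nf, n_faces(m), info = fmt)
    if (fmt == "stl") {
      expect_equal(res$vsum, corner_sum, tolerance = 1e-4, info = fmt)
    } else {
      expect_equal(res$nv, n_vertices(m), info = fmt)
      expect_equal(res$vsum, sum(abs(m$vertices)), tolerance = 1e-5,
                   info = fmt)
    }
  }
})
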