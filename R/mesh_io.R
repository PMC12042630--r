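#' Read a triangular mesh from OBJ, STL or PLY
#'
#' Supports Wavefront OBJ (`v`/`f` records; polygonal faces are
#' fan-triangulated), STL (ASCII and binary; duplicated corner vertices are
#' welded with an exact-coordinate match so the loaded topology is
#' reproducible), and PLY (ASCII and little-endian binary). The format is
#' taken from the file extension unless given explicitly. File vertex and
#' face order is preserved (STL excepted, where welding assigns indices in
#' first-appearance order).
#'
#' @param path path to the mesh file.
#' @param format one of `"auto"`, `"obj"`, `"stl"`, `"ply"`.
#' @param label,source_id optional metadata attached to the result.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "stl", "ply"),
                      label = NULL, source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") format <- guess_mesh_format(path)
  m <- switch(format,
    obj = read_obj(path),
    stl = read_stl(path),
    ply = read_ply(path))
  tri_mesh(m$vertices, m$faces, label = label,
           source_id = if (is.null(source_id)) basename(path) else source_id)
}

#' Write a triangular mesh to OBJ, STL or PLY
#'
#' The mesh is validated before anything is written. OBJ and ASCII variants
#' store coordinates with 17 significant digits so a read/write round trip
#' reproduces coordinates to well below 1e-6; binary STL uses 32-bit floats
#' (the format's fixed precision), binary PLY 64-bit doubles.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format one of `"auto"` (from extension), `"obj"`, `"stl"`, `"ply"`.
#' @param binary for STL/PLY, write the binary variant (default `TRUE` for
#'   STL, `FALSE` for PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "stl", "ply"),
                       binary = NULL) {
  validate_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  switch(format,
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path, binary = if (is.null(binary)) TRUE else binary),
    ply = write_ply(mesh, path, binary = if (is.null(binary)) FALSE else binary))
  invisible(path)
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "stl", "ply"))
    stop("cannot infer mesh format from extension: ", path)
  ext
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ file has no vertices or no faces: ", path)
  vtok <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- t(vapply(vtok, function(x) as.numeric(x[1:3]), numeric(3)))
  faces_list <- lapply(flines, function(ln) {
    tok <- strsplit(sub("^f\\s+", "", ln), "\\s+")[[1L]]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1L))
    if (length(idx) < 3L) stop("OBJ face with fewer than 3 vertices")
    # negative indices are relative to the current vertex count
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    fan_triangulate(idx)
  })
  faces <- do.call(rbind, faces_list)
  list(vertices = verts, faces = faces)
}

# fan-triangulate a polygon given as a vector of (1-based) vertex indices
fan_triangulate <- function(idx) {
  n <- length(idx)
  if (n == 3L) return(matrix(idx, 1L))
  cbind(idx[1L], idx[2:(n - 1L)], idx[3:n])
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

## ---- STL ----

read_stl <- function(path) {
  tris <- if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path)
  weld_triangle_soup(tris)
}

stl_is_ascii <- function(path) {
  n <- file.size(path)
  head <- readBin(path, "raw", min(n, 1024L))
  length(grepRaw("solid", head, fixed = TRUE)) > 0L &&
    length(grepRaw("facet", head, fixed = TRUE)) > 0L
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- lines[startsWith(lines, "vertex")]
  if (length(vlines) %% 3L != 0L || length(vlines) == 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  tok <- strsplit(sub("^vertex\\s+", "", vlines), "\\s+")
  t(vapply(tok, function(x) as.numeric(x[1:3]), numeric(3)))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ntri <= 0L) stop("binary STL reports no triangles")
  rec <- readBin(con, "raw", ntri * 50L)
  if (length(rec) < ntri * 50L) stop("truncated binary STL")
  # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16
  idx <- rep(seq_len(ntri) - 1L, each = 36L) * 50L +
    rep(12L + seq_len(36L), times = ntri)
  coords <- readBin(rec[idx], "double", n = ntri * 9L, size = 4L,
                    endian = "little")
  matrix(coords, ncol = 3L, byrow = TRUE)
}

# tris: (3m) x 3 matrix of corner coordinates, consecutive triples = faces.
# Weld with an exact-coordinate match (tolerance 0) for reproducible topology.
weld_triangle_soup <- function(tris) {
  key <- paste(sprintf("%.17g", tris[, 1]), sprintf("%.17g", tris[, 2]),
               sprintf("%.17g", tris[, 3]))
  first <- !duplicated(key)
  verts <- tris[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  nrm <- cross3(b - a, cc - a)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    # interleave normal + 3 vertices as float32 per face
    block <- cbind(nrm, a, b, cc)        # m x 12
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid odontomesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g", c(a[i, 1], b[i, 1], cc[i, 1]),
                c(a[i, 2], b[i, 2], cc[i, 2]), c(a[i, 3], b[i, 3], cc[i, 3])),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid odontomesh", con)
  }
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

## ---- PLY ----

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, off, type) {
  sz <- ply_type_size[[type]]
  bytes <- raw[(off + 1L):(off + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", 1L, size = 1L, signed = TRUE),
    uchar = , uint8 = as.integer(bytes[1L]),
    short = , int16 = readBin(bytes, "integer", 1L, size = 2L,
                              signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", 1L, size = 2L,
                                signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", 1L, size = 4L, endian = "little"),
    float = , float32 = readBin(bytes, "double", 1L, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(bytes, "double", 1L, size = 8L,
                                 endian = "little"))
  list(value = as.numeric(val), size = sz)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) { close(con); stop("PLY header truncated") }
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) { close(con); stop("PLY file lacks format line") }
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    close(con); stop("unsupported PLY format: ", fmt)
  }

  # parse element/property declarations
  elements <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L],
               item_type = tok[4L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, type = tok[2L])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    close(con); stop("PLY file lacks vertex or face elements")
  }

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    close(con)
    res <- read_ply_ascii(elements, body)
  } else {
    raw <- readBin(con, "raw", file.size(path))
    close(con)
    res <- read_ply_binary(elements, raw)
  }
  res
}

read_ply_ascii <- function(elements, body) {
  body <- body[nzchar(trimws(body))]
  pos <- 0L
  out <- list()
  for (el in elements) {
    n <- el$count
    lines <- body[(pos + 1L):(pos + n)]
    pos <- pos + n
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, character(1), "name")
      tok <- strsplit(trimws(lines), "\\s+")
      mat <- t(vapply(tok, function(x) as.numeric(x[seq_along(pnames)]),
                      numeric(length(pnames))))
      if (length(pnames) == 1L) mat <- matrix(mat, ncol = 1L)
      colnames(mat) <- pnames
      out$vertices <- unname(mat[, c("x", "y", "z"), drop = FALSE])
    } else if (el$name == "face") {
      faces <- lapply(strsplit(trimws(lines), "\\s+"), function(x) {
        k <- as.integer(x[1L])
        fan_triangulate(as.integer(x[2:(1L + k)]) + 1L)
      })
      out$faces <- do.call(rbind, faces)
    }
  }
  out
}

read_ply_binary <- function(elements, raw) {
  off <- 0L
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      # fast path: all-scalar vertex properties of equal total size
      sizes <- vapply(el$props, function(p)
        if (p$list) NA_integer_ else ply_type_size[[p$type]], integer(1))
      if (anyNA(sizes)) stop("list-typed vertex properties are unsupported")
      stride <- sum(sizes)
      pnames <- vapply(el$props, `[[`, character(1), "name")
      types <- vapply(el$props, `[[`, character(1), "type")
      if (length(unique(types)) == 1L &&
          types[1L] %in% c("float", "float32", "double", "float64")) {
        # homogeneous float records: bulk-read and reshape
        sz <- ply_type_size[[types[1L]]]
        nvals <- el$count * length(pnames)
        vals <- readBin(raw[(off + 1L):(off + nvals * sz)], "double",
                        n = nvals, size = sz, endian = "little")
        mat <- matrix(vals, el$count, length(pnames), byrow = TRUE)
      } else {
        mat <- matrix(NA_real_, el$count, length(pnames))
        for (i in seq_len(el$count)) {
          o <- off + (i - 1L) * stride
          for (j in seq_along(el$props)) {
            r <- ply_read_scalar(raw, o, el$props[[j]]$type)
            mat[i, j] <- r$value
            o <- o + r$size
          }
        }
      }
      colnames(mat) <- pnames
      out$vertices <- unname(mat[, c("x", "y", "z"), drop = FALSE])
      off <- off + el$count * stride
    } else if (el$name == "face") {
      p <- el$props[[1L]]
      if (!p$list) stop("PLY face element must carry a list property")
      faces <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        r <- ply_read_scalar(raw, off, p$count_type)
        k <- as.integer(r$value); off <- off + r$size
        idx <- integer(k)
        for (j in seq_len(k)) {
          ri <- ply_read_scalar(raw, off, p$item_type)
          idx[j] <- as.integer(ri$value); off <- off + ri$size
        }
        faces[[i]] <- fan_triangulate(idx + 1L)
      }
      out$faces <- do.call(rbind, faces)
    } else {
      stop("unsupported PLY element: ", el$name)
    }
  }
  out
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  }
}

## ---- label files ----

#' Read / write a mesh label table
#'
#' The label table is a CSV with columns `file`, `label16`, `subject_id`
#' mapping mesh files to canonical 16-type tooth labels.
#'
#' @param path CSV path.
#' @return a data.frame with character columns `file`, `label16`,
#'   `subject_id`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("file", "label16", "subject_id")
  if (!all(need %in% names(df)))
    stop("label file must have columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' @rdname read_labels
#' @param labels data.frame with columns `file`, `label16`, `subject_id`.
#' @export
write_labels <- function(labels, path) {
  need <- c("file", "label16", "subject_id")
  if (!all(need %in% names(labels)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  utils::write.csv(labels[, need], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
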