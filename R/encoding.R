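#' Extract per-triangle geometric features
#'
#' Builds the sequence representation consumed by the classifier: one row
#' per triangle, in stored face order (or a canonical centroid sort), with
#' columns holding the three corner vertex coordinates
#' `(v1x, v1y, v1z, v2x, v2y, v2z, v3x, v3y, v3z)` followed by the triangle
#' centroid `(cx, cy, cz)`. Subsets restrict to the 9 vertex columns or the
#' 3 centroid columns, matching the feature-ablation variants.
#'
#' @param mesh a [tri_mesh()].
#' @param subset `"both"` (T x 12, default), `"vertices"` (T x 9) or
#'   `"centers"` (T x 3).
#' @param budget optional required triangle count; with `strict = TRUE`
#'   (default) a mismatch is an error naming both counts, otherwise the
#'   matrix is zero-padded at the bottom or truncated, with a warning.
#' @param strict logical, see `budget`.
#' @param order `"stored"` (default) keeps the mesh's face order;
#'   `"canonical"` sorts rows by centroid z, then y, then x (for
#'   order-sensitivity experiments).
#' @return a numeric feature matrix.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'               matrix(1:3, 1))
#' extract_features(m)   # one row: 9 vertex coords + centroid (1/3, 1/3, 0)
#' @export
extract_features <- function(mesh, subset = c("both", "vertices", "centers"),
                             budget = NULL, strict = TRUE,
                             order = c("stored", "canonical")) {
  validate_mesh(mesh)
  subset <- match.arg(subset)
  order <- match.arg(order)
  v <- mesh$vertices; f <- mesh$faces
  vm <- cbind(v[f[, 1L], , drop = FALSE],
              v[f[, 2L], , drop = FALSE],
              v[f[, 3L], , drop = FALSE])
  cm <- (vm[, 1:3, drop = FALSE] + vm[, 4:6, drop = FALSE] +
           vm[, 7:9, drop = FALSE]) / 3
  fm <- switch(subset,
               both = cbind(vm, cm),
               vertices = vm,
               centers = cm)
  if (order == "canonical") {
    cc <- cm
    fm <- fm[base::order(cc[, 3L], cc[, 2L], cc[, 1L]), , drop = FALSE]
  }
  if (!is.null(budget)) {
    budget <- as.integer(budget)
    if (nrow(fm) != budget) {
      if (strict)
        stop(sprintf("feature matrix has %d rows but the triangle budget is %d",
                     nrow(fm), budget))
      warning(sprintf("padding/truncating feature matrix from %d to %d rows",
                      nrow(fm), budget))
      if (nrow(fm) > budget) {
        fm <- fm[seq_len(budget), , drop = FALSE]
      } else {
        fm <- rbind(fm, matrix(0, budget - nrow(fm), ncol(fm)))
      }
    }
  }
  unname(fm)
}

#' Convert a feature matrix to a grayscale feature image
#'
#' Applies joint (whole-matrix) min-max normalization so the matrix becomes
#' a single-intensity-scale grayscale image in `[0, 1]`; the scaling bounds
#' are stored so float-mode images are exactly invertible
#' (`pixels * (hi - lo) + lo`). A constant input (degenerate range) maps to
#' the all-zero image. Quantized mode additionally rounds to 8-bit integers
#' in `[0, 255]` for PNG export.
#'
#' @param fm numeric matrix from [extract_features()]; must be finite.
#' @param quantize_8bit logical (default `FALSE`).
#' @return an object of class `feature_image` with fields `pixels`,
#'   `norm_lo`, `norm_hi`, `quantized`.
#' @export
to_feature_image <- function(fm, quantize_8bit = FALSE) {
  fm <- as.matrix(fm)
  if (!all(is.finite(fm)))
    stop("feature matrix contains NaN or infinite values")
  lo <- min(fm); hi <- max(fm)
  if (hi > lo) {
    px <- (fm - lo) / (hi - lo)
  } else {
    px <- matrix(0, nrow(fm), ncol(fm))
  }
  if (quantize_8bit) {
    px <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  }
  structure(list(pixels = px, norm_lo = lo, norm_hi = hi,
                 quantized = isTRUE(quantize_8bit)),
            class = "feature_image")
}

#' Invert a float-mode feature image back to its feature matrix
#'
#' @param img a `feature_image` produced with `quantize_8bit = FALSE`.
#' @return the reconstructed numeric feature matrix.
#' @export
from_feature_image <- function(img) {
  stopifnot(inherits(img, "feature_image"))
  if (img$quantized)
    stop("quantized images are not exactly invertible; use float mode")
  img$pixels * (img$norm_hi - img$norm_lo) + img$norm_lo
}

#' Write / read a feature image
#'
#' Quantized images are stored as single-channel 8-bit grayscale PNG
#' (lossless). Float images are stored in a plain-text container: a JSON
#' header line (dimensions and normalization bounds) followed by one
#' whitespace-separated row per line at full double precision, restoring
#' pixels to well within 1e-7.
#'
#' @param img a `feature_image`.
#' @param path output path (`.png` for quantized images).
#' @return `path` invisibly; `read_feature_image` returns a
#'   `feature_image`.
#' @export
write_feature_image <- function(img, path) {
  stopifnot(inherits(img, "feature_image"))
  if (img$quantized) {
    png::writePNG(img$pixels / 255, path)
    meta <- list(norm_lo = img$norm_lo, norm_hi = img$norm_hi)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               paste0(path, ".json"))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- jsonlite::toJSON(list(nrow = nrow(img$pixels),
                                 ncol = ncol(img$pixels),
                                 norm_lo = img$norm_lo,
                                 norm_hi = img$norm_hi),
                            auto_unbox = TRUE, digits = NA)
    writeLines(as.character(hdr), con)
    utils::write.table(format(img$pixels, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_image
#' @export
read_feature_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    px <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
    meta_path <- paste0(path, ".json")
    meta <- if (file.exists(meta_path))
      jsonlite::fromJSON(readLines(meta_path))
    else list(norm_lo = 0, norm_hi = 1)
    structure(list(pixels = px, norm_lo = meta$norm_lo,
                   norm_hi = meta$norm_hi, quantized = TRUE),
              class = "feature_image")
  } else {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("corrupt feature-image file: ", path)
    hdr <- jsonlite::fromJSON(lines[1L])
    vals <- scan(text = lines[-1L], quiet = TRUE)
    if (length(vals) != hdr$nrow * hdr$ncol)
      stop("corrupt feature-image file: value count mismatch in ", path)
    px <- matrix(vals, hdr$nrow, hdr$ncol, byrow = TRUE)
    structure(list(pixels = px, norm_lo = hdr$norm_lo,
                   norm_hi = hdr$norm_hi, quantized = FALSE),
              class = "feature_image")
  }
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("feature_image: %d x %d %s, range [%.6g, %.6g]\n",
              nrow(x$pixels), ncol(x$pixels),
              if (x$quantized) "8-bit" else "float",
              x$norm_lo, x$norm_hi))
  invisible(x)
}

#' Encode a mesh directly to a feature image
#'
#' Convenience wrapper: [extract_features()] then [to_feature_image()].
#'
#' @inheritParams extract_features
#' @inheritParams to_feature_image
#' @return a `feature_image`.
#' @export
encode_mesh <- function(mesh, subset = "both", budget = NULL, strict = TRUE,
                        order = "stored", quantize_8bit = FALSE) {
  to_feature_image(
    extract_features(mesh, subset = subset, budget = budget,
                     strict = strict, order = order),
    quantize_8bit = quantize_8bit)
}
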