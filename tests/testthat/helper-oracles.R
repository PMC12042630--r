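# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations, kept separate from the package's code
# paths.

# random valid tri_mesh (a jittered tetrahedron fan)
random_mesh <- function(seed = 1L, n_extra = 10L) {
  set.seed(seed)
  v <- rbind(diag(3), c(0, 0, 0),
             matrix(stats::runif(3 * n_extra, -2, 2), ncol = 3))
  f <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  for (i in seq_len(n_extra))
    f <- rbind(f, c(sample(3L, 2L), 4L + i))
  tri_mesh(v, f)
}

# unit icosphere by repeated 1-to-4 subdivision of an icosahedron
icosphere <- function(depth = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (d in seq_len(depth)) {
    midkey <- new.env()
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midkey[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nv + length(newv)
      midkey[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  tri_mesh(v, f)
}

# area-weighted random points on a mesh surface
sample_surface_points <- function(mesh, n, seed = 1L) {
  set.seed(seed)
  a <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  cr <- cbind((b - a)[, 2] * (cc - a)[, 3] - (b - a)[, 3] * (cc - a)[, 2],
              (b - a)[, 3] * (cc - a)[, 1] - (b - a)[, 1] * (cc - a)[, 3],
              (b - a)[, 1] * (cc - a)[, 2] - (b - a)[, 2] * (cc - a)[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  fi <- sample.int(nrow(a), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  (1 - r1) * a[fi, ] + r1 * (1 - r2) * b[fi, ] + r1 * r2 * cc[fi, ]
}

# brute-force per-class metrics from first principles (double loop)
brute_force_metrics <- function(truth, predicted, labels) {
  n <- length(truth)
  K <- length(labels)
  conf <- matrix(0L, K, K, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    r <- which(labels == truth[i]); cc <- which(labels == predicted[i])
    conf[r, cc] <- conf[r, cc] + 1L
  }
  acc <- 100 * sum(diag(conf)) / n
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- conf[k, k]
    predk <- sum(conf[, k]); truek <- sum(conf[k, ])
    prec[k] <- if (predk > 0) tp / predk else 0
    rec[k] <- if (truek > 0) tp / truek else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = round(acc, 2), confusion = conf,
       precision = round(100 * prec, 2), recall = round(100 * rec, 2),
       f1 = round(100 * f1, 2))
}

# brute-force occlusal peak counter: rasterize the upper surface into a
# height field and count connected components of near-maximal cells.
# Connectivity has radius 2 so empty raster cells (sparse parametric
# sampling on thin crowns) cannot split one smooth bump in two.
count_occlusal_peaks <- function(mesh, ngrid = 20L, level = 0.90) {
  v <- mesh$vertices
  top <- v[v[, 3L] > 0, , drop = FALSE]
  gx <- cut(top[, 1L], ngrid, labels = FALSE)
  gy <- cut(top[, 2L], ngrid, labels = FALSE)
  hf <- matrix(-Inf, ngrid, ngrid)
  for (i in seq_len(nrow(top)))
    hf[gx[i], gy[i]] <- max(hf[gx[i], gy[i]], top[i, 3L])
  thresh <- level * max(top[, 3L])
  mask <- is.finite(hf) & hf >= thresh
  lab <- matrix(0L, ngrid, ngrid)
  comp <- 0L
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    comp <- comp + 1L
    stack <- list(c(i, j)); lab[i, j] <- comp
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -2:2) for (dj in -2:2) {
        ni <- cur[1L] + di; nj <- cur[2L] + dj
        if (ni >= 1L && ni <= ngrid && nj >= 1L && nj <= ngrid &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- comp
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  comp
}

# maximum deviation of pairwise inter-vertex distances between two meshes
# with identical topology, over a deterministic sample of vertex pairs
max_pairwise_distance_dev <- function(m1, m2, n_pairs = 2000L, seed = 1L) {
  set.seed(seed)
  n <- nrow(m1$vertices)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  d1 <- sqrt(rowSums((m1$vertices[i, ] - m1$vertices[j, ])^2))
  d2 <- sqrt(rowSums((m2$vertices[i, ] - m2$vertices[j, ])^2))
  max(abs(d1 - d2))
}
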