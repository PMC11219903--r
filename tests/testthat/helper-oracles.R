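# Independent brute-force oracles, coded directly from the definitions and
# kept free of the package's internals.

# Mean-shift filter: per-pixel iteration over the full grid.
oracle_meanshift <- function(bands, spatialr, ranger, max_iter = 100,
                             conv = 0.1) {
  nr <- nrow(bands[[1]]); nc <- ncol(bands[[1]]); nb <- length(bands)
  out <- lapply(bands, function(b) b * NA_real_)
  for (i in 1:nr) for (j in 1:nc) {
    pr <- i; pc <- j
    v <- vapply(bands, function(b) b[i, j], 0)
    for (it in 1:max_iter) {
      r0 <- max(1, ceiling(pr - spatialr)); r1 <- min(nr, floor(pr + spatialr))
      c0 <- max(1, ceiling(pc - spatialr)); c1 <- min(nc, floor(pc + spatialr))
      acc <- numeric(nb); sr <- 0; sc <- 0; cnt <- 0
      for (cc in c0:c1) for (rr in r0:r1) {
        w <- vapply(bands, function(b) b[rr, cc], 0)
        if (sum((w - v)^2) <= ranger^2) {
          acc <- acc + w; sr <- sr + rr; sc <- sc + cc; cnt <- cnt + 1
        }
      }
      nv <- acc / cnt
      mv <- sqrt(sum((nv - v)^2))
      v <- nv; pr <- sr / cnt; pc <- sc / cnt
      if (mv < conv) break
    }
    for (b in 1:nb) out[[b]][i, j] <- v[b]
  }
  out
}

# 4-connected clustering of modes with pairwise link distance <= ranger,
# labels in row-major discovery order.
oracle_cluster <- function(modes, ranger) {
  nr <- nrow(modes[[1]]); nc <- ncol(modes[[1]])
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  vec <- function(i, j) vapply(modes, function(b) b[i, j], 0)
  for (i in 1:nr) for (j in 1:nc) {
    if (lab[i, j] != 0) next
    nxt <- nxt + 1L
    lab[i, j] <- nxt
    queue <- list(c(i, j))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (lab[q[1], q[2]] != 0) next
        if (sum((vec(p[1], p[2]) - vec(q[1], q[2]))^2) <= ranger^2) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# Iterative small-region merging; means as sum/size (same arithmetic as the
# implementation so exact ties behave identically on integer-valued data).
oracle_merge <- function(labels, bands, minsize) {
  nb <- length(bands)
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(L) sum(labels == L), 0)
    small <- ids[sizes < minsize]
    if (!length(small)) break
    L <- small[which.min(sizes[match(small, ids)])]
    # smallest size; ties by priority-queue order = lowest label id
    cand_sz <- min(sizes[match(small, ids)])
    L <- min(small[sizes[match(small, ids)] == cand_sz])
    msum <- function(M) vapply(1:nb, function(b) sum(bands[[b]][labels == M]), 0)
    szL <- sum(labels == L)
    nbrs <- integer(0)
    idx <- which(labels == L, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- idx[k, ] + d
        if (q[1] < 1 || q[1] > nrow(labels) || q[2] < 1 || q[2] > ncol(labels)) next
        M <- labels[q[1], q[2]]
        if (M != 0 && M != L) nbrs <- c(nbrs, M)
      }
    }
    nbrs <- sort(unique(nbrs))
    if (!length(nbrs)) {
      # isolated region: cannot merge; exclude it from further consideration
      labels[labels == L] <- -L
      next
    }
    dist <- vapply(nbrs, function(M) {
      sum((msum(L) / szL - msum(M) / sum(labels == M))^2)
    }, 0)
    best <- nbrs[dist == min(dist)][1]
    labels[labels == L] <- best
  }
  labels[labels < 0] <- -labels[labels < 0]
  # renumber in row-major discovery order
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  map <- list()
  for (i in 1:nrow(labels)) for (j in 1:ncol(labels)) {
    L <- labels[i, j]
    if (L == 0) next
    key <- as.character(L)
    if (is.null(map[[key]])) { nxt <- nxt + 1L; map[[key]] <- nxt }
    out[i, j] <- map[[key]]
  }
  out
}

# Population zonal statistics by explicit per-pixel grouping.
oracle_zonal <- function(labels, band) {
  ids <- sort(unique(labels[labels > 0]))
  data.frame(
    zone_id = ids,
    mean = vapply(ids, function(L) mean(band[labels == L]), 0),
    sd = vapply(ids, function(L) {
      v <- band[labels == L]
      sqrt(mean((v - mean(v))^2))
    }, 0))
}

# Nearest-neighbour resampling by brute-force nearest-centre search with
# upper-left tie-break.
oracle_nn_resample <- function(src, src_ps, src_xmin, src_ymax,
                               tgt_nr, tgt_nc, tgt_ps, tgt_xmin, tgt_ymax) {
  out <- matrix(NA_real_, tgt_nr, tgt_nc)
  for (i in 1:tgt_nr) for (j in 1:tgt_nc) {
    x <- tgt_xmin + (j - 0.5) * tgt_ps
    y <- tgt_ymax - (i - 0.5) * tgt_ps
    # a target centre outside the source footprint is nodata
    if (x < src_xmin || x > src_xmin + ncol(src) * src_ps ||
        y > src_ymax || y < src_ymax - nrow(src) * src_ps) next
    best <- c(Inf, NA, NA)
    for (si in 1:nrow(src)) for (sj in 1:ncol(src)) {
      sx <- src_xmin + (sj - 0.5) * src_ps
      sy <- src_ymax - (si - 0.5) * src_ps
      d <- sqrt((x - sx)^2 + (y - sy)^2)
      if (d < best[1] - 1e-12) best <- c(d, si, sj)
    }
    if (is.finite(best[1])) out[i, j] <- src[best[2], best[3]]
  }
  out
}

# TIN interpolation oracle: per-cell point-in-triangle + barycentric weights
# over all point triples forming Delaunay triangles (empty circumcircle).
oracle_tin <- function(pts, gx, gy) {
  n <- nrow(pts)
  tris <- list()
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    p <- pts[c(a, b, cc), ]
    det <- (p$x[2] - p$x[1]) * (p$y[3] - p$y[1]) -
      (p$x[3] - p$x[1]) * (p$y[2] - p$y[1])
    if (abs(det) < 1e-12) next
    # circumcircle test
    ax <- p$x[1]; ay <- p$y[1]
    D <- 2 * (ax * (p$y[2] - p$y[3]) + p$x[2] * (p$y[3] - ay) +
                p$x[3] * (ay - p$y[2]))
    ux <- ((ax^2 + ay^2) * (p$y[2] - p$y[3]) +
             (p$x[2]^2 + p$y[2]^2) * (p$y[3] - ay) +
             (p$x[3]^2 + p$y[3]^2) * (ay - p$y[2])) / D
    uy <- ((ax^2 + ay^2) * (p$x[3] - p$x[2]) +
             (p$x[2]^2 + p$y[2]^2) * (ax - p$x[3]) +
             (p$x[3]^2 + p$y[3]^2) * (p$x[2] - ax)) / D
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(1:n, c(a, b, cc))
    if (any((pts$x[others] - ux)^2 + (pts$y[others] - uy)^2 < r2 - 1e-9)) next
    tris[[length(tris) + 1]] <- c(a, b, cc)
  }
  out <- matrix(NA_real_, length(gy), length(gx))
  for (i in seq_along(gy)) for (j in seq_along(gx)) {
    px <- gx[j]; py <- gy[i]
    for (t in tris) {
      p <- pts[t, ]
      det <- (p$y[2] - p$y[3]) * (p$x[1] - p$x[3]) +
        (p$x[3] - p$x[2]) * (p$y[1] - p$y[3])
      l1 <- ((p$y[2] - p$y[3]) * (px - p$x[3]) +
               (p$x[3] - p$x[2]) * (py - p$y[3])) / det
      l2 <- ((p$y[3] - p$y[1]) * (px - p$x[3]) +
               (p$x[1] - p$x[3]) * (py - p$y[3])) / det
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        out[i, j] <- l1 * p$z[1] + l2 * p$z[2] + l3 * p$z[3]
        break
      }
    }
  }
  out
}

# Build a raster_stack from a named list of matrices (map convention).
make_stack <- function(..., pixel_size = 1, xmin = 0, ymax = NULL) {
  raster_stack(list(...), pixel_size = pixel_size, xmin = xmin, ymax = ymax)
}

# Small scene config for fast tests.
small_scene_config <- function(...) {
  args <- utils::modifyList(
    list(extent_m = c(0.256, 0.256), pixel_size_m = 0.002,
         patch_scale_m = 0.04,
         layout = list(n_replicates = 2, n_mixtures = 2,
                       n_subplots = 4, subplot_size_m = 0.12),
         label_size_range_m = c(0.02, 0.06)),
    list(...))
  do.call(scene_config, args)
}
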