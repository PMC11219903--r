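# Polygon utilities on plain coordinate rings.
#
# A polygon is a list with element `rings`: a list of n x 2 matrices (x, y),
# open (first vertex not repeated). Ring 1 is the outer boundary; further
# rings are holes. Orientation is not enforced; areas are taken as absolute
# values with holes subtracted.

#' Construct a polygon from coordinate rings
#' @param rings a single n x 2 matrix or a list of them (first = outer ring,
#'   remaining = holes), vertices in map coordinates, not closed.
#' @export
polygon_rings <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1,
            all(vapply(rings, function(r) is.matrix(r) && ncol(r) == 2 &&
                         nrow(r) >= 3, TRUE)))
  structure(list(rings = rings), class = "cm_polygon")
}

#' Axis-aligned rectangle as a polygon
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  polygon_rings(cbind(c(xmin, xmax, xmax, xmin),
                      c(ymin, ymin, ymax, ymax)))
}

# Signed shoelace area of one open ring.
.ring_signed_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

.ring_length <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

#' Polygon area (outer ring minus holes)
#' @param p a `cm_polygon`.
#' @export
polygon_area <- function(p) {
  a <- abs(.ring_signed_area(p$rings[[1]]))
  if (length(p$rings) > 1) {
    a <- a - sum(vapply(p$rings[-1], function(r) abs(.ring_signed_area(r)), 0))
  }
  a
}

#' Polygon perimeter (outer plus inner boundary length)
#' @param p a `cm_polygon`.
#' @export
polygon_perimeter <- function(p) {
  sum(vapply(p$rings, .ring_length, 0))
}

#' Maximum distance between two polygon vertices
#' @param p a `cm_polygon`.
#' @export
polygon_dmax <- function(p) {
  v <- do.call(rbind, p$rings)
  .max_pairwise_dist(v)
}

# Max pairwise distance via convex hull (exact: the diameter is attained at
# hull vertices).
.max_pairwise_dist <- function(v) {
  v <- unique(v)
  if (nrow(v) < 2) return(0)
  if (nrow(v) > 3) v <- v[grDevices::chull(v), , drop = FALSE]
  d <- stats::dist(v)
  max(d)
}

#' Even-odd point-in-polygon test
#' @param px,py point coordinates (vectors).
#' @param p a `cm_polygon`. Points inside a hole are outside.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, p) {
  crossings <- rep(0L, length(px))
  for (r in p$rings) {
    x <- r[, 1]; y <- r[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      x1 <- x[j[k]]; y1 <- y[j[k]]; x2 <- x[k]; y2 <- y[k]
      hit <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      crossings <- crossings + as.integer(hit)
    }
  }
  crossings %% 2L == 1L
}

# Per-cell overlap areas between the grid cells of `grid` (a raster_stack or
# grid_spec) and an axis-aligned rectangle. Returns a list with the covered
# row/col index ranges and a matrix of overlap areas (map units^2). Exact for
# the pixel-aligned geometry used throughout: any polygon that is a union of
# grid cells intersects a rectangle with area equal to the sum of its cells'
# rectangle overlaps.
.cell_rect_overlap <- function(grid, xmin, xmax, ymin, ymax) {
  d <- rs_dim(grid); s <- grid$pixel_size
  # columns whose cell interval [x0, x0+s) intersects [xmin, xmax]
  j0 <- max(1L, floor((xmin - grid$xmin) / s) + 1L)
  j1 <- min(d[2], ceiling((xmax - grid$xmin) / s))
  i0 <- max(1L, floor((grid$ymax - ymax) / s) + 1L)
  i1 <- min(d[1], ceiling((grid$ymax - ymin) / s))
  if (j0 > j1 || i0 > i1) {
    return(list(rows = integer(0), cols = integer(0),
                area = matrix(0, 0, 0)))
  }
  cols <- j0:j1; rows <- i0:i1
  cx0 <- grid$xmin + (cols - 1) * s
  cy1 <- grid$ymax - (rows - 1) * s   # cell top
  wx <- pmax(0, pmin(cx0 + s, xmax) - pmax(cx0, xmin))
  wy <- pmax(0, pmin(cy1, ymax) - pmax(cy1 - s, ymin))
  list(rows = rows, cols = cols, area = outer(wy, wx))
}

#' Trace segment/label grid boundaries into polygons
#'
#' Converts an integer label grid into one polygon per label by tracing the
#' boundaries of 4-connected pixel blocks in map coordinates. Holes are
#' preserved as inner rings. Label 0 is treated as nodata and receives no
#' polygon. At corner configurations where two diagonal pixels share the
#' label, boundaries pinch through the corner without crossing.
#'
#' @param labels integer matrix (0 = nodata, >= 1 = region id).
#' @param pixel_size pixel size in map units.
#' @param xmin,ymax upper-left corner map coordinates.
#' @return named list of `cm_polygon` objects, one per label id present.
#' @export
vectorize_labels <- function(labels, pixel_size = 1, xmin = 0,
                             ymax = nrow(labels) * pixel_size) {
  ids <- sort(unique(labels[labels > 0]))
  out <- vector("list", length(ids))
  names(out) <- as.character(ids)
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  for (k in seq_along(ids)) {
    id <- ids[k]
    reg <- pad == id
    out[[k]] <- .trace_region(reg, pixel_size, xmin, ymax)
  }
  out
}

# Trace one padded logical region into rings. Corner lattice coordinates:
# corner (r, c) with r in 0..nr, c in 0..nc of the unpadded grid sits at map
# (xmin + c*s, ymax - r*s). Directed edges keep the region on the left when
# viewed in array coordinates (row increasing downward).
.trace_region <- function(reg, s, xmin, ymax) {
  nr <- nrow(reg) - 2; nc <- ncol(reg) - 2
  core <- reg[2:(nr + 1), 2:(nc + 1), drop = FALSE]
  up    <- reg[1:nr, 2:(nc + 1), drop = FALSE]
  down  <- reg[3:(nr + 2), 2:(nc + 1), drop = FALSE]
  left  <- reg[2:(nr + 1), 1:nc, drop = FALSE]
  right <- reg[2:(nr + 1), 3:(nc + 2), drop = FALSE]
  # boundary edges per pixel (i, j), corners keyed as r * (nc+1) + c
  key <- function(r, c) r * (nc + 1L) + c
  es_from <- integer(0); es_to <- integer(0)
  idx <- which(core & !up, arr.ind = TRUE)
  if (nrow(idx)) { es_from <- c(es_from, key(idx[,1] - 1L, idx[,2] - 1L))
                   es_to   <- c(es_to,   key(idx[,1] - 1L, idx[,2])) }
  idx <- which(core & !right, arr.ind = TRUE)
  if (nrow(idx)) { es_from <- c(es_from, key(idx[,1] - 1L, idx[,2]))
                   es_to   <- c(es_to,   key(idx[,1], idx[,2])) }
  idx <- which(core & !down, arr.ind = TRUE)
  if (nrow(idx)) { es_from <- c(es_from, key(idx[,1], idx[,2]))
                   es_to   <- c(es_to,   key(idx[,1], idx[,2] - 1L)) }
  idx <- which(core & !left, arr.ind = TRUE)
  if (nrow(idx)) { es_from <- c(es_from, key(idx[,1], idx[,2] - 1L))
                   es_to   <- c(es_to,   key(idx[,1] - 1L, idx[,2] - 1L)) }
  n_e <- length(es_from)
  # order outgoing edges by start corner for O(1) lookup
  ord <- order(es_from)
  es_from <- es_from[ord]; es_to <- es_to[ord]
  first <- match(unique(es_from), es_from)
  start_of <- stats::setNames(first, unique(es_from))
  count_of <- stats::setNames(tabulate(match(es_from, unique(es_from))),
                              unique(es_from))
  used <- rep(FALSE, n_e)
  dirs <- cbind((es_to - es_from) %/% (nc + 1L),       # dr
                (es_to - es_from) %% (nc + 1L))
  dirs[, 2] <- ifelse(dirs[, 2] > 1, dirs[, 2] - (nc + 1L), dirs[, 2]) # dc
  rings <- list()
  for (e0 in seq_len(n_e)) {
    if (used[e0]) next
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, es_from[e])
      nxt_corner <- es_to[e]
      if (nxt_corner == es_from[e0] && length(path) >= 2) break
      i0 <- start_of[as.character(nxt_corner)]
      cnt <- count_of[as.character(nxt_corner)]
      cand <- i0:(i0 + cnt - 1L)
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break  # closed back at a pinch corner
      if (length(cand) == 1) {
        e <- cand
      } else {
        # pinch corner: prefer the sharpest right turn relative to the
        # incoming direction so rings do not cross themselves
        din <- dirs[e, ]
        # right turn of (dr, dc) is (dc, -dr) in array coords
        right_turn <- c(din[2], -din[1])
        score <- vapply(cand, function(ce) {
          dd <- dirs[ce, ]
          if (all(dd == right_turn)) 3L
          else if (all(dd == din)) 2L
          else 1L
        }, 0L)
        e <- cand[which.max(score)]
      }
    }
    r <- path %/% (nc + 1L); c <- path %% (nc + 1L)
    rings[[length(rings) + 1L]] <- cbind(xmin + c * s, ymax - r * s)
  }
  # outer ring = largest absolute area
  areas <- vapply(rings, function(r) abs(.ring_signed_area(r)), 0)
  polygon_rings(rings[order(-areas)])
}
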