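# Per-segment learning database: zonal statistics over all stack variables
# plus polygon shape indices.

#' Zonal mean and standard deviation per segment or polygon
#'
#' For every zone and band, the mean and population (divide-by-n) standard
#' deviation of the covered pixels. Zones are either the labels of a
#' `segment_map` (cell label equals zone) or polygons (cell-centre
#' containment; a centre exactly on the boundary counts as inside). Zones
#' covering no pixel are dropped with a warning.
#'
#' @param zones a `segment_map`, an integer label matrix, or a list of
#'   `cm_polygon`s / data frame of rectangles (`xmin`, `xmax`, `ymin`,
#'   `ymax`).
#' @param stack a `raster_stack` co-registered with the zones.
#' @return data frame keyed by `zone_id` with `n_pixels` and
#'   `<band>_mean` / `<band>_sd` columns.
#' @export
zonal_stats <- function(zones, stack) {
  if (inherits(zones, "segment_map")) {
    if (!isTRUE(all.equal(dim(zones$labels), rs_dim(stack)))) {
      stop("zones and stack are not co-registered")
    }
    labels <- zones$labels
  } else if (is.matrix(zones)) {
    if (!isTRUE(all.equal(dim(zones), rs_dim(stack)))) {
      stop("zones and stack are not co-registered")
    }
    labels <- zones
  } else {
    labels <- .rasterize_zones(zones, stack)
    n_zones <- if (is.data.frame(zones)) nrow(zones) else length(zones)
  }
  a <- rs_array(stack)
  d <- dim(a)
  labels[!stack$mask] <- 0L
  K <- if (exists("n_zones", inherits = FALSE)) n_zones else max(labels, 0L)
  if (K == 0 || max(labels) == 0) stop("no zones cover any valid pixel")
  sums <- cpp_zonal_sums(labels, as.vector(a), d[1], d[2], d[3], K)
  n <- sums[, 1]
  keep <- n > 0
  if (any(!keep)) warning(sum(!keep), " zone(s) with 0 pixels dropped")
  nb <- d[3]
  mean_m <- sums[, 1 + seq_len(nb), drop = FALSE] / n
  var_m <- sums[, 1 + nb + seq_len(nb), drop = FALSE] / n - mean_m^2
  var_m[var_m < 0] <- 0
  sd_m <- sqrt(var_m)
  out <- data.frame(zone_id = seq_len(K), n_pixels = n)
  for (b in seq_len(nb)) {
    out[[paste0(names(stack$bands)[b], "_mean")]] <- mean_m[, b]
    out[[paste0(names(stack$bands)[b], "_sd")]] <- sd_m[, b]
  }
  out[keep, , drop = FALSE]
}

# Rasterize polygon zones (list of cm_polygon or rectangle data frame) by
# cell-centre containment; later zones overwrite earlier at overlaps.
.rasterize_zones <- function(zones, stack) {
  d <- rs_dim(stack)
  labels <- matrix(0L, d[1], d[2])
  ctr <- rs_centers(stack)
  if (is.data.frame(zones)) {
    for (r in seq_len(nrow(zones))) {
      jj <- which(ctr$x >= zones$xmin[r] & ctr$x <= zones$xmax[r])
      ii <- which(ctr$y >= zones$ymin[r] & ctr$y <= zones$ymax[r])
      labels[ii, jj] <- r
    }
  } else {
    for (r in seq_along(zones)) {
      p <- zones[[r]]
      v <- do.call(rbind, p$rings)
      jj <- which(ctr$x >= min(v[, 1]) & ctr$x <= max(v[, 1]))
      ii <- which(ctr$y >= min(v[, 2]) & ctr$y <= max(v[, 2]))
      if (!length(jj) || !length(ii)) next
      px <- rep(ctr$x[jj], each = length(ii))
      py <- rep(ctr$y[ii], times = length(jj))
      inside <- point_in_polygon(px, py, p)
      sub <- labels[ii, jj, drop = FALSE]
      sub[matrix(inside, length(ii), length(jj))] <- r
      labels[ii, jj] <- sub
    }
  }
  labels
}

#' Shape indices of a polygon
#'
#' A (area), P (perimeter: outer plus inner boundary), P/A, P/sqrt(A),
#' Sphericity = 2*sqrt(pi*A)/P, ShapeIndex = P/(2*sqrt(pi*A)) (the exact
#' reciprocal of the sphericity), Dmax (maximum distance between two polygon
#' vertices), Dmax/A, Dmax/sqrt(A).
#'
#' @param p a `cm_polygon` (holes allowed) or an n x 2 vertex matrix.
#' @return named numeric vector of the nine indices.
#' @export
shape_indices <- function(p) {
  if (is.matrix(p)) p <- polygon_rings(p)
  A <- polygon_area(p)
  if (A <= 0) stop("zero-area polygon")
  P <- polygon_perimeter(p)
  Dmax <- polygon_dmax(p)
  sph <- 2 * sqrt(pi * A) / P
  c(A = A, P = P, P_A = P / A, P_sqrtA = P / sqrt(A),
    Sphericity = sph, ShapeIndex = 1 / sph,
    Dmax = Dmax, Dmax_A = Dmax / A, Dmax_sqrtA = Dmax / sqrt(A))
}

# Grid-based shape statistics for every label of a segment map: area from
# pixel counts, perimeter from boundary edge counts, Dmax from the convex
# hull of boundary-pixel corners. Identical to shape_indices() applied to
# vectorize() output (the staircase boundary), but without ring tracing.
.grid_shape_stats <- function(labels, pixel_size, xmin, ymax) {
  K <- max(labels, 0L)
  if (K == 0) {
    return(data.frame(zone_id = integer(0)))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  npix <- tabulate(labels, nbins = K)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  edge_ct <- integer(K)
  bnd <- matrix(FALSE, nr, nc)
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
    diff <- core > 0 & nb != core
    edge_ct <- edge_ct + tabulate(core[diff], nbins = K)
    bnd <- bnd | diff
  }
  # Dmax per label from boundary pixel corners
  idx <- which(bnd, arr.ind = TRUE)
  lab <- labels[bnd]
  cx0 <- xmin + (idx[, 2] - 1) * pixel_size
  cy1 <- ymax - (idx[, 1] - 1) * pixel_size
  corners <- rbind(cbind(lab, cx0, cy1),
                   cbind(lab, cx0 + pixel_size, cy1),
                   cbind(lab, cx0, cy1 - pixel_size),
                   cbind(lab, cx0 + pixel_size, cy1 - pixel_size))
  split_idx <- split(seq_len(nrow(corners)), corners[, 1])
  dmax <- numeric(K)
  for (nm in names(split_idx)) {
    v <- corners[split_idx[[nm]], 2:3, drop = FALSE]
    dmax[as.integer(nm)] <- .max_pairwise_dist(v)
  }
  A <- npix * pixel_size^2
  P <- edge_ct * pixel_size
  sph <- 2 * sqrt(pi * A) / P
  data.frame(zone_id = seq_len(K), A = A, P = P, P_A = P / A,
             P_sqrtA = P / sqrt(A), Sphericity = sph, ShapeIndex = 1 / sph,
             Dmax = dmax, Dmax_A = dmax / A, Dmax_sqrtA = dmax / sqrt(A))
}

#' Build the per-segment feature table
#'
#' Zonal mean/sd of every stack band plus the nine shape indices, keyed by
#' segment id, with plot/replicate identifiers attached.
#'
#' @param segmap a `segment_map`.
#' @param stack the full analysis `raster_stack`.
#' @param plot_id,replicate identifiers stored on every row.
#' @return data frame, one row per segment.
#' @export
build_feature_table <- function(segmap, stack, plot_id = NA_character_,
                                replicate = NA_character_) {
  zs <- zonal_stats(segmap, stack)
  sh <- .grid_shape_stats(segmap$labels, segmap$pixel_size, segmap$xmin,
                          segmap$ymax)
  ft <- merge(zs, sh, by = "zone_id", sort = TRUE)
  names(ft)[names(ft) == "zone_id"] <- "segment_id"
  ft$plot_id <- plot_id
  ft$replicate <- replicate
  ft
}

#' Names of the predictor columns in a feature table
#' @param ft a feature table from [build_feature_table()].
#' @export
feature_columns <- function(ft) {
  setdiff(names(ft), c("segment_id", "zone_id", "n_pixels", "plot_id",
                       "replicate", "class", "ref_id", "within"))
}
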