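# Mean-shift segmentation under the spatialr / ranger / minsize
# parameterization, with small-region merging and vectorization.

#' Segmentation parameters
#'
#' @param spatialr spatial neighbourhood radius in pixels (>= 1). The window
#'   is square (Chebyshev distance), matching windowed mean-shift tools.
#' @param ranger spectral range radius in radiometry units (> 0): DN for
#'   8-bit imagery, reflectance for 0-1 imagery.
#' @param minsize minimum region size in pixels kept after clustering;
#'   smaller regions are merged into their spectrally closest neighbour.
#' @param max_iter iteration cap for the mean-shift filter.
#' @param conv_threshold stop when the spectral mode moves less than this.
#' @param tile_size optional tile edge length in pixels; tiles are filtered
#'   with an overlap margin and re-assembled before clustering.
#' @export
segmentation_params <- function(spatialr = 10, ranger = 10, minsize = 30,
                                max_iter = 100, conv_threshold = 0.1,
                                tile_size = NULL) {
  stopifnot(spatialr >= 1, ranger > 0, minsize >= 1, max_iter >= 1,
            conv_threshold > 0)
  if (!is.null(tile_size)) stopifnot(tile_size >= 2 * spatialr)
  structure(list(spatialr = spatialr, ranger = ranger, minsize = minsize,
                 max_iter = max_iter, conv_threshold = conv_threshold,
                 tile_size = tile_size),
            class = "segmentation_params")
}

.seg_bands_array <- function(stack, bands = NULL) {
  if (!is.null(bands)) stack <- rs_subset(stack, bands)
  a <- rs_array(stack)
  if (any(!is.finite(a[rep(stack$mask, length(stack$bands))]))) {
    stop("stack contains non-finite values inside the valid mask")
  }
  a
}

#' Mean-shift filter
#'
#' Iteratively replaces every pixel's spectral vector by the mean of the
#' pixels within Chebyshev spatial distance `spatialr` of its current
#' (floating) position whose Euclidean spectral distance to its current value
#' is at most `ranger`; the position moves to the contributing pixels' mean
#' position. Stops when the value moves less than `conv_threshold` or after
#' `max_iter` iterations.
#'
#' @param stack a `raster_stack` (finite values on one grid).
#' @param params [segmentation_params()].
#' @param bands optional band subset to filter.
#' @return `raster_stack` of converged modes (same band names).
#' @export
meanshift_filter <- function(stack, params, bands = NULL) {
  if (!is.null(bands)) stack <- rs_subset(stack, bands)
  a <- .seg_bands_array(stack)
  d <- dim(a)
  m <- cpp_meanshift_filter(as.vector(a), d[1], d[2], d[3], stack$mask,
                            params$spatialr, params$ranger, params$max_iter,
                            params$conv_threshold)
  modes <- lapply(seq_len(d[3]), function(b) {
    matrix(m[((b - 1) * d[1] * d[2] + 1):(b * d[1] * d[2])], d[1], d[2])
  })
  names(modes) <- names(stack$bands)
  raster_stack(modes, pixel_size = stack$pixel_size, xmin = stack$xmin,
               ymax = stack$ymax, mask = stack$mask)
}

#' Cluster converged modes into labelled regions
#'
#' 4-connected components of pixels whose mode vectors differ by at most
#' `ranger` along each connection receive one label; labels are numbered
#' 1..K in row-major discovery order. Nodata pixels keep label 0.
#'
#' @param modes `raster_stack` of mean-shift modes.
#' @param params [segmentation_params()].
#' @return integer label matrix.
#' @export
cluster_modes <- function(modes, params) {
  a <- rs_array(modes)
  d <- dim(a)
  cpp_cluster_modes(as.vector(a), d[1], d[2], d[3], modes$mask, params$ranger)
}

#' Merge regions smaller than the minimum size
#'
#' Iteratively merges the smallest region below `minsize` into the 4-adjacent
#' region with the nearest mean spectral vector (Euclidean; ties to the lower
#' label id), updating region means after each merge, until every region has
#' at least `minsize` pixels or a single region remains. Regions with no
#' neighbour (isolated by nodata) are kept as is.
#'
#' @param labels integer label matrix (0 = nodata).
#' @param stack `raster_stack` whose bands define the spectral signature.
#' @param minsize minimum region size in pixels.
#' @return relabelled integer matrix (row-major renumbering).
#' @export
merge_small_regions <- function(labels, stack, minsize) {
  a <- rs_array(stack)
  d <- dim(a)
  stopifnot(all(dim(labels) == d[1:2]))
  cpp_merge_small(labels, as.vector(a), d[1], d[2], d[3], as.integer(minsize))
}

#' Vectorize a segment map into polygons
#'
#' One polygon (with holes) per label, tracing 4-connected pixel-block
#' boundaries in map coordinates.
#'
#' @param x a `segment_map` (or integer label matrix with `pixel_size`,
#'   `xmin`, `ymax` supplied).
#' @param pixel_size,xmin,ymax georeference when `x` is a bare matrix.
#' @return named list of `cm_polygon`s keyed by label id.
#' @export
vectorize <- function(x, pixel_size = 1, xmin = 0, ymax = NULL) {
  if (inherits(x, "segment_map")) {
    vectorize_labels(x$labels, x$pixel_size, x$xmin, x$ymax)
  } else {
    if (is.null(ymax)) ymax <- nrow(x) * pixel_size
    vectorize_labels(x, pixel_size, xmin, ymax)
  }
}

#' Segment an analysis stack
#'
#' Composition of [meanshift_filter()], [cluster_modes()] and
#' [merge_small_regions()], optionally tile-wise for the (quadratic-cost)
#' filter stage. Tiles are filtered with an overlap margin of
#' `spatialr * max_iter` pixels (capped at `tile_size / 2`); only core pixels
#' are kept, after which clustering and merging run on the assembled mode
#' grid, so a sufficient margin reproduces the untiled partition exactly.
#'
#' @param stack a `raster_stack`.
#' @param params [segmentation_params()].
#' @param bands optional band subset used for segmentation.
#' @param vectorize_polygons trace polygons now (`TRUE`) or leave them to a
#'   later [vectorize()] call (`FALSE`, default — cheaper for large grids).
#' @return a `segment_map`: list with `labels`, `n_segments`, `modes`,
#'   `params`, `polygons` (or `NULL`) and the georeference.
#' @export
segment_image <- function(stack, params, bands = NULL,
                          vectorize_polygons = FALSE) {
  if (!is.null(bands)) stack <- rs_subset(stack, bands)
  d <- rs_dim(stack)
  ts <- params$tile_size
  if (is.null(ts) || ts >= max(d)) {
    modes <- meanshift_filter(stack, params)
  } else {
    margin <- min(params$spatialr * params$max_iter, floor(ts / 2))
    mode_bands <- lapply(stack$bands, function(b) matrix(NA_real_, d[1], d[2]))
    for (r0 in seq(1, d[1], by = ts)) {
      for (c0 in seq(1, d[2], by = ts)) {
        r1 <- min(d[1], r0 + ts - 1); c1 <- min(d[2], c0 + ts - 1)
        er0 <- max(1, r0 - margin); er1 <- min(d[1], r1 + margin)
        ec0 <- max(1, c0 - margin); ec1 <- min(d[2], c1 + margin)
        sub <- raster_stack(
          lapply(stack$bands, function(b) b[er0:er1, ec0:ec1, drop = FALSE]),
          pixel_size = stack$pixel_size,
          xmin = stack$xmin + (ec0 - 1) * stack$pixel_size,
          ymax = stack$ymax - (er0 - 1) * stack$pixel_size,
          mask = stack$mask[er0:er1, ec0:ec1, drop = FALSE])
        mm <- meanshift_filter(sub, params)
        core_r <- (r0 - er0 + 1):(r1 - er0 + 1)
        core_c <- (c0 - ec0 + 1):(c1 - ec0 + 1)
        for (nm in names(mode_bands)) {
          mode_bands[[nm]][r0:r1, c0:c1] <-
            mm$bands[[nm]][core_r, core_c, drop = FALSE]
        }
      }
    }
    modes <- raster_stack(mode_bands, pixel_size = stack$pixel_size,
                          xmin = stack$xmin, ymax = stack$ymax,
                          mask = stack$mask)
  }
  labels <- cluster_modes(modes, params)
  labels <- merge_small_regions(labels, stack, params$minsize)
  n_seg <- max(labels, 0L)
  out <- structure(list(labels = labels, n_segments = n_seg, modes = modes,
                        params = params, polygons = NULL,
                        pixel_size = stack$pixel_size, xmin = stack$xmin,
                        ymax = stack$ymax),
                   class = "segment_map")
  if (vectorize_polygons) out$polygons <- vectorize(out)
  out
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf(paste0("segment_map: %d segments (spatialr %g, ranger %g, ",
                     "minsize %d), %d x %d px\n"),
              x$n_segments, x$params$spatialr, x$params$ranger,
              x$params$minsize, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}
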