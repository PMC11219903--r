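#' Lightweight in-memory raster stack
#'
#' A `raster_stack` holds one or more co-registered single-band grids as plain
#' numeric matrices together with a minimal georeference: square pixels of
#' size `pixel_size` (map units, metres), an origin at the grid's upper-left
#' corner, rows running top to bottom (map y decreases with row) and columns
#' left to right. Cells are half-open intervals: cell (i, j) covers
#' x in \[xmin + (j-1)s, xmin + js) and y in (ymax - is, ymax - (i-1)s\].
#'
#' @param bands named list of numeric matrices, all with identical dimensions.
#' @param pixel_size pixel edge length in map units (> 0).
#' @param xmin,ymax map coordinates of the upper-left corner of cell (1, 1).
#' @param mask optional logical matrix, `TRUE` where data are valid; defaults
#'   to all valid. `NA` in any band also marks a cell invalid.
#' @param domain optional character scalar or per-band vector describing the
#'   value domain (`"dn_0_255"`, `"reflectance_0_1"`, `"meters"`, `"index"`).
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(bands, pixel_size, xmin = 0, ymax = NULL,
                         mask = NULL, domain = NULL) {
  if (is.matrix(bands)) bands <- list(band_1 = bands)
  stopifnot(is.list(bands), length(bands) >= 1)
  if (is.null(names(bands)) || anyDuplicated(names(bands)) ||
      any(!nzchar(names(bands)))) {
    stop("bands must be uniquely named")
  }
  dims <- vapply(bands, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all bands must share the same dimensions")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar")
  }
  nr <- dims[1, 1]; nc <- dims[2, 1]
  if (is.null(ymax)) ymax <- nr * pixel_size
  if (is.null(mask)) {
    mask <- matrix(TRUE, nr, nc)
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == c(nr, nc)))
  }
  na_any <- Reduce(`|`, lapply(bands, is.na))
  mask <- mask & !na_any
  if (!is.null(domain)) {
    if (length(domain) == 1) domain <- rep(domain, length(bands))
    names(domain) <- names(bands)
  }
  structure(list(bands = bands, pixel_size = pixel_size,
                 xmin = xmin, ymax = ymax, mask = mask, domain = domain),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- rs_dim(x)
  cat(sprintf("raster_stack: %d x %d px, %d band(s), pixel %g m\n",
              d[1], d[2], length(x$bands), x$pixel_size))
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + d[2] * x$pixel_size,
              x$ymax - d[1] * x$pixel_size, x$ymax))
  invisible(x)
}

#' Dimensions of a raster stack
#' @param x a `raster_stack`.
#' @return integer `c(nrow, ncol)`.
#' @export
rs_dim <- function(x) dim(x$bands[[1]])

#' Extract one band as a matrix
#' @param x a `raster_stack`.
#' @param name band name or index.
#' @export
rs_band <- function(x, name) {
  b <- x$bands[[name]]
  if (is.null(b)) stop("no such band: ", name)
  b
}

#' Add or replace bands
#' @param x a `raster_stack`.
#' @param ... named matrices (or a single named list) to add.
#' @param domain optional domain tag(s) for the new bands.
#' @export
rs_add_band <- function(x, ..., domain = NULL) {
  new <- list(...)
  if (length(new) == 1 && is.list(new[[1]]) && !is.matrix(new[[1]])) {
    new <- new[[1]]
  }
  for (nm in names(new)) {
    stopifnot(all(dim(new[[nm]]) == rs_dim(x)))
    x$bands[[nm]] <- new[[nm]]
    if (!is.null(domain)) x$domain[nm] <- domain
  }
  na_any <- Reduce(`|`, lapply(x$bands, is.na))
  x$mask <- x$mask & !na_any
  x
}

#' Subset bands of a stack
#' @param x a `raster_stack`.
#' @param names character vector of band names to keep.
#' @export
rs_subset <- function(x, names) {
  miss <- setdiff(names, names(x$bands))
  if (length(miss)) stop("missing bands: ", paste(miss, collapse = ", "))
  x$bands <- x$bands[names]
  if (!is.null(x$domain)) x$domain <- x$domain[names]
  x
}

#' Map coordinates of cell centers
#' @param x a `raster_stack` (or grid spec with the same fields).
#' @return list with vectors `x` (per column) and `y` (per row).
#' @export
rs_centers <- function(x) {
  d <- rs_dim(x); s <- x$pixel_size
  list(x = x$xmin + (seq_len(d[2]) - 0.5) * s,
       y = x$ymax - (seq_len(d[1]) - 0.5) * s)
}

#' Stack bands as a 3-D array (row, col, band)
#' @param x a `raster_stack`.
#' @export
rs_array <- function(x) {
  d <- rs_dim(x)
  array(unlist(x$bands, use.names = FALSE), dim = c(d[1], d[2], length(x$bands)),
        dimnames = list(NULL, NULL, names(x$bands)))
}

# Grid specification without data; used as an alignment target.
#' Describe a target grid
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel_size pixel size in map units.
#' @param xmin,ymax upper-left corner map coordinates.
#' @export
grid_spec <- function(nrow, ncol, pixel_size, xmin = 0, ymax = nrow * pixel_size) {
  structure(list(bands = list(g = matrix(NA_real_, nrow, ncol)),
                 pixel_size = pixel_size, xmin = xmin, ymax = ymax,
                 mask = matrix(TRUE, nrow, ncol), domain = NULL),
            class = "raster_stack")
}

# Nearest source index along one axis for target coordinates `coord`
# (cell-center positions). `origin` is the source coordinate of index 0 and
# `step` the signed per-index increment. Ties (coordinate exactly between two
# source centers) are broken toward the smaller index, i.e. the upper-left
# source cell.
.nearest_index <- function(coord, origin, step, n) {
  t <- (coord - origin) / step          # position in source cell units
  i <- floor(t) + 1L
  tie <- abs(t - round(t)) < 1e-9
  i[tie] <- pmax(1L, as.integer(round(t[tie])))
  i[i < 1L | i > n] <- NA_integer_
  i
}

#' Align rasters onto a common grid by nearest-neighbour resampling
#'
#' Every input raster is resampled onto `target` by nearest-neighbour lookup
#' of the source cell whose center is closest to each target cell center.
#' Distance ties are broken toward the upper-left source cell. The outputs are
#' stacked into one `raster_stack`; duplicate band names are suffixed.
#'
#' @param rasters a `raster_stack` or list of them, georeferenced in one frame.
#' @param target a `raster_stack` or [grid_spec()] defining the output grid.
#' @return a `raster_stack` on the target grid.
#' @export
align_rasters <- function(rasters, target) {
  if (inherits(rasters, "raster_stack")) rasters <- list(rasters)
  d <- rs_dim(target); s <- target$pixel_size
  cx <- target$xmin + (seq_len(d[2]) - 0.5) * s
  cy <- target$ymax - (seq_len(d[1]) - 0.5) * s
  out <- list(); dom <- character(0)
  mask <- matrix(TRUE, d[1], d[2])
  for (r in rasters) {
    sd <- rs_dim(r)
    jj <- .nearest_index(cx, r$xmin, r$pixel_size, sd[2])
    ii <- .nearest_index(cy, r$ymax, -r$pixel_size, sd[1])
    if (all(is.na(jj)) || all(is.na(ii))) {
      stop("raster extent does not overlap the target grid")
    }
    ok_i <- !is.na(ii); ok_j <- !is.na(jj)
    for (nm in names(r$bands)) {
      m <- matrix(NA_real_, d[1], d[2])
      m[ok_i, ok_j] <- r$bands[[nm]][ii[ok_i], jj[ok_j], drop = FALSE]
      vm <- matrix(FALSE, d[1], d[2])
      vm[ok_i, ok_j] <- r$mask[ii[ok_i], jj[ok_j], drop = FALSE]
      out_nm <- nm
      k <- 1L
      while (out_nm %in% names(out)) { k <- k + 1L; out_nm <- paste0(nm, "_", k) }
      out[[out_nm]] <- m
      mask <- mask & (vm | is.na(m))   # cells never covered stay invalid below
      mask[is.na(m)] <- FALSE
      if (!is.null(r$domain)) dom[out_nm] <- unname(r$domain[nm])
    }
  }
  raster_stack(out, pixel_size = s, xmin = target$xmin, ymax = target$ymax,
               mask = mask, domain = if (length(dom)) dom else NULL)
}

#' Write a single band to an ESRI ASCII grid file
#' @param x a `raster_stack`.
#' @param band band name.
#' @param path output file path.
#' @param nodata nodata sentinel written for masked cells.
#' @export
write_asc <- function(x, band, path, nodata = -9999) {
  m <- rs_band(x, band)
  m[!x$mask | is.na(m)] <- nodata
  d <- dim(m)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", x$xmin),
           sprintf("yllcorner %.10g", x$ymax - d[1] * x$pixel_size),
           sprintf("cellsize %.10g", x$pixel_size),
           sprintf("NODATA_value %.10g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file as a one-band raster stack
#' @param path file path.
#' @param band name for the band.
#' @export
read_asc <- function(path, band = "band_1") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          tolower(vapply(kv, `[`, "", 1)))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  nd <- vals[["nodata_value"]]
  mask <- m != nd
  m[!mask] <- NA_real_
  raster_stack(stats::setNames(list(m), band), pixel_size = vals[["cellsize"]],
               xmin = vals[["xllcorner"]],
               ymax = vals[["yllcorner"]] + nrow(m) * vals[["cellsize"]],
               mask = mask)
}
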