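# Preprocessing: terrain interpolation, canopy height, colour transform,
# vegetation indices, and stacking of the per-sensor analysis raster.

#' Interpolate a digital terrain model from ground points (TIN)
#'
#' Builds a Delaunay triangulation of the surveyed ground points and linearly
#' (barycentrically) interpolates elevations at every cell center of the
#' target grid. Cells outside the convex hull are extrapolated from the plane
#' of the triangle adjacent to the nearest hull edge and flagged.
#'
#' @param points data frame with columns `x`, `y`, `z` (map units / metres);
#'   at least 3 non-collinear points.
#' @param target a `raster_stack` or [grid_spec()] defining the output grid.
#' @return one-band `raster_stack` (`dtm`, metres) with a logical attribute
#'   `extrapolated` marking outside-hull cells.
#' @export
compute_dtm_tin <- function(points, target) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 ground points")
  dd <- suppressWarnings(deldir::deldir(points$x, points$y, suppressMsge = TRUE))
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0) stop("degenerate triangulation: ground points are collinear")
  ctr <- rs_centers(target)
  d <- rs_dim(target)
  gx <- rep(ctr$x, each = d[1]); gy <- rep(ctr$y, times = d[2])
  z <- rep(NA_real_, length(gx))
  # plane coefficients per triangle and barycentric containment
  tris <- lapply(tl, function(tt) {
    p <- points[tt$ptNum, ]
    A <- cbind(1, p$x, p$y)
    coef <- tryCatch(solve(A, p$z), error = function(e) NULL)
    list(x = p$x, y = p$y, z = p$z, coef = coef, pts = tt$ptNum)
  })
  eps <- 1e-9
  for (tr in tris) {
    if (is.null(tr$coef)) next
    todo <- which(is.na(z))
    if (!length(todo)) break
    b <- .barycentric(gx[todo], gy[todo], tr$x, tr$y)
    inside <- b[, 1] >= -eps & b[, 2] >= -eps & b[, 3] >= -eps
    hit <- todo[inside]
    z[hit] <- tr$coef[1] + tr$coef[2] * gx[hit] + tr$coef[3] * gy[hit]
  }
  extrap <- is.na(z)
  if (any(extrap)) {
    hull <- grDevices::chull(points$x, points$y)
    hx <- points$x[hull]; hy <- points$y[hull]
    n <- length(hull)
    todo <- which(extrap)
    best_d <- rep(Inf, length(todo)); best_e <- rep(NA_integer_, length(todo))
    for (e in seq_len(n)) {
      a <- e; bb <- if (e == n) 1L else e + 1L
      dseg <- .dist_point_segment(gx[todo], gy[todo], hx[a], hy[a], hx[bb], hy[bb])
      upd <- dseg < best_d
      best_d[upd] <- dseg[upd]; best_e[upd] <- e
    }
    for (e in unique(best_e)) {
      a <- hull[e]; bb <- hull[if (e == length(hull)) 1L else e + 1L]
      # triangle of the TIN sharing this hull edge
      tr <- NULL
      for (cand in tris) {
        if (all(c(a, bb) %in% cand$pts) && !is.null(cand$coef)) { tr <- cand; break }
      }
      if (is.null(tr)) tr <- tris[[1]]
      sel <- todo[best_e == e]
      z[sel] <- tr$coef[1] + tr$coef[2] * gx[sel] + tr$coef[3] * gy[sel]
    }
  }
  zm <- matrix(z, d[1], d[2])
  out <- raster_stack(list(dtm = zm), pixel_size = target$pixel_size,
                      xmin = target$xmin, ymax = target$ymax, domain = "meters")
  attr(out, "extrapolated") <- matrix(extrap, d[1], d[2])
  out
}

.barycentric <- function(px, py, tx, ty) {
  det <- (ty[2] - ty[3]) * (tx[1] - tx[3]) + (tx[3] - tx[2]) * (ty[1] - ty[3])
  l1 <- ((ty[2] - ty[3]) * (px - tx[3]) + (tx[3] - tx[2]) * (py - ty[3])) / det
  l2 <- ((ty[3] - ty[1]) * (px - tx[3]) + (tx[1] - tx[3]) * (py - ty[3])) / det
  cbind(l1, l2, 1 - l1 - l2)
}

.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Canopy height model from surface and terrain models
#'
#' CHM = DSM - DTM at pixel level. Negative heights (canopy below terrain,
#' physically impossible) are clamped to zero. Nodata in either input
#' propagates.
#'
#' @param dsm,dtm one-band `raster_stack`s on identical grids.
#' @return one-band `raster_stack` (`chm`, metres).
#' @export
compute_chm <- function(dsm, dtm) {
  if (!isTRUE(all.equal(rs_dim(dsm), rs_dim(dtm))) ||
      dsm$pixel_size != dtm$pixel_size ||
      abs(dsm$xmin - dtm$xmin) > 1e-9 || abs(dsm$ymax - dtm$ymax) > 1e-9) {
    stop("dsm and dtm must share one grid")
  }
  chm <- dsm$bands[[1]] - dtm$bands[[1]]
  chm[chm < 0] <- 0
  mask <- dsm$mask & dtm$mask
  chm[!mask] <- NA_real_
  raster_stack(list(chm = chm), pixel_size = dsm$pixel_size,
               xmin = dsm$xmin, ymax = dsm$ymax, mask = mask, domain = "meters")
}

#' Transform RGB digital numbers to hue, intensity, saturation
#'
#' HSL-family decomposition: intensity is lightness (max+min)/2, saturation
#' follows the HSL convention, hue lies in \[0, 360) with achromatic pixels
#' assigned hue 0. With `scale = "unit"`, H is in degrees and I/S in \[0, 1\];
#' with `scale = "dn"` all three are rescaled to 0-255 (H by 255/360).
#'
#' @param stack `raster_stack` with bands `red`, `green`, `blue` in DN 0-255.
#' @param scale `"unit"` or `"dn"`.
#' @return `raster_stack` with bands `hue`, `intensity`, `saturation`.
#' @export
rgb_to_his <- function(stack, scale = c("unit", "dn")) {
  scale <- match.arg(scale)
  R <- rs_band(stack, "red"); G <- rs_band(stack, "green"); B <- rs_band(stack, "blue")
  if (any(R < 0 | R > 255 | G < 0 | G > 255 | B < 0 | B > 255, na.rm = TRUE)) {
    warning("DN values outside 0-255 clipped")
    R <- pmin(pmax(R, 0), 255); G <- pmin(pmax(G, 0), 255); B <- pmin(pmax(B, 0), 255)
  }
  r <- R / 255; g <- G / 255; b <- B / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  L <- (mx + mn) / 2
  delta <- mx - mn
  S <- ifelse(delta == 0, 0,
              ifelse(L <= 0.5, delta / (mx + mn), delta / (2 - mx - mn)))
  H <- matrix(0, nrow(R), ncol(R))
  nz <- delta != 0 & !is.na(delta)
  hr <- nz & mx == r
  hg <- nz & mx == g & !hr
  hb <- nz & !hr & !hg
  H[hr] <- 60 * (((g[hr] - b[hr]) / delta[hr]) %% 6)
  H[hg] <- 60 * ((b[hg] - r[hg]) / delta[hg] + 2)
  H[hb] <- 60 * ((r[hb] - g[hb]) / delta[hb] + 4)
  H[is.na(delta)] <- NA_real_
  if (scale == "dn") {
    H <- H * 255 / 360; S <- S * 255; L <- L * 255
  }
  raster_stack(list(hue = H, intensity = L, saturation = S),
               pixel_size = stack$pixel_size, xmin = stack$xmin,
               ymax = stack$ymax, mask = stack$mask,
               domain = if (scale == "dn") "dn_0_255" else "index")
}

#' Inverse HIS (HSL) transform back to RGB digital numbers
#' @param his `raster_stack` with `hue`, `intensity`, `saturation` on the
#'   `"unit"` convention (H in degrees, I/S in \[0, 1\]).
#' @return `raster_stack` with `red`, `green`, `blue` in 0-255.
#' @export
his_to_rgb <- function(his) {
  H <- rs_band(his, "hue"); L <- rs_band(his, "intensity")
  S <- rs_band(his, "saturation")
  C <- (1 - abs(2 * L - 1)) * S
  Hp <- H / 60
  X <- C * (1 - abs(Hp %% 2 - 1))
  m <- L - C / 2
  r <- g <- b <- matrix(0, nrow(H), ncol(H))
  seg <- floor(Hp) %% 6
  pick <- function(sel, rv, gv, bv) {
    r[sel] <<- rv[sel]; g[sel] <<- gv[sel]; b[sel] <<- bv[sel]
  }
  zero <- matrix(0, nrow(H), ncol(H))
  pick(seg == 0, C, X, zero); pick(seg == 1, X, C, zero)
  pick(seg == 2, zero, C, X); pick(seg == 3, zero, X, C)
  pick(seg == 4, X, zero, C); pick(seg == 5, C, zero, X)
  raster_stack(list(red = (r + m) * 255, green = (g + m) * 255,
                    blue = (b + m) * 255),
               pixel_size = his$pixel_size, xmin = his$xmin, ymax = his$ymax,
               mask = his$mask, domain = "dn_0_255")
}

#' Vegetation indices for RGB imagery
#'
#' Computes ExG, ExR, ExGR and NGRDI from chromatic coordinates
#' r = R/(R+G+B) (and likewise g, b): ExG = 2g - r - b, ExR = 1.4r - g,
#' ExGR = ExG - ExR, NGRDI = (G - R)/(G + R). Pixels with a zero denominator
#' become nodata.
#'
#' @param stack `raster_stack` with `red`, `green`, `blue` bands.
#' @return `raster_stack` with bands `ExG`, `ExR`, `ExGR`, `NGRDI`.
#' @export
compute_vis_rgb <- function(stack) {
  R <- rs_band(stack, "red"); G <- rs_band(stack, "green"); B <- rs_band(stack, "blue")
  tot <- R + G + B
  tot[tot == 0] <- NA_real_
  r <- R / tot; g <- G / tot; b <- B / tot
  ExG <- 2 * g - r - b
  ExR <- 1.4 * r - g
  ExGR <- ExG - ExR
  den <- G + R
  den[den == 0] <- NA_real_
  NGRDI <- (G - R) / den
  raster_stack(list(ExG = ExG, ExR = ExR, ExGR = ExGR, NGRDI = NGRDI),
               pixel_size = stack$pixel_size, xmin = stack$xmin,
               ymax = stack$ymax, mask = stack$mask, domain = "index")
}

#' Default band roles for the 10-band multispectral sensor
#'
#' The dual-camera sensor carries two greens (531/560), two reds (650/668)
#' and three red-edge bands (705/717/740). Index formulas use the wavelengths
#' closest to each index's canonical definition: green 560, red 668, blue
#' 475, red edge 705 and 717, NIR 840. Override to remap.
#' @export
ms_band_roles <- function() {
  c(green = "b560", red = "b668", blue = "b475",
    re705 = "b705", re717 = "b717", nir = "b840")
}

#' Vegetation indices for multispectral imagery
#'
#' Computes CIg, EVI, GARI, GNDVI, MCARI, MSAVI, NDVI and SR_717 from
#' reflectance bands (0-1). Zero denominators yield nodata.
#'
#' @param stack `raster_stack` with the 10 reflectance bands (`b444` ...
#'   `b840`).
#' @param roles named character vector mapping roles to band names; see
#'   [ms_band_roles()].
#' @return `raster_stack` of the eight index bands.
#' @export
compute_vis_ms <- function(stack, roles = ms_band_roles()) {
  gb <- rs_band(stack, roles[["green"]]); rd <- rs_band(stack, roles[["red"]])
  bl <- rs_band(stack, roles[["blue"]]); re5 <- rs_band(stack, roles[["re705"]])
  re7 <- rs_band(stack, roles[["re717"]]); nir <- rs_band(stack, roles[["nir"]])
  safe_div <- function(num, den) {
    den[den == 0] <- NA_real_
    num / den
  }
  CIg <- safe_div(nir, gb) - 1
  EVI <- 2.5 * safe_div(nir - rd, nir + 6 * rd - 7.5 * bl + 1)
  gcorr <- gb - 1.7 * (bl - rd)
  GARI <- safe_div(nir - gcorr, nir + gcorr)
  GNDVI <- safe_div(nir - gb, nir + gb)
  MCARI <- ((re5 - rd) - 0.2 * (re5 - gb)) * safe_div(re5, rd)
  disc <- (2 * nir + 1)^2 - 8 * (nir - rd)
  disc[disc < 0] <- NA_real_
  MSAVI <- (2 * nir + 1 - sqrt(disc)) / 2
  NDVI <- safe_div(nir - rd, nir + rd)
  SR_717 <- safe_div(nir, re7)
  raster_stack(list(CIg = CIg, EVI = EVI, GARI = GARI, GNDVI = GNDVI,
                    MCARI = MCARI, MSAVI = MSAVI, NDVI = NDVI,
                    SR_717 = SR_717),
               pixel_size = stack$pixel_size, xmin = stack$xmin,
               ymax = stack$ymax, mask = stack$mask, domain = "index")
}

#' Assemble the per-sensor analysis stack
#'
#' Builds the full variable stack used downstream. For the RGB sensor:
#' red/green/blue DN, HIS (0-255 scaling so radiometry units match the DN
#' range radius), CHM and the four RGB indices. For the MS sensor: the ten
#' reflectance bands, CHM and the eight MS indices. The segmentation runs on
#' a subset of bands (spectral + HIS + CHM for RGB; spectral + CHM for MS);
#' classification uses everything.
#'
#' @param spectral `raster_stack` of sensor bands.
#' @param chm one-band CHM `raster_stack` on the same grid (use
#'   [align_rasters()] first if not).
#' @param sensor `"rgb"` or `"ms"`.
#' @return list with `stack` (all bands), `seg_bands`, `feature_bands`.
#' @export
build_analysis_stack <- function(spectral, chm, sensor = c("rgb", "ms")) {
  sensor <- match.arg(sensor)
  if (sensor == "rgb") {
    his <- rgb_to_his(spectral, scale = "dn")
    vis <- compute_vis_rgb(spectral)
    stack <- rs_add_band(spectral, his$bands)
    stack <- rs_add_band(stack, chm = rs_band(chm, "chm"), domain = "meters")
    stack <- rs_add_band(stack, vis$bands)
    seg_bands <- c("red", "green", "blue", "hue", "intensity", "saturation", "chm")
  } else {
    vis <- compute_vis_ms(spectral)
    stack <- rs_add_band(spectral, chm = rs_band(chm, "chm"), domain = "meters")
    seg_bands <- names(stack$bands)
    stack <- rs_add_band(stack, vis$bands)
  }
  list(stack = stack, seg_bands = seg_bands, feature_bands = names(stack$bands))
}
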