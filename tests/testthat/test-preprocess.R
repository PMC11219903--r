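test_that("TIN interpolation reproduces an affine surface exactly", {
  set.seed(1)
  pts <- data.frame(x = runif(12, 0, 10), y = runif(12, 0, 10))
  pts$z <- 2 * pts$x + 3 * pts$y + 1
  tgt <- grid_spec(10, 10, pixel_size = 1, xmin = 0, ymax = 10)
  dtm <- compute_dtm_tin(pts, tgt)
  ctr <- rs_centers(dtm)
  expected <- outer(ctr$y, ctr$x, function(y, x) 2 * x + 3 * y + 1)
  # linear barycentric interpolation is exact for planes, inside and
  # (by plane extrapolation) outside the hull
  expect_equal(dtm$bands$dtm, expected, tolerance = 1e-9)
})

test_that("a grid node coincident with an input point gets that point's z", {
  pts <- data.frame(x = c(0.5, 5.5, 2.5, 8.5), y = c(0.5, 0.5, 7.5, 6.5),
                    z = c(3, 1, 4, 2))
  tgt <- grid_spec(10, 10, pixel_size = 1, xmin = 0, ymax = 10)
  dtm <- compute_dtm_tin(pts, tgt)
  # point (2.5, 7.5) sits at cell centre row 3, col 3
  expect_equal(dtm$bands$dtm[3, 3], 4, tolerance = 1e-9)
  expect_equal(dtm$bands$dtm[10, 1], 3, tolerance = 1e-9)
})

test_that("TIN matches the brute-force point-in-triangle oracle", {
  set.seed(7)
  pts <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 10))
  pts$z <- sin(pts$x) + 0.3 * pts$y
  tgt <- grid_spec(10, 10, pixel_size = 1, xmin = 0, ymax = 10)
  dtm <- compute_dtm_tin(pts, tgt)
  ctr <- rs_centers(tgt)
  exp <- oracle_tin(pts, ctr$x, ctr$y)
  inside <- !is.na(exp)
  expect_gt(sum(inside), 50)
  expect_equal(dtm$bands$dtm[inside], exp[inside], tolerance = 1e-7)
  expect_equal(attr(dtm, "extrapolated"), is.na(exp))
})

test_that("collinear ground points raise a degenerate-triangulation error", {
  pts <- data.frame(x = 1:5, y = 2 * (1:5), z = 1:5)
  tgt <- grid_spec(4, 4, 1)
  expect_error(compute_dtm_tin(pts, tgt), "degenerate|collinear")
})

test_that("CHM is the clamped pixelwise difference", {
  mk <- function(m) raster_stack(list(z = m), 1)
  expect_equal(compute_chm(mk(matrix(5, 3, 3)), mk(matrix(5, 3, 3)))$bands$chm,
               matrix(0, 3, 3))
  expect_equal(compute_chm(mk(matrix(10.5, 2, 2)),
                           mk(matrix(10, 2, 2)))$bands$chm,
               matrix(0.5, 2, 2))
  set.seed(3)
  a <- matrix(rnorm(16), 4, 4); b <- matrix(rnorm(16), 4, 4)
  got <- compute_chm(mk(a), mk(b))$bands$chm
  exp <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) exp[i, j] <- max(a[i, j] - b[i, j], 0)
  expect_equal(got, exp)
  expect_error(compute_chm(mk(matrix(1, 2, 2)), mk(matrix(1, 3, 3))),
               "grid")
})

test_that("HIS anchors: pure red and gray", {
  x <- raster_stack(list(red = matrix(c(255, 128), 1, 2),
                         green = matrix(c(0, 128), 1, 2),
                         blue = matrix(c(0, 128), 1, 2)), 1)
  his <- rgb_to_his(x)
  expect_equal(his$bands$hue[1, 1], 0)
  expect_equal(his$bands$saturation[1, 1], 1)
  expect_equal(his$bands$intensity[1, 1], 0.5)
  expect_equal(his$bands$saturation[1, 2], 0)   # gray has no chroma
  expect_equal(his$bands$hue[1, 2], 0)          # achromatic hue convention
})

test_that("HIS forward then inverse recovers RGB within 1 DN", {
  set.seed(11)
  n <- 100
  R <- matrix(sample(0:255, n, TRUE), 10, 10)
  G <- matrix(sample(0:255, n, TRUE), 10, 10)
  B <- matrix(sample(0:255, n, TRUE), 10, 10)
  x <- raster_stack(list(red = R, green = G, blue = B), 1)
  back <- his_to_rgb(rgb_to_his(x, scale = "unit"))
  expect_lt(max(abs(back$bands$red - R)), 1)
  expect_lt(max(abs(back$bands$green - G)), 1)
  expect_lt(max(abs(back$bands$blue - B)), 1)
})

test_that("RGB vegetation indices match hand values and identities", {
  x <- raster_stack(list(red = matrix(c(100, 0), 1, 2),
                         green = matrix(c(100, 255), 1, 2),
                         blue = matrix(c(100, 0), 1, 2)), 1)
  vi <- compute_vis_rgb(x)
  expect_equal(vi$bands$ExG[1, 1], 0)     # achromatic
  expect_equal(vi$bands$NGRDI[1, 1], 0)
  expect_equal(vi$bands$ExG[1, 2], 2)     # pure green: g = 1
  expect_equal(vi$bands$ExR[1, 2], -1)
  expect_equal(vi$bands$ExGR[1, 2], 3)
  expect_equal(vi$bands$NGRDI[1, 2], 1)
  set.seed(5)
  y <- raster_stack(list(red = matrix(runif(64, 0, 255), 8),
                         green = matrix(runif(64, 0, 255), 8),
                         blue = matrix(runif(64, 0, 255), 8)), 1)
  v <- compute_vis_rgb(y)
  expect_equal(v$bands$ExGR, v$bands$ExG - v$bands$ExR, tolerance = 1e-12)
  expect_true(all(abs(v$bands$NGRDI) <= 1))
})

test_that("MS vegetation indices match hand values", {
  nb <- paste0("b", c(444, 475, 531, 560, 650, 668, 705, 717, 740, 840))
  bands <- stats::setNames(lapply(nb, function(z) matrix(0.3, 1, 1)), nb)
  bands$b840 <- matrix(0.5, 1, 1)
  bands$b668 <- matrix(0.1, 1, 1)
  x <- raster_stack(bands, 1)
  vi <- compute_vis_ms(x)
  expect_equal(vi$bands$NDVI[1, 1], 0.4 / 0.6, tolerance = 1e-12)
  # NIR == red -> NDVI = 0 and MSAVI = 0; NIR == green -> GNDVI = 0
  bands$b840 <- matrix(0.1, 1, 1)
  vi2 <- compute_vis_ms(raster_stack(bands, 1))
  expect_equal(vi2$bands$NDVI[1, 1], 0)
  expect_equal(vi2$bands$MSAVI[1, 1], 0, tolerance = 1e-12)
  bands$b840 <- matrix(0.3, 1, 1)
  vi3 <- compute_vis_ms(raster_stack(bands, 1))
  expect_equal(vi3$bands$GNDVI[1, 1], 0)
})
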