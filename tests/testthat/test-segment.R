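two_block <- function(lo = 0, hi = 100, nr = 6, nc = 6) {
  m <- matrix(lo, nr, nc)
  m[, (nc / 2 + 1):nc] <- hi
  m
}

test_that("constant image converges immediately to the constant", {
  x <- make_stack(v = matrix(7, 5, 5))
  p <- segmentation_params(spatialr = 2, ranger = 3, minsize = 1)
  modes <- meanshift_filter(x, p)
  expect_equal(modes$bands$v, matrix(7, 5, 5))
  expect_equal(max(cluster_modes(modes, p)), 1)
})

test_that("two homogeneous blocks with a gap > ranger keep their means", {
  m <- two_block()
  x <- make_stack(v = m)
  p <- segmentation_params(spatialr = 3, ranger = 10, minsize = 1)
  modes <- meanshift_filter(x, p)
  expect_equal(modes$bands$v, m)   # block means equal the block values
  lab <- cluster_modes(modes, p)
  expect_equal(max(lab), 2)
  expect_equal(length(unique(lab[m == 0])), 1)
  expect_equal(length(unique(lab[m == 100])), 1)
})

test_that("infinite ranger and global window average to the global mean", {
  set.seed(2)
  m <- matrix(rnorm(36, 50, 5), 6, 6)
  x <- make_stack(v = m)
  p <- segmentation_params(spatialr = 10, ranger = 1e9, minsize = 1,
                           conv_threshold = 1e-8)
  modes <- meanshift_filter(x, p)
  expect_equal(modes$bands$v, matrix(mean(m), 6, 6), tolerance = 1e-6)
})

test_that("filter agrees with the per-pixel iterative oracle", {
  set.seed(4)
  for (case in 1:5) {
    nr <- sample(3:7, 1); nc <- sample(3:7, 1)
    b1 <- matrix(sample(0:20, nr * nc, TRUE) + 0, nr, nc)
    b2 <- matrix(sample(0:20, nr * nc, TRUE) + 0, nr, nc)
    x <- make_stack(a = b1, b = b2)
    p <- segmentation_params(spatialr = sample(1:3, 1),
                             ranger = sample(c(5, 12, 25), 1), minsize = 1,
                             max_iter = 20)
    got <- meanshift_filter(x, p)
    exp <- oracle_meanshift(list(b1, b2), p$spatialr, p$ranger,
                            max_iter = 20, conv = p$conv_threshold)
    expect_equal(got$bands$a, exp[[1]], info = paste("case", case))
    expect_equal(got$bands$b, exp[[2]], info = paste("case", case))
  }
})

test_that("clustering matches the component oracle and the checkerboard", {
  p <- segmentation_params(spatialr = 2, ranger = 5, minsize = 1)
  cb <- matrix(0, 4, 4); cb[(row(cb) + col(cb)) %% 2 == 0] <- 10
  lab <- cluster_modes(make_stack(v = cb), p)
  expect_equal(max(lab), 16)   # every pixel its own label
  set.seed(9)
  for (case in 1:5) {
    m <- matrix(sample(c(0, 6, 40), 30, TRUE), 5, 6)
    got <- cluster_modes(make_stack(v = m), p)
    exp <- oracle_cluster(list(m), p$ranger)
    expect_identical(got, exp, info = paste("case", case))
  }
})

test_that("labels are numbered in row-major discovery order", {
  m <- rbind(c(0, 10, 20), c(0, 10, 20))  # three vertical components
  lab <- cluster_modes(make_stack(v = m),
                       segmentation_params(ranger = 1, minsize = 1))
  expect_equal(lab[1, ], c(1L, 2L, 3L))
  expect_equal(lab[2, ], c(1L, 2L, 3L))
})

test_that("small-region merging follows the closest spectral neighbour", {
  # 8x8: left half 0, right half 20, with a 3-pixel bridge region at value 5
  # adjacent to both; |5-0| = 5 < |5-20| = 15 -> merges left
  m <- matrix(0, 8, 8)
  m[, 5:8] <- 20
  m[4, 4:6] <- 5
  lab <- matrix(1L, 8, 8)
  lab[, 5:8] <- 2L
  lab[4, 4:6] <- 3L
  merged <- merge_small_regions(lab, make_stack(v = m), minsize = 4)
  expect_equal(length(unique(as.vector(merged))), 2)
  # bridge pixels joined the left (value-0) region
  expect_equal(unique(merged[4, 4:6]), merged[1, 1])
})

test_that("merging is a no-op when all regions meet minsize", {
  lab <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  out <- merge_small_regions(lab, make_stack(v = matrix(c(0, 0, 9, 9), 2, 2)),
                             minsize = 2)
  expect_equal(out, lab)
})

test_that("an image smaller than minsize collapses to one region", {
  lab <- matrix(1:4, 2, 2)
  out <- merge_small_regions(lab, make_stack(v = matrix(1:4 * 1.0, 2, 2)),
                             minsize = 100)
  expect_equal(length(unique(as.vector(out))), 1)
})

test_that("merge agrees with the brute-force oracle on random rasters", {
  set.seed(21)
  for (case in 1:8) {
    nr <- sample(4:8, 1); nc <- sample(4:8, 1)
    m <- matrix(sample(0:9, nr * nc, TRUE) + 0, nr, nc)
    p <- segmentation_params(spatialr = 1, ranger = 2, minsize = 1)
    lab <- cluster_modes(make_stack(v = m), p)
    ms <- sample(2:5, 1)
    got <- merge_small_regions(lab, make_stack(v = m), ms)
    exp <- oracle_merge(lab, list(m), ms)
    expect_identical(got, exp, info = paste("case", case))
  }
})

test_that("vectorize traces pixel blocks with exact areas and holes", {
  lab <- matrix(0L, 4, 4)
  lab[2:3, 2:3] <- 1L
  polys <- vectorize(lab, pixel_size = 0.002)
  expect_equal(polygon_area(polys[["1"]]), 4 * 0.002^2, tolerance = 1e-15)
  expect_equal(polygon_perimeter(polys[["1"]]), 8 * 0.002)
  # a ring region with a hole
  ring <- matrix(1L, 5, 5); ring[3, 3] <- 2L
  pr <- vectorize(ring, pixel_size = 1)
  expect_equal(length(pr[["1"]]$rings), 2)          # outer + hole
  expect_equal(polygon_area(pr[["1"]]), 24)
  expect_equal(polygon_area(pr[["2"]]), 1)
})

test_that("polygon areas conserve pixel counts on random label grids", {
  set.seed(31)
  for (case in 1:20) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    m <- matrix(sample(0:6, nr * nc, TRUE), nr, nc)
    lab <- cluster_modes(make_stack(v = m + 0),
                         segmentation_params(ranger = 0.5, minsize = 1))
    lab[m == 0] <- lab[m == 0]  # keep as is; labels partition everything
    polys <- vectorize(lab, pixel_size = 0.5)
    counts <- tabulate(lab, nbins = max(lab))
    for (id in names(polys)) {
      expect_equal(polygon_area(polys[[id]]) / 0.25,
                   counts[as.integer(id)], tolerance = 1e-12,
                   info = paste("case", case, "label", id))
    }
    tot <- sum(vapply(polys, polygon_area, 0))
    expect_equal(tot, sum(lab > 0) * 0.25, tolerance = 1e-9)
  }
})

test_that("segment_image recovers two ground-truth patches and is monotone in minsize", {
  set.seed(8)
  m <- matrix(10, 24, 24)
  m[9:16, 9:20] <- 200
  truth <- (m == 200) + 1
  x <- make_stack(v = m + matrix(rnorm(576, 0, 0.5), 24, 24))
  p <- segmentation_params(spatialr = 3, ranger = 30, minsize = 1)
  sm <- segment_image(x, p)
  expect_equal(sm$n_segments, 2)
  expect_true(all(tapply(sm$labels, truth, function(v) length(unique(v))) == 1))
  n_prev <- Inf
  for (ms in c(1, 30, 120)) {
    p2 <- segmentation_params(spatialr = 3, ranger = 30, minsize = ms)
    n_now <- segment_image(x, p2)$n_segments
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("tiled and untiled segmentation produce identical partitions", {
  set.seed(12)
  base <- matrix(0, 128, 128)
  base[, 65:128] <- 60
  base[40:80, 30:100] <- 120
  x <- make_stack(v = base + matrix(rnorm(128^2, 0, 1), 128, 128))
  p0 <- segmentation_params(spatialr = 3, ranger = 30, minsize = 20,
                            max_iter = 10)
  pt <- segmentation_params(spatialr = 3, ranger = 30, minsize = 20,
                            max_iter = 10, tile_size = 64)
  s0 <- segment_image(x, p0)
  st <- segment_image(x, pt)
  expect_identical(s0$labels, st$labels)
})

test_that("band order permutation does not change the partition", {
  set.seed(14)
  a <- matrix(sample(0:5, 64, TRUE) * 10 + 0, 8, 8)
  b <- matrix(sample(0:5, 64, TRUE) * 10 + 0, 8, 8)
  p <- segmentation_params(spatialr = 2, ranger = 8, minsize = 3)
  s1 <- segment_image(make_stack(a = a, b = b), p)
  s2 <- segment_image(make_stack(b = b, a = a), p)
  expect_identical(s1$labels, s2$labels)
})

test_that("nodata pixels carry no label and valid pixels exactly one", {
  m <- matrix(1:16 + 0, 4, 4)
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  x <- raster_stack(list(v = m), 1, mask = mask)
  sm <- segment_image(x, segmentation_params(spatialr = 1, ranger = 100,
                                             minsize = 1))
  expect_equal(sm$labels[1, 1], 0L)
  expect_true(all(sm$labels[mask] >= 1))
})
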