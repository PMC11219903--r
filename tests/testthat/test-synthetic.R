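test_that("realized class fractions track the priors", {
  cfg <- scene_config(extent_m = c(2, 2), pixel_size_m = 0.002,
                      patch_scale_m = 0.08, seed = 1)  # 1000 x 1000 px
  cm <- generate_class_map(cfg)   # priors (0.45, 0.45, 0.07, 0.03)
  f <- tabulate(cm, nbins = 4) / length(cm)
  expect_true(all(abs(f - cfg$class_priors) <= 0.05))
})

test_that("degenerate prior yields a single class and seeds reproduce", {
  cfg <- small_scene_config()
  cm <- generate_class_map(cfg, priors = c(1, 0, 0, 0))
  expect_true(all(cm == 1L))
  cm1 <- generate_class_map(cfg)
  cm2 <- generate_class_map(cfg)
  expect_identical(cm1, cm2)
  cm3 <- generate_class_map(cfg, seed = cfg$seed + 1L)
  expect_false(identical(cm1, cm3))
})

test_that("invalid configurations error", {
  expect_error(scene_config(pixel_size_m = -1), "pixel_size")
  expect_error(scene_config(extent_m = 0.0001), "extent")
  expect_error(scene_config(class_priors = c(0.5, 0.5, 0.5, -0.5)), "priors")
  expect_error(scene_config(dmy_beta = 0), "dmy_beta")
  cfg <- small_scene_config()
  expect_error(render_scene(generate_class_map(cfg), cfg, sensor = "lidar"),
               "unknown sensor")
})

test_that("zero noise renders exact class means; grass darker than clover", {
  cfg <- small_scene_config()
  cfg$spectral_model$rgb$sd <- 0
  cm <- matrix(2L, 16, 16)
  r <- render_scene(cm, cfg, sensor = "rgb")
  mu <- cfg$spectral_model$rgb$mean["clover", ]
  expect_equal(r$stack$bands$red, matrix(mu["red"], 16, 16),
               ignore_attr = TRUE)
  expect_equal(r$stack$bands$green, matrix(mu["green"], 16, 16),
               ignore_attr = TRUE)
  # default config: per-class green means on a rendered mixed scene
  cfg2 <- small_scene_config(seed = 3)
  cm2 <- generate_class_map(cfg2)
  r2 <- render_scene(cm2, cfg2, sensor = "rgb")
  expect_lt(mean(r2$stack$bands$green[cm2 == 1]),
            mean(r2$stack$bands$green[cm2 == 2]))
})

test_that("dsm - dtm over a pure-grass region matches the grass height", {
  cfg <- small_scene_config(seed = 5)
  cm <- matrix(1L, 64, 64)
  r <- render_scene(cm, cfg, sensor = "rgb")
  h <- r$dsm$bands$dsm - r$dtm$bands$dtm
  # mean of n correlated draws; use 3 x marginal sd as a generous bound
  expect_lt(abs(mean(h) - cfg$height_model$mean["grass"]),
            3 * cfg$height_model$sd)
})

test_that("class-conditional band means converge to the model means", {
  # law of large numbers at >= 1e5 pixels; tolerance 3 x sd of the mean with
  # the effective sample size implied by the noise correlation length
  cfg <- scene_config(extent_m = c(0.8, 0.8), pixel_size_m = 0.002, seed = 7)
  cm <- matrix(1L, 400, 400)
  r <- render_scene(cm, cfg, sensor = "rgb")
  corr_px <- cfg$noise_corr_m / cfg$pixel_size_m
  n_eff <- length(cm) / (2 * pi * corr_px^2)
  tol <- 3 * cfg$spectral_model$rgb$sd / sqrt(n_eff)
  for (b in c("red", "green", "blue")) {
    expect_lt(abs(mean(r$stack$bands[[b]]) -
                    cfg$spectral_model$rgb$mean["grass", b]), tol)
  }
})

test_that("reference polygons hit the coverage target and are pure", {
  cfg <- small_scene_config(seed = 11)
  cm <- generate_class_map(cfg)
  refs <- suppressWarnings(generate_reference_polygons(cm, cfg))
  plot_area <- prod(dim(cm)) * cfg$pixel_size_m^2
  frac <- sum(refs$area) / plot_area
  expect_gte(frac, 0.12)
  expect_lte(frac, 0.22)
  # every polygon's interior pixels are >= 90% its assigned class
  s <- cfg$pixel_size_m
  H <- nrow(cm) * s
  for (r in seq_len(nrow(refs))) {
    j <- max(1, floor(refs$xmin[r] / s) + 1):min(ncol(cm),
                                                 ceiling(refs$xmax[r] / s))
    i <- max(1, floor((H - refs$ymax[r]) / s) + 1):min(nrow(cm),
                                                 ceiling((H - refs$ymin[r]) / s))
    cells <- cm[i, j]
    expect_gte(mean(cells == refs$class[r]), 0.90)
  }
  cfg0 <- small_scene_config()
  cfg0$label_coverage_target <- 0
  expect_equal(nrow(generate_reference_polygons(cm, cfg0)), 0)
})

test_that("reference counts reflect class prevalence", {
  # larger plot so minor-class patches exist but stay rare
  cfg <- small_scene_config(seed = 13, extent_m = c(0.512, 0.512))
  cm <- generate_class_map(cfg)
  refs <- suppressWarnings(generate_reference_polygons(cm, cfg))
  cnt <- tabulate(refs$class, nbins = 4)
  expect_gt(sum(cnt[1:2]), 3 * sum(cnt[3:4]))  # majors dominate the labels
})

test_that("cover-to-weight distortion matches the stated formula", {
  expect_equal(cover_to_weight(0.55, 0.5), 0.275 / 0.725, tolerance = 1e-12)
  expect_equal(cover_to_weight(0, 2), 0)
  cs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(cover_to_weight(cs, 1), cs, tolerance = 1e-12)  # identity
  expect_true(all(cover_to_weight(cs, 0.5) < cs))  # monotone distortion
  expect_error(cover_to_weight(0.5, 0), "dmy_beta")
})

test_that("generate_dmy reproduces the distortion in the noise-free limit", {
  cfg <- small_scene_config()
  cfg$dmy_noise_sd <- 0
  tc <- data.frame(subplot_id = rep("S1", 4), class = 1:4,
                   cover = c(0.40, 0.55, 0.05, 0.00))
  dmy <- generate_dmy(tc, cfg)
  w <- dmy$dry_weight_g / sum(dmy$dry_weight_g)
  expect_equal(w[2], 0.275 / 0.725, tolerance = 1e-9)
  expect_equal(w[1] / w[3], 0.40 / 0.05, tolerance = 1e-9)
  expect_equal(w[4], 0)
  expect_true(all(dmy$dry_weight_g >= 0))
})

test_that("simulate_scene builds a consistent, reproducible world", {
  cfg <- small_scene_config(seed = 17)
  sc <- simulate_scene(cfg, sensor = "rgb")
  expect_equal(length(sc$plots), 4)   # 2 replicates x 2 mixtures here
  expect_equal(nrow(sc$subplots), 4)
  # per-subplot true cover sums to 1
  sums <- tapply(sc$true_cover$cover, sc$true_cover$subplot_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # mixture-2 plots contain no plantain
  m2 <- sc$plots[[sc$plot_table$plot_id[sc$plot_table$mixture == "2"][1]]]
  expect_false(3L %in% unique(as.vector(rs_band(m2$class_map, 1))))
  # determinism: full second simulation is identical
  sc2 <- simulate_scene(cfg, sensor = "rgb")
  expect_identical(sc$plots[[1]]$stack$bands, sc2$plots[[1]]$stack$bands)
  expect_identical(sc$dmy, sc2$dmy)
  expect_identical(sc$subplots, sc2$subplots)
})

test_that("ms sensor renders 10 reflectance bands in range", {
  cfg <- small_scene_config(pixel_size_m = 0.02, extent_m = c(0.64, 0.64))
  cm <- generate_class_map(cfg)
  r <- render_scene(cm, cfg, sensor = "ms")
  expect_equal(length(r$stack$bands), 10)
  expect_true(all(vapply(r$stack$bands, function(b)
    all(b >= 0 & b <= 1), TRUE)))
})

test_that("separation scaling moves the grass-clover Mahalanobis distance", {
  cfg <- small_scene_config()
  d1 <- spectral_separation(cfg, "rgb")
  expect_gt(d1, 4); expect_lt(d1, 7)
  cfg$separation_scale <- 0.33
  expect_lt(spectral_separation(cfg, "rgb"), 2.2)
})
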