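# Synthetic sward scenes with known ground truth.
#
# The generator emulates the structure of a mixed grass-clover field trial:
# 8 plots (2 mixtures x 4 replicates) of patchy 4-class ground cover
# (grass = 1, clover = 2, plantain = 3, weed = 4), class-specific spectral
# signatures (grass darker than clover across bands, plantain/weed close to
# clover), near-identical canopy heights across classes, a deterministic
# gentle terrain, two sensor resolutions, 0.55 x 0.55 m subplot frames and a
# dry-matter-yield table linked to true cover through a "visible clover is
# about twice its weight fraction" distortion.

#' Default per-class spectral model
#'
#' Returns per-class band means and a common noise standard deviation for a
#' sensor. Rows are grass, clover, plantain, weed. RGB means are digital
#' numbers (0-255, noise sd 12 DN); MS means are reflectances (0-1, noise sd
#' 0.02). Defaults place the grass-clover Mahalanobis separation near 6
#' (classifiable but not trivial) and plantain/weed close to clover.
#' @param sensor `"rgb"` or `"ms"`.
#' @export
default_spectral_model <- function(sensor = c("rgb", "ms")) {
  sensor <- match.arg(sensor)
  if (sensor == "rgb") {
    # plantain/weed sit between grass and clover (slightly clover-ward):
    # confusable minors whose misclassification splits between both majors
    mean <- rbind(grass    = c(70, 100, 50),
                  clover   = c(110, 150, 80),
                  plantain = c(92, 128, 70),
                  weed     = c(95, 122, 72))
    colnames(mean) <- c("red", "green", "blue")
    list(mean = mean, sd = 12, range = c(0, 255))
  } else {
    mean <- rbind(
      grass    = c(0.020, 0.025, 0.050, 0.070, 0.040, 0.035, 0.18, 0.25, 0.38, 0.45),
      clover   = c(0.030, 0.040, 0.080, 0.110, 0.060, 0.050, 0.22, 0.30, 0.44, 0.52),
      plantain = c(0.028, 0.038, 0.075, 0.105, 0.058, 0.048, 0.21, 0.29, 0.43, 0.50),
      weed     = c(0.032, 0.042, 0.078, 0.108, 0.062, 0.052, 0.22, 0.31, 0.45, 0.51))
    colnames(mean) <- paste0("b", c(444, 475, 531, 560, 650, 668, 705, 717, 740, 840))
    list(mean = mean, sd = 0.02, range = c(0, 1))
  }
}

#' Synthetic scene configuration
#'
#' @param extent_m per-plot width/height in metres (length-2 or scalar).
#' @param pixel_size_m ground sampling distance in metres (2 mm RGB-like,
#'   2 cm MS-like).
#' @param class_priors target area fractions for grass/clover/plantain/weed
#'   (sum to 1, non-negative); used when a plot has no mixture-specific
#'   priors.
#' @param mixture_priors list of per-mixture prior vectors; mixture 2 holds
#'   grass + clover, mixture 3 grass + clover + plantain, both with a small
#'   weed fraction.
#' @param patch_scale_m spatial correlation length of species patches.
#' @param noise_corr_m correlation length of the within-class spectral
#'   texture (leaf-scale speckle); 0 gives iid pixel noise.
#' @param spectral_model list with `rgb` and `ms` entries as returned by
#'   [default_spectral_model()].
#' @param separation_scale multiplies the spread of class means around their
#'   common centre; 1 keeps the default grass-clover Mahalanobis separation
#'   (about 6), smaller values make classes harder to tell apart.
#' @param height_model per-class canopy height mean (m) and common sd.
#' @param dtm_amplitude_m amplitude of the deterministic terrain undulation.
#' @param dmy_beta cover-to-weight distortion coefficient: clover weight
#'   fraction w = beta c / (beta c + (1 - c)); beta = 0.5 encodes the field
#'   rule of thumb that visible clover cover is roughly twice its dry-matter
#'   share.
#' @param dmy_noise_sd sd of the lognormal noise multiplying the clover
#'   weight before renormalization.
#' @param dmy_total_mean_g,dmy_total_sdlog total subplot dry weight is drawn
#'   from a lognormal with this mean (g) and log-sd.
#' @param label_coverage_target fraction of plot area to cover with reference
#'   polygons (in (0,1); the field protocol reached about 0.17).
#' @param label_size_range_m edge-length range of the rectangular reference
#'   polygons (patches of species rather than single leaves).
#' @param layout list: `n_replicates`, `n_mixtures`, `n_subplots`,
#'   `subplot_size_m`.
#' @param n_ground_points surveyed terrain points, spread evenly.
#' @param seed integer; one seed governs every draw of the scene.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(extent_m = c(1.024, 1.024),
                         pixel_size_m = 0.002,
                         class_priors = c(grass = 0.45, clover = 0.45,
                                          plantain = 0.07, weed = 0.03),
                         mixture_priors = list(
                           "2" = c(grass = 0.50, clover = 0.45,
                                   plantain = 0.00, weed = 0.05),
                           "3" = c(grass = 0.45, clover = 0.40,
                                   plantain = 0.10, weed = 0.05)),
                         patch_scale_m = 0.08,
                         noise_corr_m = 0.01,
                         spectral_model = list(rgb = default_spectral_model("rgb"),
                                               ms = default_spectral_model("ms")),
                         separation_scale = 1,
                         height_model = list(mean = c(grass = 0.16, clover = 0.15,
                                                      plantain = 0.17, weed = 0.15),
                                             sd = 0.02),
                         dtm_amplitude_m = 0.05,
                         dmy_beta = 0.5,
                         dmy_noise_sd = 0.05,
                         dmy_total_mean_g = 60,
                         dmy_total_sdlog = 0.15,
                         label_coverage_target = 0.17,
                         label_size_range_m = c(0.04, 0.10),
                         layout = list(n_replicates = 4, n_mixtures = 2,
                                       n_subplots = 10, subplot_size_m = 0.55),
                         n_ground_points = 20,
                         seed = 1L) {
  if (length(extent_m) == 1) extent_m <- c(extent_m, extent_m)
  if (!is.numeric(pixel_size_m) || pixel_size_m <= 0) {
    stop("invalid config: pixel_size_m must be > 0")
  }
  if (any(extent_m < pixel_size_m)) {
    stop("invalid config: extent smaller than one pixel")
  }
  if (any(class_priors < 0) || abs(sum(class_priors) - 1) > 1e-9) {
    stop("invalid config: class_priors must be non-negative and sum to 1")
  }
  for (p in mixture_priors) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("invalid config: mixture priors must be non-negative and sum to 1")
    }
  }
  if (label_coverage_target < 0 || label_coverage_target >= 1) {
    stop("invalid config: label_coverage_target must lie in [0, 1)")
  }
  if (dmy_beta <= 0) stop("invalid config: dmy_beta must be > 0")
  structure(list(extent_m = extent_m, pixel_size_m = pixel_size_m,
                 class_priors = class_priors, mixture_priors = mixture_priors,
                 patch_scale_m = patch_scale_m, noise_corr_m = noise_corr_m,
                 spectral_model = spectral_model,
                 separation_scale = separation_scale,
                 height_model = height_model,
                 dtm_amplitude_m = dtm_amplitude_m,
                 dmy_beta = dmy_beta, dmy_noise_sd = dmy_noise_sd,
                 dmy_total_mean_g = dmy_total_mean_g,
                 dmy_total_sdlog = dmy_total_sdlog,
                 label_coverage_target = label_coverage_target,
                 label_size_range_m = label_size_range_m,
                 layout = layout, n_ground_points = n_ground_points,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Class codes and names
#' @export
class_codes <- function() c(grass = 1L, clover = 2L, plantain = 3L, weed = 4L)

# Scale class means around their common centre (controls class separability).
.scaled_means <- function(model, scale) {
  ctr <- colMeans(model$mean)
  sweep(sweep(model$mean, 2, ctr, "-") * scale, 2, ctr, "+")
}

#' Grass-clover Mahalanobis separation implied by a configuration
#' @param cfg a `scene_config`.
#' @param sensor `"rgb"` or `"ms"`.
#' @export
spectral_separation <- function(cfg, sensor = "rgb") {
  model <- cfg$spectral_model[[sensor]]
  m <- .scaled_means(model, cfg$separation_scale)
  sqrt(sum(((m["grass", ] - m["clover", ]) / model$sd)^2))
}

# Smoothed standard Gaussian random field via FFT convolution with a
# (wrapped) Gaussian kernel; output standardized to mean 0, sd 1.
.gaussian_field <- function(nr, nc, sd_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sd_px < 1e-9) return(z)
  kr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  kc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  # separable wrapped Gaussian: exp(-(r^2+c^2)/2s^2)
  k <- outer(exp(-kr^2 / (2 * sd_px^2)), exp(-kc^2 / (2 * sd_px^2)))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE))
  (f - mean(f)) / stats::sd(f)
}

#' Generate a patchy class-code map
#'
#' One smoothed Gaussian random field per class; per-class additive offsets
#' are calibrated (deterministically, given the fields) so that the realized
#' argmax fractions match the priors; each pixel takes the class with the
#' largest offset field value. Patches are spatially contiguous at the
#' configured patch scale.
#'
#' @param cfg a `scene_config`.
#' @param priors optional prior vector overriding `cfg$class_priors`.
#' @param seed optional seed overriding `cfg$seed`.
#' @return integer matrix of class codes 1-4.
#' @export
generate_class_map <- function(cfg, priors = cfg$class_priors,
                               seed = cfg$seed) {
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-9) {
    stop("invalid config: priors must be non-negative and sum to 1")
  }
  nr <- floor(cfg$extent_m[2] / cfg$pixel_size_m)
  nc <- floor(cfg$extent_m[1] / cfg$pixel_size_m)
  if (nr < 1 || nc < 1) stop("invalid config: extent smaller than one pixel")
  set.seed(seed)
  active <- which(priors > 0)
  if (length(active) == 1) {
    return(matrix(as.integer(active), nr, nc))
  }
  sd_px <- cfg$patch_scale_m / cfg$pixel_size_m
  fields <- lapply(seq_along(priors), function(k) {
    if (priors[k] > 0) .gaussian_field(nr, nc, sd_px) else NULL
  })
  offs <- rep(-Inf, length(priors))
  offs[active] <- log(priors[active])
  arr <- array(-Inf, dim = c(nr, nc, length(priors)))
  for (k in active) arr[, , k] <- fields[[k]]
  assign_map <- function(offs) {
    best <- matrix(active[1], nr, nc)
    bestv <- arr[, , active[1]] + offs[active[1]]
    for (k in active[-1]) {
      v <- arr[, , k] + offs[k]
      upd <- v > bestv
      best[upd] <- k
      bestv[upd] <- v[upd]
    }
    best
  }
  # damped fixed-point calibration of the offsets toward the target
  # fractions; steps are clamped so a class that momentarily vanishes does
  # not trigger an overshoot cascade, and the best-seen offsets win
  best_offs <- offs
  best_err <- Inf
  for (it in 1:120) {
    cm <- assign_map(offs)
    f <- tabulate(cm, nbins = length(priors)) / (nr * nc)
    err <- max(abs(f[active] - priors[active]))
    if (err < best_err) {
      best_err <- err
      best_offs <- offs
    }
    delta <- 0.5 * (log(priors + 1e-4) - log(f + 1e-4))
    delta <- pmin(pmax(delta, -0.5), 0.5)
    offs[active] <- offs[active] + delta[active]
  }
  matrix(as.integer(assign_map(best_offs)), nr, nc)
}

# Deterministic terrain: a sum of low-frequency sinusoids in absolute map
# coordinates, so TIN recovery from surveyed points is checkable.
.dtm_fun <- function(cfg) {
  A <- cfg$dtm_amplitude_m
  function(x, y) {
    A * (0.6 * sin(2 * pi * x / 3.7) + 0.4 * cos(2 * pi * y / 2.9)) +
      0.002 * x + 0.001 * y + 10
  }
}

#' Render a class map into sensor imagery plus surface/terrain models
#'
#' Per-pixel band values are the class's (separation-scaled) spectral mean
#' plus spatially correlated Gaussian noise, clipped to the sensor's valid
#' range. The DSM is the deterministic DTM plus the class canopy height plus
#' correlated noise; the DTM is evaluated analytically at cell centres.
#'
#' @param class_map integer matrix of class codes.
#' @param cfg a `scene_config`.
#' @param sensor `"rgb"` (3 DN bands) or `"ms"` (10 reflectance bands).
#' @param origin map coordinates `c(xmin, ymax)` of the plot's upper-left
#'   corner.
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `stack`, `dsm`, `dtm` (all `raster_stack`s).
#' @export
render_scene <- function(class_map, cfg, sensor = "rgb",
                         origin = c(0, nrow(class_map) * cfg$pixel_size_m),
                         seed = cfg$seed) {
  if (!sensor %in% c("rgb", "ms")) stop("unknown sensor: ", sensor)
  if (!all(class_map %in% 1:4)) stop("class_map codes must lie in 1..4")
  model <- cfg$spectral_model[[sensor]]
  means <- .scaled_means(model, cfg$separation_scale)
  nr <- nrow(class_map); nc <- ncol(class_map)
  set.seed(seed)
  corr_px <- cfg$noise_corr_m / cfg$pixel_size_m
  bands <- list()
  for (b in seq_len(ncol(means))) {
    base <- matrix(means[class_map, b], nr, nc)
    if (model$sd > 0) {
      base <- base + model$sd * .gaussian_field(nr, nc, corr_px)
    }
    bands[[colnames(means)[b]]] <- pmin(pmax(base, model$range[1]),
                                        model$range[2])
  }
  dtm_f <- .dtm_fun(cfg)
  s <- cfg$pixel_size_m
  cx <- origin[1] + (seq_len(nc) - 0.5) * s
  cy <- origin[2] - (seq_len(nr) - 0.5) * s
  dtm <- outer(cy, cx, function(y, x) dtm_f(x, y))
  hm <- cfg$height_model
  height <- matrix(hm$mean[class_map], nr, nc)
  if (hm$sd > 0) height <- height + hm$sd * .gaussian_field(nr, nc, corr_px)
  height[height < 0] <- 0
  dsm <- dtm + height
  dom <- if (sensor == "rgb") "dn_0_255" else "reflectance_0_1"
  mk <- function(b, nm, d) raster_stack(stats::setNames(list(b), nm),
                                        pixel_size = s, xmin = origin[1],
                                        ymax = origin[2], domain = d)
  list(stack = raster_stack(bands, pixel_size = s, xmin = origin[1],
                            ymax = origin[2], domain = dom),
       dsm = mk(dsm, "dsm", "meters"),
       dtm = mk(dtm, "dtm", "meters"))
}

#' Generate labelled reference polygons inside single-class patches
#'
#' Rectangles with edge lengths in `label_size_range_m` are placed at random
#' inside the plot and accepted when at least 95% of the covered pixels share
#' one class (the rectangle's label), until the accepted area reaches
#' `label_coverage_target` of the plot area. Class counts therefore reflect
#' class prevalence.
#'
#' @param class_map integer class-code matrix.
#' @param cfg a `scene_config`.
#' @param origin map coordinates `c(xmin, ymax)` of the plot corner.
#' @param seed optional seed.
#' @param priors priors of the plot's mixture (classes with positive prior
#'   that are absent from the map trigger a warning).
#' @return data frame: `ref_id`, `class`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `area`.
#' @export
generate_reference_polygons <- function(class_map, cfg,
                                        origin = c(0, nrow(class_map) *
                                                     cfg$pixel_size_m),
                                        seed = cfg$seed,
                                        priors = cfg$class_priors) {
  set.seed(seed)
  s <- cfg$pixel_size_m
  nr <- nrow(class_map); nc <- ncol(class_map)
  W <- nc * s; H <- nr * s
  target <- cfg$label_coverage_target * W * H
  out <- list()
  tot <- 0
  attempts <- 0
  max_attempts <- 4000
  while (tot < target && attempts < max_attempts) {
    attempts <- attempts + 1
    w <- stats::runif(1, cfg$label_size_range_m[1], cfg$label_size_range_m[2])
    h <- stats::runif(1, cfg$label_size_range_m[1], cfg$label_size_range_m[2])
    w <- min(w, W); h <- min(h, H)
    x0 <- stats::runif(1, 0, W - w)
    y0 <- stats::runif(1, 0, H - h)
    j0 <- max(1, floor(x0 / s) + 1); j1 <- min(nc, ceiling((x0 + w) / s))
    i0 <- max(1, floor((H - (y0 + h)) / s) + 1)
    i1 <- min(nr, ceiling((H - y0) / s))
    cells <- class_map[i0:i1, j0:j1]
    cnt <- tabulate(cells, nbins = 4)
    if (max(cnt) / length(cells) < 0.95) next
    cls <- which.max(cnt)
    out[[length(out) + 1]] <- data.frame(
      class = cls,
      xmin = origin[1] + x0, xmax = origin[1] + x0 + w,
      ymin = origin[2] - H + y0, ymax = origin[2] - H + y0 + h,
      area = w * h)
    tot <- tot + w * h
  }
  present <- unique(as.vector(class_map))
  for (k in which(priors > 0)) {
    if (!(k %in% present)) {
      warning("class ", names(class_codes())[k],
              " requested but absent from the class map; zero polygons")
    }
  }
  if (!length(out)) {
    return(data.frame(ref_id = integer(0), class = integer(0),
                      xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0),
                      area = numeric(0)))
  }
  df <- do.call(rbind, out)
  cbind(ref_id = seq_len(nrow(df)), df)
}

#' Clover weight fraction implied by clover cover
#'
#' The monotone distortion w = beta c / (beta c + (1 - c)). With beta = 1 the
#' weight fraction equals the cover fraction; beta < 1 makes clover lighter
#' than it looks (for beta = 0.5, 55% visible cover corresponds to about 38%
#' of the dry weight).
#' @param c clover cover fraction(s) in \[0, 1\].
#' @param beta distortion coefficient (> 0).
#' @export
cover_to_weight <- function(c, beta) {
  if (beta <= 0) stop("invalid config: dmy_beta must be > 0")
  beta * c / (beta * c + (1 - c))
}

#' Generate a dry-matter-yield table from true cover fractions
#'
#' The clover weight fraction follows [cover_to_weight()] with multiplicative
#' lognormal noise, renormalized against the non-clover remainder; non-clover
#' classes split the remainder in proportion to their cover. Total subplot
#' dry weight is lognormal.
#'
#' @param true_cover data frame with columns `subplot_id`, `class`, `cover`
#'   (per-subplot fractions summing to 1).
#' @param cfg a `scene_config`.
#' @param seed optional seed.
#' @return data frame: `subplot_id`, `class`, `dry_weight_g`.
#' @export
generate_dmy <- function(true_cover, cfg, seed = cfg$seed) {
  if (cfg$dmy_beta <= 0) stop("invalid config: dmy_beta must be > 0")
  set.seed(seed)
  sp <- split(true_cover, true_cover$subplot_id)
  rows <- lapply(sp, function(d) {
    if (abs(sum(d$cover) - 1) > 1e-6) {
      stop("per-subplot cover fractions must sum to 1")
    }
    cov <- stats::setNames(rep(0, 4), 1:4)
    cov[as.character(d$class)] <- d$cover
    c_cl <- cov["2"]
    w <- cover_to_weight(c_cl, cfg$dmy_beta)
    if (cfg$dmy_noise_sd > 0) {
      wn <- w * stats::rlnorm(1, 0, cfg$dmy_noise_sd)
      w <- wn / (wn + (1 - w))
    }
    shares <- rep(0, 4)
    shares[2] <- w
    if (c_cl < 1) {
      other <- cov[c("1", "3", "4")] / (1 - c_cl)
      shares[c(1, 3, 4)] <- (1 - w) * other
    }
    total <- stats::rlnorm(1, log(cfg$dmy_total_mean_g), cfg$dmy_total_sdlog)
    data.frame(subplot_id = d$subplot_id[1], class = 1:4,
               dry_weight_g = shares * total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' True per-subplot cover fractions from a class map
#'
#' Exact pixel-rectangle overlap areas: each cell contributes the area of its
#' intersection with the subplot frame to its class.
#'
#' @param class_map_rs one-band `raster_stack` of class codes (or a plain
#'   matrix plus georeference via `pixel_size`, `xmin`, `ymax`).
#' @param subplots data frame with `subplot_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @return data frame: `subplot_id`, `class`, `area_m2`, `cover`.
#' @export
true_cover_fractions <- function(class_map_rs, subplots) {
  out <- list()
  for (r in seq_len(nrow(subplots))) {
    sp <- subplots[r, ]
    ov <- .cell_rect_overlap(class_map_rs, sp$xmin, sp$xmax, sp$ymin, sp$ymax)
    if (!length(ov$rows)) next
    cm <- rs_band(class_map_rs, 1)[ov$rows, ov$cols, drop = FALSE]
    areas <- vapply(1:4, function(k) sum(ov$area[cm == k]), 0)
    tot <- sum(areas)
    out[[length(out) + 1]] <- data.frame(
      subplot_id = sp$subplot_id, class = 1:4, area_m2 = areas,
      cover = if (tot > 0) areas / tot else rep(0, 4))
  }
  do.call(rbind, out)
}

#' Simulate a full multi-plot sward scene
#'
#' Lays out `n_replicates` x `n_mixtures` plots on a regular grid (replicates
#' as rows), generates a class map and rendered imagery per plot, reference
#' polygons, subplot frames, surveyed ground points (on the deterministic
#' terrain), true cover fractions and the dry-matter-yield table. One
#' configuration seed governs every draw; per-plot seeds are derived
#' deterministically from it.
#'
#' @param cfg a `scene_config`.
#' @param sensor `"rgb"` or `"ms"`.
#' @return object of class `sward_scene`: list with `cfg`, `sensor`, `plots`
#'   (each: `plot_id`, `replicate`, `mixture`, `origin`, `class_map`,
#'   `stack`, `dsm`, `dtm`, `refs`), `plot_table`, `subplots`,
#'   `ground_points`, `true_cover`, `dmy`.
#' @export
simulate_scene <- function(cfg, sensor = "rgb") {
  lay <- cfg$layout
  s <- cfg$pixel_size_m
  nrp <- lay$n_replicates; nmx <- lay$n_mixtures
  if (nmx > length(cfg$mixture_priors)) {
    stop("not enough mixture_priors entries for n_mixtures")
  }
  gap <- ceiling(0.2 / s) * s
  pw <- floor(cfg$extent_m[1] / s) * s
  ph <- floor(cfg$extent_m[2] / s) * s
  reps <- LETTERS[seq_len(nrp)]
  mixes <- names(cfg$mixture_priors)[seq_len(nmx)]
  plot_table <- expand.grid(replicate = reps, mixture = mixes,
                            stringsAsFactors = FALSE)
  plot_table$plot_id <- paste0(plot_table$replicate, plot_table$mixture)
  plot_table$col <- match(plot_table$mixture, mixes)
  plot_table$row <- match(plot_table$replicate, reps)
  plot_table$xmin <- (plot_table$col - 1) * (pw + gap)
  plot_table$ymax <- nrp * (ph + gap) - (plot_table$row - 1) * (ph + gap)
  base_seed <- cfg$seed
  plots <- vector("list", nrow(plot_table))
  names(plots) <- plot_table$plot_id
  for (i in seq_len(nrow(plot_table))) {
    pt <- plot_table[i, ]
    priors <- cfg$mixture_priors[[pt$mixture]]
    sd_i <- (base_seed * 1009L + i * 7L) %% 2147483647L
    cm <- generate_class_map(cfg, priors = priors, seed = sd_i)
    origin <- c(pt$xmin, pt$ymax)
    rend <- render_scene(cm, cfg, sensor = sensor, origin = origin,
                         seed = sd_i + 1L)
    refs <- generate_reference_polygons(cm, cfg, origin = origin,
                                        seed = sd_i + 2L, priors = priors)
    if (nrow(refs)) refs$plot_id <- pt$plot_id
    plots[[i]] <- list(plot_id = pt$plot_id, replicate = pt$replicate,
                       mixture = pt$mixture, origin = origin,
                       class_map = raster_stack(list(class_map = cm),
                                                pixel_size = s,
                                                xmin = origin[1],
                                                ymax = origin[2]),
                       stack = rend$stack, dsm = rend$dsm, dtm = rend$dtm,
                       refs = refs)
  }
  # subplot frames: one per plot, extras on the first plots, placed at a
  # seeded random position with the frame fully inside the plot
  set.seed((base_seed * 2003L + 11L) %% 2147483647L)
  fs <- lay$subplot_size_m
  n_sub <- lay$n_subplots
  host <- rep_len(seq_len(nrow(plot_table)), n_sub)
  subplots <- data.frame(subplot_id = paste0("S", seq_len(n_sub)),
                         plot_id = plot_table$plot_id[host],
                         xmin = NA_real_, xmax = NA_real_,
                         ymin = NA_real_, ymax = NA_real_)
  if (fs > pw || fs > ph) stop("subplot frame larger than plot extent")
  for (i in seq_len(n_sub)) {
    pt <- plot_table[host[i], ]
    x0 <- pt$xmin + stats::runif(1, 0, pw - fs)
    y1 <- pt$ymax - stats::runif(1, 0, ph - fs)
    subplots$xmin[i] <- x0; subplots$xmax[i] <- x0 + fs
    subplots$ymax[i] <- y1; subplots$ymin[i] <- y1 - fs
  }
  # ground points: jittered even grid over the scene footprint, z from the
  # deterministic terrain
  W <- nmx * pw + (nmx - 1) * gap
  H <- nrp * ph + (nrp - 1) * gap
  ng <- cfg$n_ground_points
  gpc <- ceiling(sqrt(ng * W / H)); gpr <- ceiling(ng / gpc)
  gx <- rep(seq(0, W, length.out = gpc), times = gpr)
  gy <- rep(seq(0, H, length.out = gpr), each = gpc)
  keep <- seq_len(min(ng, length(gx)))
  jx <- stats::runif(length(keep), -0.02, 0.02) * W / gpc
  jy <- stats::runif(length(keep), -0.02, 0.02) * H / gpr
  dtm_f <- .dtm_fun(cfg)
  gpts <- data.frame(x = pmin(pmax(gx[keep] + jx, 0), W),
                     y = pmin(pmax(gy[keep] + jy, 0), H))
  gpts$z <- dtm_f(gpts$x, gpts$y)
  # ground truth cover and DMY
  tc <- list()
  for (i in seq_len(n_sub)) {
    pl <- plots[[subplots$plot_id[i]]]
    tc[[i]] <- true_cover_fractions(pl$class_map, subplots[i, ])
  }
  true_cover <- do.call(rbind, tc)
  dmy <- generate_dmy(true_cover, cfg,
                      seed = (base_seed * 3001L + 17L) %% 2147483647L)
  structure(list(cfg = cfg, sensor = sensor, plots = plots,
                 plot_table = plot_table, subplots = subplots,
                 ground_points = gpts, true_cover = true_cover, dmy = dmy),
            class = "sward_scene")
}

#' @export
print.sward_scene <- function(x, ...) {
  cat(sprintf("sward_scene: %d plots (%s sensor), %d subplots, seed %d\n",
              length(x$plots), x$sensor, nrow(x$subplots), x$cfg$seed))
  invisible(x)
}
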