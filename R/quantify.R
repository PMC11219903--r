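# Full-scene species mapping, per-subplot cover fractions, DMY proportions
# and the cover-vs-DMY regression.

#' Predict a class for every segment of a map
#'
#' @param model a `clover_rf` (typically trained on labelled segments from
#'   all plots).
#' @param segmap a `segment_map`.
#' @param features feature table covering all segments of `segmap`.
#' @return list of class `classified_map`: `segmap`, `pred` (data frame
#'   `segment_id`, `class`), `class_grid` (one-band `raster_stack` of
#'   predicted class codes, 0 = nodata).
#' @export
predict_map <- function(model, segmap, features) {
  ids <- sort(unique(segmap$labels[segmap$labels > 0]))
  if (!all(ids %in% features$segment_id)) {
    stop("features do not cover all segments")
  }
  features <- features[match(ids, features$segment_id), , drop = FALSE]
  cls <- predict(model, features)
  lut <- integer(max(ids) + 1L)           # index = label + 1, 0 -> nodata
  lut[ids + 1L] <- cls
  grid <- matrix(lut[segmap$labels + 1L], nrow(segmap$labels),
                 ncol(segmap$labels))
  class_grid <- raster_stack(list(class_pred = grid),
                             pixel_size = segmap$pixel_size,
                             xmin = segmap$xmin, ymax = segmap$ymax,
                             mask = segmap$labels > 0)
  structure(list(segmap = segmap,
                 pred = data.frame(segment_id = ids, class = cls),
                 class_grid = class_grid),
            class = "classified_map")
}

#' Per-subplot class cover areas and fractions
#'
#' Clips the classified map by each subplot frame and sums the clipped area
#' per class. Because classified segments are unions of grid cells, the
#' exact polygon intersection with an axis-aligned frame equals the sum of
#' the per-cell rectangle overlaps, which is what is computed. The cover
#' fraction is class area / subplot area, in percent.
#'
#' @param map a `classified_map` (or one-band class-code `raster_stack`),
#'   or a named list of them keyed by `plot_id` for multi-plot scenes.
#' @param subplots data frame: `subplot_id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   and `plot_id` when `map` is a list.
#' @return data frame of class `cover_report`: `subplot_id`, `class`,
#'   `area_m2`, `cover_pct`, `subplot_area_m2`.
#' @export
cover_fractions <- function(map, subplots) {
  get_grid <- function(m) {
    if (inherits(m, "classified_map")) m$class_grid else m
  }
  rows <- list()
  for (r in seq_len(nrow(subplots))) {
    sp <- subplots[r, ]
    grid <- if (is.list(map) && !inherits(map, "classified_map") &&
                !inherits(map, "raster_stack")) {
      get_grid(map[[sp$plot_id]])
    } else {
      get_grid(map)
    }
    if (is.null(grid)) stop("no classified map for subplot ", sp$subplot_id)
    d <- rs_dim(grid); s <- grid$pixel_size
    if (sp$xmin < grid$xmin - 1e-9 ||
        sp$xmax > grid$xmin + d[2] * s + 1e-9 ||
        sp$ymax > grid$ymax + 1e-9 ||
        sp$ymin < grid$ymax - d[1] * s - 1e-9) {
      stop("subplot ", sp$subplot_id, " outside the mapped extent")
    }
    ov <- .cell_rect_overlap(grid, sp$xmin, sp$xmax, sp$ymin, sp$ymax)
    cm <- rs_band(grid, 1)[ov$rows, ov$cols, drop = FALSE]
    areas <- vapply(1:4, function(k) sum(ov$area[cm == k]), 0)
    sub_area <- (sp$xmax - sp$xmin) * (sp$ymax - sp$ymin)
    rows[[r]] <- data.frame(subplot_id = sp$subplot_id, class = 1:4,
                            area_m2 = areas,
                            cover_pct = 100 * areas / sub_area,
                            subplot_area_m2 = sub_area)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cover_report", class(out))
  out
}

#' Per-subplot dry-matter-yield proportions
#'
#' Weight percentage per class: class dry weight / total subplot dry weight
#' x 100.
#'
#' @param dmy_table data frame: `subplot_id`, `class`, `dry_weight_g`
#'   (non-negative).
#' @return data frame: `subplot_id`, `class`, `dmy_pct`.
#' @export
dmy_proportions <- function(dmy_table) {
  if (any(dmy_table$dry_weight_g < 0)) stop("negative dry weights")
  sp <- split(dmy_table, dmy_table$subplot_id)
  rows <- lapply(sp, function(d) {
    tot <- sum(d$dry_weight_g)
    if (tot <= 0) stop("zero total weight in subplot ", d$subplot_id[1])
    data.frame(subplot_id = d$subplot_id, class = d$class,
               dmy_pct = 100 * d$dry_weight_g / tot)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least squares of DMY proportion on cover fraction
#'
#' y = a + b x with R-squared reported as the squared Pearson correlation, a
#' two-sided t-test p-value for the slope and a pointwise 95% confidence
#' band for the mean response.
#'
#' @param cover numeric vector (cover percentages, x).
#' @param dmy numeric vector (weight percentages, y), same length.
#' @param conf_level confidence level for the band.
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `band` (data frame `x`,
#'   `fit`, `lwr`, `upr`), `model`.
#' @export
regress_cover_vs_dmy <- function(cover, dmy, conf_level = 0.95) {
  stopifnot(length(cover) == length(dmy))
  n <- length(cover)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::var(cover) == 0) stop("zero variance in cover")
  fit <- stats::lm(dmy ~ cover, data = data.frame(cover = cover, dmy = dmy))
  co <- stats::coef(fit)
  r <- if (stats::sd(dmy) == 0) 0 else stats::cor(cover, dmy)
  p <- suppressWarnings(summary(fit)$coefficients["cover", "Pr(>|t|)"])
  xs <- seq(min(cover), max(cover), length.out = 50)
  ci <- stats::predict(fit, newdata = data.frame(cover = xs),
                       interval = "confidence", level = conf_level)
  structure(list(slope = unname(co["cover"]),
                 intercept = unname(co["(Intercept)"]),
                 r_squared = r^2, p_value = unname(p), n = n,
                 band = data.frame(x = xs, fit = ci[, "fit"],
                                   lwr = ci[, "lwr"], upr = ci[, "upr"]),
                 model = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.3f + %.3f x, R^2 = %.3f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}
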