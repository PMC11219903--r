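# Experiment orchestration: segmentation-parameter grids, the full
# segment -> features -> label -> cross-validate chain per combination,
# degenerate-combination filtering, full-scene mapping and quantification.

#' Segmentation parameter grid (sensor-matched)
#'
#' The 12-combination grid crossing two spatial radii, two range radii and
#' three minimum sizes, in the conventional order (spatialr outermost,
#' minsize innermost). RGB (DN imagery): spatialr \{10, 30\} x ranger
#' \{10, 30\} x minsize \{30, 120, 200\}. MS (reflectance imagery): spatialr
#' \{5, 15\} x ranger \{0.01, 0.02\} x minsize \{2, 8, 14\}.
#'
#' @param sensor `"rgb"` or `"ms"`.
#' @return data frame with `combination`, `spatialr`, `ranger`, `minsize`.
#' @export
table1_grid <- function(sensor = c("rgb", "ms")) {
  sensor <- match.arg(sensor)
  if (sensor == "rgb") {
    g <- expand.grid(minsize = c(30, 120, 200), ranger = c(10, 30),
                     spatialr = c(10, 30))
  } else {
    g <- expand.grid(minsize = c(2, 8, 14), ranger = c(0.01, 0.02),
                     spatialr = c(5, 15))
  }
  data.frame(combination = seq_len(nrow(g)), spatialr = g$spatialr,
             ranger = g$ranger, minsize = g$minsize)
}

#' Experiment configuration
#'
#' @param scene a [scene_config()] (the synthetic-scene source).
#' @param sensor `"rgb"` or `"ms"`.
#' @param grid segmentation parameter grid (data frame with `spatialr`,
#'   `ranger`, `minsize`); defaults to [table1_grid()] for the sensor.
#' @param labeling_mode `"within_overlap"` or `"within_only"`.
#' @param rf [rf_hyperparams()].
#' @param designated_combination grid row used for full-scene mapping and
#'   quantification; `NULL` picks the best pooled OA among non-degenerate
#'   combinations.
#' @param degenerate_floor minimum segment count (scene total) for a
#'   combination to stay in the summary; `NULL` uses the number of labelled
#'   reference polygons.
#' @param tile_size optional tile size forwarded to segmentation.
#' @param seed experiment seed; overrides the scene seed so one integer
#'   reproduces everything.
#' @export
experiment_config <- function(scene = scene_config(), sensor = "rgb",
                              grid = NULL, labeling_mode = "within_overlap",
                              rf = rf_hyperparams(),
                              designated_combination = NULL,
                              degenerate_floor = NULL, tile_size = NULL,
                              seed = scene$seed) {
  if (is.null(grid)) grid <- table1_grid(sensor)
  stopifnot(nrow(grid) >= 1,
            all(c("spatialr", "ranger", "minsize") %in% names(grid)))
  if (!"combination" %in% names(grid)) grid$combination <- seq_len(nrow(grid))
  scene$seed <- as.integer(seed)
  structure(list(scene = scene, sensor = sensor, grid = grid,
                 labeling_mode = labeling_mode, rf = rf,
                 designated_combination = designated_combination,
                 degenerate_floor = degenerate_floor, tile_size = tile_size,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Preprocess a simulated scene into per-plot analysis stacks
#'
#' For every plot: TIN-interpolated DTM from the surveyed ground points on
#' the plot grid, CHM = DSM - DTM, and the sensor's analysis stack (bands,
#' HIS for RGB, CHM, vegetation indices).
#'
#' @param scene a `sward_scene`.
#' @return named list per plot: `stack`, `seg_bands`, `feature_bands`,
#'   `dtm_tin`, `chm`.
#' @export
preprocess_scene <- function(scene) {
  out <- vector("list", length(scene$plots))
  names(out) <- names(scene$plots)
  for (nm in names(scene$plots)) {
    pl <- scene$plots[[nm]]
    dtm <- compute_dtm_tin(scene$ground_points, pl$dsm)
    chm <- compute_chm(pl$dsm, dtm)
    an <- build_analysis_stack(pl$stack, chm, sensor = scene$sensor)
    out[[nm]] <- c(an, list(dtm_tin = dtm, chm = chm))
  }
  out
}

# Run one parameter combination over all plots: segment, extract features,
# label. Returns segmaps, per-plot features, and the pooled learning db.
.run_combination <- function(scene, prep, params, mode) {
  segmaps <- list(); feats <- list(); dbs <- list()
  for (nm in names(scene$plots)) {
    pl <- scene$plots[[nm]]
    an <- prep[[nm]]
    sm <- segment_image(an$stack, params, bands = an$seg_bands)
    ft <- build_feature_table(sm, an$stack, plot_id = pl$plot_id,
                              replicate = pl$replicate)
    db <- spatial_join_labels(sm, pl$refs, features = ft, mode = mode)
    segmaps[[nm]] <- sm; feats[[nm]] <- ft
    if (nrow(db)) dbs[[nm]] <- db
  }
  list(segmaps = segmaps, features = feats,
       db = if (length(dbs)) do.call(rbind, dbs) else NULL)
}

#' Run a full experiment
#'
#' For each segmentation parameter combination: segment every plot, build
#' the feature tables, label segments by spatial join with the reference
#' polygons, and evaluate a Random Forest under replicate-wise spatial
#' cross-validation. Degenerate combinations (fewer segments than labelled
#' polygons by default) are flagged and excluded from the summary. A
#' designated combination (default: best pooled OA) is then used to map the
#' whole scene, clip the classified map by the subplot frames, and regress
#' clover cover against the dry-matter-yield proportion. The experiment is a
#' pure function of (config, seed): stage failures are recorded per
#' combination and remaining combinations continue.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print progress.
#' @return object of class `experiment_report`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  scene <- simulate_scene(cfg$scene, sensor = cfg$sensor)
  prep <- preprocess_scene(scene)
  folds <- make_folds(scene$plot_table)
  n_refs <- sum(vapply(scene$plots, function(p) nrow(p$refs), 0L))
  combos <- cfg$grid
  combos$n_segments <- NA_integer_
  combos$n_labeled <- NA_integer_
  combos$oa <- NA_real_
  for (cn in names(class_codes())) combos[[paste0("f1_", cn)]] <- NA_real_
  combos$error <- NA_character_
  details <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    if (verbose) {
      message(sprintf("combination %d: spatialr %g ranger %g minsize %g",
                      combos$combination[i], combos$spatialr[i],
                      combos$ranger[i], combos$minsize[i]))
    }
    res <- tryCatch({
      params <- segmentation_params(spatialr = combos$spatialr[i],
                                    ranger = combos$ranger[i],
                                    minsize = combos$minsize[i],
                                    tile_size = cfg$tile_size)
      cr <- .run_combination(scene, prep, params, cfg$labeling_mode)
      if (is.null(cr$db) || nrow(cr$db) == 0) stop("no labelled segments")
      hp <- cfg$rf
      hp$seed <- (cfg$seed * 31L + i) %% 2147483647L
      cv <- run_spatial_cv(cr$db, folds, hp)
      list(cr = cr, cv = cv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      combos$error[i] <- conditionMessage(res)
      next
    }
    combos$n_segments[i] <- sum(vapply(res$cr$segmaps,
                                       function(s) s$n_segments, 0L))
    combos$n_labeled[i] <- nrow(res$cr$db)
    combos$oa[i] <- res$cv$metrics$oa
    f1 <- res$cv$metrics$f1
    for (k in seq_along(f1)) {
      combos[[paste0("f1_", names(class_codes())[k])]][i] <- f1[k]
    }
    details[[i]] <- res
  }
  report <- structure(list(cfg = cfg, scene = scene, combos = combos,
                           details = details, n_refs = n_refs,
                           flagged = integer(0), quantification = NULL),
                      class = "experiment_report")
  report <- drop_degenerate_combinations(report, floor = cfg$degenerate_floor)
  report <- .quantify_designated(report, verbose = verbose)
  report
}

#' Flag combinations with insufficient object separation
#'
#' Combinations whose scene-wide segment count falls below a configurable
#' floor (default: the number of labelled reference polygons, i.e. fewer
#' segments than labels) are flagged and excluded from summary tables, with
#' the reason recorded.
#'
#' @param report an `experiment_report`.
#' @param floor minimum admissible segment count; `NULL` uses the labelled
#'   polygon count.
#' @return the report with `flagged` set and a `kept` column on `combos`.
#' @export
drop_degenerate_combinations <- function(report, floor = NULL) {
  if (is.null(floor)) floor <- report$n_refs
  cs <- report$combos
  flagged <- which(!is.na(cs$n_segments) & cs$n_segments < floor)
  cs$kept <- !is.na(cs$oa) & !(seq_len(nrow(cs)) %in% flagged)
  cs$flag_reason <- NA_character_
  cs$flag_reason[flagged] <-
    sprintf("insufficient object separation: %d segments < floor %d",
            cs$n_segments[flagged], floor)
  report$combos <- cs
  report$flagged <- flagged
  report$degenerate_floor <- floor
  report
}

# Full-scene mapping + quantification for the designated combination.
.quantify_designated <- function(report, verbose = FALSE) {
  cs <- report$combos
  kept <- which(cs$kept)
  if (!length(kept)) return(report)
  des <- report$cfg$designated_combination
  i <- if (is.null(des)) kept[which.max(cs$oa[kept])] else
    which(cs$combination == des)
  if (!length(i) || is.null(report$details[[i]])) return(report)
  if (verbose) message("quantifying with combination ", cs$combination[i])
  det <- report$details[[i]]
  hp <- report$cfg$rf
  hp$seed <- (report$cfg$seed * 47L + 13L) %% 2147483647L
  model <- train_rf(det$cr$db, hp)
  maps <- list()
  for (nm in names(det$cr$segmaps)) {
    maps[[nm]] <- predict_map(model, det$cr$segmaps[[nm]],
                              det$cr$features[[nm]])
  }
  cov <- cover_fractions(maps, report$scene$subplots)
  dmyp <- dmy_proportions(report$scene$dmy)
  cl <- cov[cov$class == 2, ]
  dm <- dmyp[dmyp$class == 2, ]
  m <- merge(cl[, c("subplot_id", "cover_pct")],
             dm[, c("subplot_id", "dmy_pct")], by = "subplot_id")
  reg <- tryCatch(regress_cover_vs_dmy(m$cover_pct, m$dmy_pct),
                  error = function(e) NULL)
  report$quantification <- list(combination = cs$combination[i],
                                model = model, maps = maps, cover = cov,
                                dmy_proportions = dmyp,
                                clover = m, regression = reg)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cs <- x$combos
  cat(sprintf("experiment_report: %d combinations (%d kept), sensor %s\n",
              nrow(cs), sum(cs$kept), x$cfg$sensor))
  print(cs[, c("combination", "spatialr", "ranger", "minsize", "n_segments",
               "n_labeled", "oa", "kept")], row.names = FALSE)
  if (!is.null(x$quantification) && !is.null(x$quantification$regression)) {
    r <- x$quantification$regression
    cat(sprintf("clover cover vs DMY: R^2 = %.3f, p = %.3g (combination %d)\n",
                r$r_squared, r$p_value, x$quantification$combination))
  }
  invisible(x)
}

#' Write the experiment report tables to a directory
#'
#' Writes `combos.csv` (per-combination parameters and metrics),
#' `confusion_<combination>.csv`, `cover.csv`, `dmy_proportions.csv`,
#' `regression.csv` and `config.yaml`. Output is deterministic for a fixed
#' (config, seed).
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) utils::write.csv(format(d, digits = 12),
                                        file.path(dir, f), row.names = FALSE)
  wr(report$combos[, setdiff(names(report$combos), "error")], "combos.csv")
  for (i in seq_along(report$details)) {
    if (is.null(report$details[[i]])) next
    conf <- report$details[[i]]$cv$pooled_confusion
    utils::write.csv(conf, file.path(
      dir, sprintf("confusion_%d.csv", report$combos$combination[i])))
  }
  q <- report$quantification
  if (!is.null(q)) {
    wr(q$cover, "cover.csv")
    wr(q$dmy_proportions, "dmy_proportions.csv")
    if (!is.null(q$regression)) {
      r <- q$regression
      wr(data.frame(combination = q$combination, slope = r$slope,
                    intercept = r$intercept, r_squared = r$r_squared,
                    p_value = r$p_value, n = r$n), "regression.csv")
    }
  }
  cfgl <- report$cfg
  yaml::write_yaml(list(sensor = cfgl$sensor, seed = cfgl$seed,
                        labeling_mode = cfgl$labeling_mode,
                        grid = lapply(seq_len(nrow(cfgl$grid)), function(i)
                          as.list(cfgl$grid[i, c("spatialr", "ranger",
                                                 "minsize")]))),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a simulated scene to plain-text artifacts
#'
#' Per plot: class map, spectral bands, DSM and DTM as ESRI ASCII grids;
#' scene-level CSVs for reference polygons, subplot frames, ground points,
#' true cover and the DMY table, plus the scene configuration as YAML.
#'
#' @param scene a `sward_scene`.
#' @param dir output directory.
#' @param rasters write per-plot rasters too (can be large).
#' @export
write_scene <- function(scene, dir, rasters = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- do.call(rbind, lapply(scene$plots, function(p) p$refs))
  utils::write.csv(refs, file.path(dir, "reference_polygons.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$subplots, file.path(dir, "subplots.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$ground_points, file.path(dir, "ground_points.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$true_cover, file.path(dir, "true_cover.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$dmy, file.path(dir, "dmy.csv"), row.names = FALSE)
  if (rasters) {
    for (nm in names(scene$plots)) {
      pl <- scene$plots[[nm]]
      write_asc(pl$class_map, 1, file.path(dir, paste0(nm, "_class_map.asc")))
      write_asc(pl$dsm, 1, file.path(dir, paste0(nm, "_dsm.asc")))
      write_asc(pl$dtm, 1, file.path(dir, paste0(nm, "_dtm.asc")))
      for (b in names(pl$stack$bands)) {
        write_asc(pl$stack, b, file.path(dir, paste0(nm, "_", b, ".asc")))
      }
    }
  }
  cfg <- scene$cfg
  yaml::write_yaml(list(extent_m = cfg$extent_m,
                        pixel_size_m = cfg$pixel_size_m,
                        class_priors = as.list(cfg$class_priors),
                        patch_scale_m = cfg$patch_scale_m,
                        dmy_beta = cfg$dmy_beta,
                        dmy_noise_sd = cfg$dmy_noise_sd,
                        label_coverage_target = cfg$label_coverage_target,
                        seed = cfg$seed, sensor = scene$sensor),
                   file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
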