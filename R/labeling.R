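# Attach ground-truth classes to segments via spatial join, and summarize
# reference polygons (boxplot/PCA inputs).

# Long table of segment x reference-rectangle intersection areas (exact for
# pixel-aligned segments: per-cell rectangle overlap summed by label).
.segment_ref_intersections <- function(segmap, refs) {
  grid <- structure(list(bands = list(l = segmap$labels),
                         pixel_size = segmap$pixel_size,
                         xmin = segmap$xmin, ymax = segmap$ymax,
                         mask = segmap$labels > 0, domain = NULL),
                    class = "raster_stack")
  out <- vector("list", nrow(refs))
  for (r in seq_len(nrow(refs))) {
    ov <- .cell_rect_overlap(grid, refs$xmin[r], refs$xmax[r],
                             refs$ymin[r], refs$ymax[r])
    if (!length(ov$rows)) next
    lab <- segmap$labels[ov$rows, ov$cols, drop = FALSE]
    sel <- lab > 0 & ov$area > 0
    if (!any(sel)) next
    ag <- rowsum(ov$area[sel], lab[sel])
    out[[r]] <- data.frame(segment_id = as.integer(rownames(ag)),
                           ref_id = refs$ref_id[r],
                           class = refs$class[r],
                           inter_area = ag[, 1])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(segment_id = integer(0), ref_id = integer(0),
                      class = integer(0), inter_area = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Select and label segments by spatial join with reference polygons
#'
#' Builds the learning database. In `within_overlap` mode a segment is
#' selected when it lies entirely inside a labelled polygon or its interior
#' intersects one with positive area; in `within_only` mode only
#' entirely-inside segments are kept. A segment intersecting several labelled
#' polygons takes the class of the largest intersection area; exact area ties
#' exclude the segment with a warning.
#'
#' @param segmap a `segment_map`.
#' @param refs data frame of labelled reference rectangles (`ref_id`,
#'   `class`, `xmin`, `xmax`, `ymin`, `ymax`).
#' @param features optional feature table from [build_feature_table()]; when
#'   given, the labelled rows are returned with their features attached.
#' @param mode `"within_overlap"` or `"within_only"`.
#' @return data frame with `segment_id`, `class`, `ref_id`, `within` plus
#'   feature columns when `features` is supplied.
#' @export
spatial_join_labels <- function(segmap, refs, features = NULL,
                                mode = c("within_overlap", "within_only")) {
  mode <- match.arg(mode)
  if (is.null(refs) || nrow(refs) == 0) stop("empty reference set")
  inter <- .segment_ref_intersections(segmap, refs)
  if (!nrow(inter)) {
    return(data.frame(segment_id = integer(0), class = integer(0),
                      ref_id = integer(0), within = logical(0)))
  }
  px_area <- segmap$pixel_size^2
  seg_area <- tabulate(segmap$labels, nbins = segmap$n_segments) * px_area
  tol <- 1e-9 * px_area
  inter$within <- inter$inter_area >= seg_area[inter$segment_id] - tol
  if (mode == "within_only") inter <- inter[inter$within, , drop = FALSE]
  sel <- split(inter, inter$segment_id)
  rows <- lapply(sel, function(d) {
    mx <- max(d$inter_area)
    top <- d[d$inter_area >= mx - tol, , drop = FALSE]
    if (nrow(top) > 1) {
      warning("segment ", d$segment_id[1],
              " has tied intersection areas; excluded")
      return(NULL)
    }
    data.frame(segment_id = top$segment_id, class = top$class,
               ref_id = top$ref_id, within = top$within)
  })
  db <- do.call(rbind, rows)
  if (is.null(db)) {
    db <- data.frame(segment_id = integer(0), class = integer(0),
                     ref_id = integer(0), within = logical(0))
  }
  rownames(db) <- NULL
  if (!is.null(features)) {
    db <- merge(db, features, by = "segment_id", sort = TRUE)
  }
  db
}

#' Per-polygon zonal means of all stack variables, keyed by class
#'
#' The reference-polygon summary feeding grouped boxplots and PCA.
#'
#' @param refs labelled reference rectangles (see [spatial_join_labels()]).
#' @param stack the analysis `raster_stack`.
#' @return data frame: `ref_id`, `class`, then one `<band>_mean` column per
#'   variable.
#' @export
reference_summary <- function(refs, stack) {
  zs <- zonal_stats(refs, stack)
  keep <- c("zone_id", "n_pixels", grep("_mean$", names(zs), value = TRUE))
  zs <- zs[, keep]
  names(zs)[names(zs) == "zone_id"] <- "ref_id"
  merge(refs[, c("ref_id", "class")], zs, by = "ref_id", sort = TRUE)
}

#' Principal component analysis of a reference summary table
#'
#' Correlation PCA (columns standardized) via eigen-decomposition: bands,
#' indices and heights live on incommensurable scales. Components are
#' ordered by decreasing variance; each loading vector is oriented so its
#' largest-magnitude entry is positive. Zero-variance columns are dropped
#' with a warning.
#'
#' @param table data frame; all numeric columns except identifiers are used.
#' @param exclude columns to ignore.
#' @return list with `scores`, `loadings`, `explained` (variance fractions),
#'   `sdev`.
#' @export
pca_reference <- function(table, exclude = c("ref_id", "class", "n_pixels",
                                             "plot_id", "replicate")) {
  num <- table[, setdiff(names(table), exclude), drop = FALSE]
  num <- num[, vapply(num, is.numeric, TRUE), drop = FALSE]
  if (nrow(num) < 2 || ncol(num) < 2) stop("need >= 2 rows and >= 2 columns")
  if (anyNA(num)) stop("missing values in PCA input")
  v <- vapply(num, stats::var, 0)
  if (any(v == 0)) {
    warning("zero-variance column(s) dropped: ",
            paste(names(num)[v == 0], collapse = ", "))
    num <- num[, v > 0, drop = FALSE]
    if (ncol(num) < 2) stop("fewer than 2 informative columns")
  }
  X <- scale(as.matrix(num))
  e <- eigen(stats::cor(as.matrix(num)), symmetric = TRUE)
  val <- pmax(e$values, 0)
  L <- e$vectors
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  rownames(L) <- colnames(num)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- X %*% L
  list(scores = scores, loadings = L, explained = val / sum(val),
       sdev = sqrt(val))
}
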