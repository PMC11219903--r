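# Random Forest classification with replicate-wise spatial cross-validation.

#' Random Forest hyperparameters
#'
#' Defaults follow common practice for classification forests: 500 trees,
#' mtry = floor(sqrt(p)) candidate features per split, minimum node size 1.
#'
#' @param num_trees number of trees.
#' @param mtry features tried per split; `NULL` means floor(sqrt(p)) at
#'   training time.
#' @param min_node_size minimal node size (1 grows trees to purity).
#' @param seed integer seed driving bootstrap and feature subsampling.
#' @export
rf_hyperparams <- function(num_trees = 500, mtry = NULL, min_node_size = 1,
                           seed = 1L) {
  stopifnot(num_trees >= 1, min_node_size >= 1)
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "rf_hyperparams")
}

#' Train a Random Forest on a learning database
#'
#' Bagged CART ensemble with Gini splits, mtry random candidate features per
#' node and majority voting with a deterministic tie-break (lowest class
#' code). Class codes are 1 = grass, 2 = clover, 3 = plantain, 4 = weed.
#'
#' @param db learning database: data frame with a `class` column and feature
#'   columns (see [feature_columns()]).
#' @param hp [rf_hyperparams()].
#' @param feature_cols optional explicit predictor column names.
#' @param n_classes number of class codes (default 4).
#' @return object of class `clover_rf` with out-of-bag votes.
#' @export
train_rf <- function(db, hp = rf_hyperparams(), feature_cols = NULL,
                     n_classes = 4L) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(db)
  X <- as.matrix(db[, feature_cols, drop = FALSE])
  y <- as.integer(db$class)
  if (length(unique(y)) < 2) stop("single-class training set")
  if (anyNA(X)) stop("missing feature values")
  mtry <- if (is.null(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else
    as.integer(hp$mtry)
  set.seed(hp$seed)
  fit <- cpp_rf_train(X, y, as.integer(n_classes), hp$num_trees, mtry,
                      hp$min_node_size)
  oob_votes <- fit$oob_votes
  oob_pred <- apply(oob_votes, 1, function(v) {
    if (sum(v) == 0) NA_integer_ else which.max(v)
  })
  structure(list(trees = fit$trees, feature_cols = feature_cols,
                 n_classes = as.integer(n_classes), mtry = mtry, hp = hp,
                 oob_votes = oob_votes, oob_pred = oob_pred,
                 oob_accuracy = mean(oob_pred == y, na.rm = TRUE)),
            class = "clover_rf")
}

#' @export
print.clover_rf <- function(x, ...) {
  cat(sprintf("clover_rf: %d trees, mtry %d, %d features, OOB accuracy %.3f\n",
              length(x$trees), x$mtry, length(x$feature_cols),
              x$oob_accuracy))
  invisible(x)
}

#' Predict classes for feature rows
#' @param object a `clover_rf`.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return integer class codes (majority vote; ties to the lowest code).
#' @export
predict.clover_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  if (anyNA(X)) stop("missing feature values")
  votes <- cpp_rf_votes(object$trees, X, object$n_classes)
  apply(votes, 1, which.max)  # which.max takes the first (lowest) on ties
}

#' Replicate-wise fold scheme
#'
#' One fold per replicate: the replicate's plots form the test set and all
#' other plots the training set (spatial hold-out following the field
#' layout).
#'
#' @param plots data frame with `plot_id` and `replicate` columns.
#' @return object of class `fold_scheme`: named list of
#'   `list(train = plot_ids, test = plot_ids)`.
#' @export
make_folds <- function(plots) {
  stopifnot(all(c("plot_id", "replicate") %in% names(plots)))
  reps <- unique(plots$replicate)
  if (length(reps) < 2) stop("need >= 2 replicates for spatial folds")
  folds <- lapply(reps, function(r) {
    list(train = plots$plot_id[plots$replicate != r],
         test = plots$plot_id[plots$replicate == r])
  })
  names(folds) <- as.character(reps)
  structure(folds, class = "fold_scheme")
}

#' Accuracy metrics from a confusion matrix
#'
#' Rows are truth, columns predictions. OA = trace/total; per class,
#' precision = M_cc / column sum, recall = M_cc / row sum,
#' F1 = 2PR/(P + R). A class absent from both truth and predictions has
#' undefined (NA) F1 and is excluded from averages.
#'
#' @param confusion square non-negative matrix.
#' @return list with `oa`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  tot <- sum(confusion)
  if (tot == 0) stop("all-zero confusion matrix")
  di <- diag(confusion)
  support_t <- rowSums(confusion)
  support_p <- colSums(confusion)
  precision <- ifelse(support_p > 0, di / support_p, NA_real_)
  recall <- ifelse(support_t > 0, di / support_t, NA_real_)
  f1 <- numeric(length(di))
  for (k in seq_along(di)) {
    if (support_t[k] == 0 && support_p[k] == 0) {
      f1[k] <- NA_real_
    } else {
      p <- if (is.na(precision[k])) 0 else precision[k]
      r <- if (is.na(recall[k])) 0 else recall[k]
      f1[k] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    }
  }
  names(f1) <- rownames(confusion)
  list(oa = sum(di) / tot, precision = precision, recall = recall, f1 = f1)
}

#' Run replicate-wise spatial cross-validation
#'
#' Per fold: train on the training plots' rows, predict the test plots'
#' rows, accumulate a 4 x 4 confusion matrix (rows = truth). Reports
#' per-fold and pooled metrics; the pooled confusion is the elementwise sum
#' of the fold confusions.
#'
#' @param db learning database with `class`, `plot_id` and feature columns.
#' @param scheme a `fold_scheme` from [make_folds()].
#' @param hp [rf_hyperparams()]; per-fold seeds derive deterministically
#'   from `hp$seed`.
#' @param n_classes number of class codes.
#' @return object of class `classification_report`: list with `folds`
#'   (confusion + metrics per fold), `pooled_confusion`, `metrics`.
#' @export
run_spatial_cv <- function(db, scheme, hp = rf_hyperparams(),
                           n_classes = 4L) {
  cls_names <- names(class_codes())[seq_len(n_classes)]
  pooled <- matrix(0, n_classes, n_classes,
                   dimnames = list(truth = cls_names, pred = cls_names))
  folds_out <- list()
  for (i in seq_along(scheme)) {
    f <- scheme[[i]]
    tr <- db[db$plot_id %in% f$train, , drop = FALSE]
    te <- db[db$plot_id %in% f$test, , drop = FALSE]
    if (nrow(te) == 0) {
      warning("fold ", names(scheme)[i], " has no test rows; skipped")
      next
    }
    hp_i <- hp
    hp_i$seed <- (hp$seed * 131L + i) %% 2147483647L
    model <- train_rf(tr, hp_i, n_classes = n_classes)
    pred <- predict(model, te)
    conf <- matrix(0, n_classes, n_classes,
                   dimnames = dimnames(pooled))
    for (k in seq_along(pred)) {
      conf[te$class[k], pred[k]] <- conf[te$class[k], pred[k]] + 1
    }
    pooled <- pooled + conf
    folds_out[[names(scheme)[i]]] <-
      list(confusion = conf, metrics = compute_metrics(conf))
  }
  if (!length(folds_out)) stop("no fold produced test predictions")
  structure(list(folds = folds_out, pooled_confusion = pooled,
                 metrics = compute_metrics(pooled)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: %d folds, pooled OA %.3f\n",
              length(x$folds), x$metrics$oa))
  f1 <- x$metrics$f1
  cat("  F1:", paste(sprintf("%s %.3f", names(f1), f1), collapse = ", "),
      "\n")
  invisible(x)
}
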