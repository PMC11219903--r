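test_that("replicate folds partition plots 6/2 for the 8-plot layout", {
  plots <- expand.grid(replicate = c("A", "B", "C", "D"),
                       mixture = c("2", "3"), stringsAsFactors = FALSE)
  plots$plot_id <- paste0(plots$replicate, plots$mixture)
  fs <- make_folds(plots)
  expect_equal(length(fs), 4)
  for (f in fs) {
    expect_equal(length(f$train), 6)
    expect_equal(length(f$test), 2)
    expect_length(intersect(f$train, f$test), 0)
  }
  tests <- unlist(lapply(fs, `[[`, "test"))
  expect_setequal(tests, plots$plot_id)          # union = all plots
  expect_equal(anyDuplicated(tests), 0)          # pairwise disjoint
  p2 <- data.frame(plot_id = c("A1", "A2", "B1", "B2"),
                   replicate = c("A", "A", "B", "B"))
  fs2 <- make_folds(p2)
  expect_equal(length(fs2), 2)
  expect_equal(lengths(lapply(fs2, `[[`, "train")), c(A = 2, B = 2))
  expect_error(make_folds(data.frame(plot_id = "X", replicate = "A")),
               "replicates")
})

test_that("metrics: hand-computed confusion matrices", {
  m <- compute_metrics(diag(c(5, 3, 2, 1)))
  expect_equal(m$oa, 1)
  expect_equal(unname(m$f1), rep(1, 4))
  conf <- matrix(c(8, 2, 2, 8), 2, 2, byrow = TRUE)
  m2 <- compute_metrics(conf)
  expect_equal(m2$oa, 0.8)
  expect_equal(unname(m2$f1), c(0.8, 0.8))
  # truth 10 clover all predicted grass
  conf3 <- matrix(0, 2, 2, dimnames = list(c("grass", "clover"),
                                           c("grass", "clover")))
  conf3["clover", "grass"] <- 10
  conf3["grass", "grass"] <- 5
  m3 <- compute_metrics(conf3)
  expect_equal(unname(m3$recall["clover"]), 0)
  expect_equal(unname(m3$f1["clover"]), 0)
  # class absent from truth and prediction -> NA F1
  conf4 <- diag(c(4, 4, 0, 2))
  expect_true(is.na(compute_metrics(conf4)$f1[3]))
  expect_error(compute_metrics(matrix(0, 3, 3)), "all-zero")
})

test_that("metrics match a definition-by-definition oracle on random matrices", {
  set.seed(44)
  for (case in 1:20) {
    conf <- matrix(rpois(16, 5), 4, 4)
    if (sum(conf) == 0) next
    m <- compute_metrics(conf)
    expect_equal(m$oa, sum(diag(conf)) / sum(conf))
    for (k in 1:4) {
      p <- if (sum(conf[, k]) > 0) conf[k, k] / sum(conf[, k]) else NA
      r <- if (sum(conf[k, ]) > 0) conf[k, k] / sum(conf[k, ]) else NA
      if (!is.na(p) && !is.na(r) && p + r > 0) {
        expect_equal(unname(m$f1[k]), 2 * p * r / (p + r))
      }
    }
  }
  # permutation invariance
  conf <- matrix(rpois(16, 4), 4, 4)
  perm <- c(3, 1, 4, 2)
  m1 <- compute_metrics(conf)
  m2 <- compute_metrics(conf[perm, perm])
  expect_equal(unname(m2$f1), unname(m1$f1[perm]))
  expect_equal(m2$oa, m1$oa)
})

test_that("RF defaults, separable data, degenerate inputs", {
  set.seed(55)
  n <- 200
  X <- data.frame(matrix(rnorm(n * 25), n, 25))
  names(X) <- paste0("f", 1:25)
  cls <- rep(1:2, each = n / 2)
  X$f1 <- X$f1 + 8 * (cls == 2)          # huge margin on one feature
  db <- cbind(X, class = cls, plot_id = "P", replicate = "A",
              segment_id = 1:n, n_pixels = 1)
  hp <- rf_hyperparams(num_trees = 100, seed = 9)
  model <- train_rf(db, hp)
  expect_equal(model$mtry, 5)            # floor(sqrt(25))
  expect_gte(model$oob_accuracy, 0.95)
  expect_equal(unname(predict(model, db)), cls)  # resubstitution is exact here
  # constant features -> every prediction is the majority class
  db2 <- db
  db2[paste0("f", 1:25)] <- 1
  db2$class <- c(rep(1, 150), rep(2, 50))
  m2 <- train_rf(db2, hp)
  expect_true(all(predict(m2, db2) == 1))
  expect_error(train_rf(db[db$class == 1, ], hp), "single-class")
  db3 <- db; db3$f1[1] <- NA
  expect_error(train_rf(db3, hp), "missing")
})

test_that("RF training and prediction are reproducible under one seed", {
  set.seed(77)
  n <- 80
  db <- data.frame(a_mean = rnorm(n), b_mean = rnorm(n),
                   class = sample(1:3, n, TRUE), plot_id = "P",
                   replicate = "A", segment_id = 1:n, n_pixels = 1)
  hp <- rf_hyperparams(num_trees = 50, seed = 4)
  p1 <- predict(train_rf(db, hp), db)
  p2 <- predict(train_rf(db, hp), db)
  expect_identical(p1, p2)
})

test_that("spatial CV: perfect features give OA 1; pooled = sum of folds", {
  set.seed(66)
  plots <- data.frame(plot_id = paste0(rep(c("A", "B", "C"), each = 2),
                                       rep(c("2", "3"), 3)),
                      replicate = rep(c("A", "B", "C"), each = 2))
  n_per <- 30
  db <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    cls <- sample(1:2, n_per, TRUE)
    data.frame(segment_id = 1:n_per, n_pixels = 1,
               x_mean = cls * 10 + rnorm(n_per, 0, 0.1),
               class = cls, plot_id = plots$plot_id[i],
               replicate = plots$replicate[i])
  }))
  cv <- run_spatial_cv(db, make_folds(plots),
                       rf_hyperparams(num_trees = 50, seed = 2))
  expect_equal(cv$metrics$oa, 1)
  expect_equal(unname(cv$metrics$f1[1:2]), c(1, 1))
  fold_sum <- Reduce(`+`, lapply(cv$folds, `[[`, "confusion"))
  expect_equal(fold_sum, cv$pooled_confusion)
  # a fold with no test rows is skipped with a warning
  db_missing <- db[db$replicate != "C", ]
  expect_warning(cv2 <- run_spatial_cv(db_missing, make_folds(plots),
                                       rf_hyperparams(num_trees = 20,
                                                      seed = 2)),
                 "skipped")
  expect_equal(length(cv2$folds), 2)
})
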