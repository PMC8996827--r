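random_binary_matrix <- function(n, d, p = 0.2) {
  m <- matrix(rbinom(n * d, 1, p), n, d)
  storage.mode(m) <- "integer"
  m
}

test_that("knn agrees with an exhaustive pairwise-distance oracle", {
  set.seed(11)
  for (trial in 1:5) {
    n <- 60; d <- 32
    x <- random_binary_matrix(n, d)
    lab <- sample(letters[1:4], n, replace = TRUE)
    q <- random_binary_matrix(15, d)
    idx <- drfp_knn(x, lab)
    pred <- predict(idx, q, k = 5)
    for (i in seq_len(nrow(q))) {
      dists <- apply(x, 1, function(row) sum(row != q[i, ]))  # literal Hamming
      ord <- order(dists, seq_len(n))[1:5]
      votes <- table(lab[ord])
      top <- names(votes)[votes == max(votes)]
      if (length(top) == 1) {
        expect_equal(as.character(pred[i]), top)
      } else {
        expect_true(as.character(pred[i]) %in% top)
      }
    }
  }
})

test_that("knn boundary behaviour: single row, self query, k clipping", {
  one <- drfp_knn(matrix(c(1L, 0L, 1L), 1, 3), "only")
  expect_equal(as.character(predict(one, matrix(c(0L, 1L, 0L), 1, 3), k = 1)), "only")

  set.seed(2)
  x <- random_binary_matrix(10, 16)
  idx <- drfp_knn(x, rep(c("a", "b"), 5))
  pred_self <- predict(idx, x[3, , drop = FALSE], k = 1)
  expect_equal(as.character(pred_self), "a")

  small <- drfp_knn(x[1:3, ], c("a", "a", "b"))
  expect_warning(predict(small, x[1:2, ], k = 4), "clipped")

  expect_error(drfp_knn(matrix(integer(0), 0, 4), character(0)),
               class = "drfp_empty_training_set")
})

test_that("knn votes deterministically under distance and vote ties", {
  x <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L),
             c(0L, 0L, 1L, 0L), c(0L, 0L, 0L, 1L))
  idx <- drfp_knn(x, c("a", "a", "b", "b"))
  q <- matrix(0L, 1, 4)  # equidistant from all four rows
  p1 <- predict(idx, q, k = 4)
  p2 <- predict(idx, q, k = 4)
  expect_identical(p1, p2)
  expect_equal(as.character(p1), "a")  # tie broken by first-seen order
})

test_that("the MLP separates disjoint bit patterns and is seed-reproducible", {
  set.seed(5)
  n_per <- 40; d <- 32
  xa <- cbind(random_binary_matrix(n_per, d %/% 2, 0.5),
              matrix(0L, n_per, d %/% 2))
  xb <- cbind(matrix(0L, n_per, d %/% 2),
              random_binary_matrix(n_per, d %/% 2, 0.5))
  x <- rbind(xa, xb)
  y <- rep(c("alpha", "beta"), each = n_per)
  fit <- drfp_mlp(x, y, hidden_width = 16, epochs = 10, batch_size = 8, seed = 3)
  expect_equal(mean(predict(fit, x) == y), 1.0)
  # loss decreases over training
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])

  fit2 <- drfp_mlp(x, y, hidden_width = 16, epochs = 10, batch_size = 8, seed = 3)
  expect_identical(predict(fit2, x), predict(fit, x))
  expect_identical(fit2$w1, fit$w1)

  fit3 <- drfp_mlp(x, y, hidden_width = 16, epochs = 10, batch_size = 8, seed = 4)
  expect_false(identical(fit3$w1, fit$w1))

  expect_error(drfp_mlp(x, rep("one", nrow(x))), class = "drfp_label_encoding")
})

test_that("gbm defaults carry the fixed hyperparameter values", {
  hp <- gbm_hyperparams()
  expect_equal(hp$n_estimators, 999999)
  expect_equal(hp$learning_rate, 0.01)
  expect_equal(hp$max_depth, 15)
  expect_equal(hp$min_child_weight, 8)
  expect_equal(hp$colsample_bytree, 0.2125)
  expect_equal(hp$subsample, 1)
  expect_equal(hp$early_stopping_rounds, 20)
  expect_equal(hp$validation_fraction, 0.10)
})

test_that("gbm learns a constant target and respects the validation split", {
  set.seed(9)
  x <- random_binary_matrix(80, 24)
  y <- rep(50, 80)
  fit <- drfp_gbm(x, y, seed = 7)
  expect_true(all(abs(predict(fit, x) - 50) < 0.5))
  expect_equal(length(intersect(fit$validation_rows, fit$training_rows)), 0)
  expect_equal(sort(c(fit$validation_rows, fit$training_rows)), 1:80)
  expect_equal(length(fit$validation_rows), 8)
  expect_lte(fit$best_iteration, gbm_hyperparams()$n_estimators)

  fit2 <- drfp_gbm(x, y, seed = 7)
  expect_identical(fit2$validation_rows, fit$validation_rows)
  expect_identical(fit2$best_iteration, fit$best_iteration)

  expect_error(drfp_gbm(x[1, , drop = FALSE], 50), class = "drfp_too_few_rows")
})

test_that("gbm recovers a learnable additive signal", {
  set.seed(13)
  x <- random_binary_matrix(300, 24, 0.4)
  y <- 40 + 25 * x[, 1] - 15 * x[, 2] + 10 * x[, 3] + rnorm(300, 0, 2)
  sp <- split_train_test(300, 0.7, seed = 1)
  fit <- drfp_gbm(x[sp$train, ], y[sp$train], seed = 2)
  met <- regression_metrics(y[sp$test], predict(fit, x[sp$test, ]))
  expect_gt(met$r_squared, 0.8)
})

test_that("classification metrics match their closed forms and references", {
  perfect <- classification_metrics(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$mcc, 1.0)
  expect_equal(perfect$cen, 0.0)

  # binary confusion matrix [[40,10],[10,40]]
  truth <- rep(c("x", "y"), each = 50)
  pred <- c(rep("x", 40), rep("y", 10), rep("x", 10), rep("y", 40))
  m <- classification_metrics(truth, pred)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$mcc, 0.6)

  # constant prediction over two balanced classes
  m2 <- classification_metrics(rep(c("x", "y"), 25), rep("x", 50))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$mcc, 0.0)

  expect_error(classification_metrics(c("a", "b"), "a"),
               class = "drfp_length_mismatch")

  set.seed(21)
  for (i in 1:20) {
    cm <- random_confusion(sample(2:6, 1))
    if (sum(cm) == 0) next
    expect_equal(drfp:::mcc_from_confusion(cm), ref_mcc(cm), tolerance = 1e-12)
    expect_equal(drfp:::cen_from_confusion(cm), ref_cen(cm), tolerance = 1e-12)
  }
})

test_that("regression metrics reproduce the worked R-squared examples", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3))$r_squared, 1.0)
  expect_equal(regression_metrics(c(1, 2, 3), rep(2, 3))$r_squared, 0.0)
  expect_equal(regression_metrics(c(0, 10, 20), c(0, 10, 30))$r_squared, 0.5)
  expect_error(regression_metrics(c(5, 5, 5), c(1, 2, 3)),
               class = "drfp_constant_truth")
  expect_error(regression_metrics(1:3, 1:4), class = "drfp_length_mismatch")
})
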