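# Downstream harnesses: exact 5-nearest-neighbour classification on Hamming
# distance, a single-hidden-layer MLP classifier trained with Adam, and
# gradient-boosting yield regression via xgboost with early stopping.

as_fp_matrix <- function(x) {
  m <- fp_matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Seeded train/test split
#'
#' @param n number of rows.
#' @param train_fraction fraction assigned to the training set.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, train_fraction = 0.7, seed = 1) {
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

# -- k-nearest neighbours -----------------------------------------------------

#' Fit an exact nearest-neighbour classifier on binary fingerprints
#'
#' Distances are Hamming counts; on 0/1 vectors this ranks neighbours
#' identically to squared Euclidean distance. The search is exact (full
#' pairwise scan via matrix products).
#'
#' @param x n-by-d binary matrix or `drfp_fingerprints`.
#' @param labels class labels, one per row.
#' @return object of class `drfp_knn`.
#' @export
drfp_knn <- function(x, labels) {
  m <- as_fp_matrix(x)
  if (nrow(m) == 0)
    drfp_error("drfp_empty_training_set", "cannot fit a neighbour index on 0 rows")
  stopifnot(length(labels) == nrow(m))
  structure(list(x = m, labels = as.factor(labels), row_sums = rowSums(m)),
            class = "drfp_knn")
}

#' @export
print.drfp_knn <- function(x, ...) {
  cat(sprintf("exact Hamming k-NN index: %d reactions x %d bits, %d classes\n",
              nrow(x$x), ncol(x$x), nlevels(x$labels)))
  invisible(x)
}

#' Predict classes by majority vote among the k nearest training rows
#'
#' Vote ties are broken by the smaller summed distance of the tied classes,
#' then by first-seen order among the ordered neighbours; neighbour distance
#' ties are broken by training-row index. Fully deterministic.
#'
#' @param object a `drfp_knn` index.
#' @param newdata query matrix (or `drfp_fingerprints`).
#' @param k number of neighbours (default 5); clipped to the training size
#'   with a warning when larger.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.drfp_knn <- function(object, newdata, k = 5, ...) {
  q <- as_fp_matrix(newdata)
  n_train <- nrow(object$x)
  if (k > n_train) {
    warning(sprintf("k = %d exceeds training size %d; clipped", k, n_train),
            call. = FALSE)
    k <- n_train
  }
  # Hamming distance between 0/1 rows: |a| + |b| - 2 a.b
  cross <- tcrossprod(q, object$x)
  d_mat <- outer(rowSums(q), object$row_sums, "+") - 2 * cross
  lab <- as.character(object$labels)
  out <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    ord <- order(d_mat[i, ], seq_len(n_train))[seq_len(k)]
    cls <- lab[ord]
    dst <- d_mat[i, ord]
    first_seen <- unique(cls)
    counts <- vapply(first_seen, function(cl) sum(cls == cl), numeric(1))
    cand <- first_seen[counts == max(counts)]
    if (length(cand) > 1) {
      sums <- vapply(cand, function(cl) sum(dst[cls == cl]), numeric(1))
      cand <- cand[sums == min(sums)]
    }
    out[i] <- cand[1]
  }
  factor(out, levels = levels(object$labels))
}

# -- multilayer perceptron ----------------------------------------------------

#' Fit a single-hidden-layer MLP classifier
#'
#' Architecture: dense hidden layer (default width 1664) with tanh
#' activation, dense softmax output, sparse categorical cross-entropy loss,
#' Adam optimizer (learning rate 0.001), minibatch training for a fixed
#' number of epochs. All randomness (Glorot initialization, shuffling)
#' derives from `seed`, so identical calls give identical models.
#'
#' @param x n-by-d binary matrix or `drfp_fingerprints`.
#' @param labels class labels (at least two distinct classes).
#' @param hidden_width hidden layer size; default 1664.
#' @param epochs training epochs; default 10.
#' @param batch_size minibatch size; default 64.
#' @param learning_rate Adam step size; default 0.001.
#' @param seed integer seed.
#' @return object of class `drfp_mlp` with the learned weights and the
#'   per-epoch mean training loss.
#' @export
drfp_mlp <- function(x, labels, hidden_width = 1664, epochs = 10,
                     batch_size = 64, learning_rate = 0.001, seed = 1) {
  m <- as_fp_matrix(x)
  labels <- as.factor(labels)
  stopifnot(length(labels) == nrow(m))
  n_class <- nlevels(labels)
  if (n_class < 2)
    drfp_error("drfp_label_encoding",
               "need at least two classes (softmax over one class is degenerate)")
  n <- nrow(m); d <- ncol(m); h <- as.integer(hidden_width)
  y <- as.integer(labels)

  with_seed(seed, {
    lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + n_class))
    w1 <- matrix(runif(d * h, -lim1, lim1), d, h)
    b1 <- numeric(h)
    w2 <- matrix(runif(h * n_class, -lim2, lim2), h, n_class)
    b2 <- numeric(n_class)

    adam <- function(dim) list(m = array(0, dim), v = array(0, dim))
    st <- list(w1 = adam(dim(w1)), b1 = adam(h), w2 = adam(dim(w2)), b2 = adam(n_class))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    upd <- function(param, grad, s) {
      s$m <- beta1 * s$m + (1 - beta1) * grad
      s$v <- beta2 * s$v + (1 - beta2) * grad^2
      mhat <- s$m / (1 - beta1^t_step)
      vhat <- s$v / (1 - beta2^t_step)
      list(param = param - learning_rate * mhat / (sqrt(vhat) + eps), state = s)
    }

    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        xb <- m[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)

        hid <- tanh(sweep(xb %*% w1, 2, b1, "+"))
        logits <- sweep(hid %*% w2, 2, b2, "+")
        logits <- logits - apply(logits, 1, max)
        expl <- exp(logits)
        probs <- expl / rowSums(expl)
        losses <- c(losses, -mean(log(pmax(probs[cbind(seq_len(nb), yb)], 1e-12))))

        dlogits <- probs
        dlogits[cbind(seq_len(nb), yb)] <- dlogits[cbind(seq_len(nb), yb)] - 1
        dlogits <- dlogits / nb
        gw2 <- crossprod(hid, dlogits)
        gb2 <- colSums(dlogits)
        dhid <- tcrossprod(dlogits, w2) * (1 - hid^2)
        gw1 <- crossprod(xb, dhid)
        gb1 <- colSums(dhid)

        t_step <- t_step + 1
        r <- upd(w1, gw1, st$w1); w1 <- r$param; st$w1 <- r$state
        r <- upd(b1, gb1, st$b1); b1 <- r$param; st$b1 <- r$state
        r <- upd(w2, gw2, st$w2); w2 <- r$param; st$w2 <- r$state
        r <- upd(b2, gb2, st$b2); b2 <- r$param; st$b2 <- r$state
      }
      loss_hist[ep] <- mean(losses)
    }
    structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                   levels = levels(labels), loss = loss_hist,
                   hidden_width = h, epochs = epochs, batch_size = batch_size,
                   learning_rate = learning_rate, seed = seed),
              class = "drfp_mlp")
  })
}

#' @export
print.drfp_mlp <- function(x, ...) {
  cat(sprintf("MLP classifier: %d-%d-%d (tanh/softmax), %d epochs, final loss %.4f\n",
              nrow(x$w1), x$hidden_width, length(x$levels),
              x$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict from a fitted MLP
#'
#' @param object a `drfp_mlp`.
#' @param newdata query matrix (or `drfp_fingerprints`).
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return factor of classes or numeric probability matrix.
#' @export
predict.drfp_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  q <- as_fp_matrix(newdata)
  hid <- tanh(sweep(q %*% object$w1, 2, object$b1, "+"))
  logits <- sweep(hid %*% object$w2, 2, object$b2, "+")
  logits <- logits - apply(logits, 1, max)
  expl <- exp(logits)
  probs <- expl / rowSums(expl)
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

# -- gradient boosting --------------------------------------------------------

#' Gradient-boosting hyperparameters
#'
#' Defaults are the fixed values used for all yield-regression benchmarks:
#' effectively unbounded rounds with early stopping on a held-out 10%
#' validation slice of the training data.
#'
#' @param n_estimators maximum boosting rounds (default 999999).
#' @param learning_rate shrinkage (default 0.01).
#' @param max_depth maximum tree depth (default 15).
#' @param min_child_weight minimum child weight (default 8).
#' @param colsample_bytree column subsample per tree (default 0.2125).
#' @param subsample row subsample (default 1).
#' @param early_stopping_rounds stop after this many rounds without
#'   validation improvement (default 20).
#' @param validation_fraction fraction of training rows held out for early
#'   stopping (default 0.10).
#' @return object of class `drfp_gbm_params`.
#' @export
gbm_hyperparams <- function(n_estimators = 999999, learning_rate = 0.01,
                            max_depth = 15, min_child_weight = 8,
                            colsample_bytree = 0.2125, subsample = 1,
                            early_stopping_rounds = 20,
                            validation_fraction = 0.10) {
  structure(list(n_estimators = n_estimators, learning_rate = learning_rate,
                 max_depth = max_depth, min_child_weight = min_child_weight,
                 colsample_bytree = colsample_bytree, subsample = subsample,
                 early_stopping_rounds = early_stopping_rounds,
                 validation_fraction = validation_fraction),
            class = "drfp_gbm_params")
}

#' Fit the gradient-boosting yield regressor
#'
#' A seeded random `validation_fraction` of the training rows is held out;
#' boosting runs until the validation RMSE fails to improve for
#' `early_stopping_rounds` rounds, and the model at the best validation round
#' is used for prediction.
#'
#' @param x n-by-d binary matrix or `drfp_fingerprints`.
#' @param y numeric yields (percent).
#' @param params a [gbm_hyperparams()] object.
#' @param seed integer seed (validation split and xgboost RNG).
#' @param nthread xgboost threads; default 1.
#' @return object of class `drfp_gbm` with the booster, the best iteration
#'   and the validation row indices.
#' @export
drfp_gbm <- function(x, y, params = gbm_hyperparams(), seed = 1, nthread = 1) {
  m <- as_fp_matrix(x)
  stopifnot(inherits(params, "drfp_gbm_params"), length(y) == nrow(m))
  n <- nrow(m)
  n_val <- max(1L, round(params$validation_fraction * n))
  if (n < 2 || n - n_val < 1)
    drfp_error("drfp_too_few_rows",
               sprintf("%d rows cannot be split into training and validation", n))
  val_idx <- with_seed(seed, sort(sample.int(n, n_val)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  dtrain <- xgboost::xgb.DMatrix(m[tr_idx, , drop = FALSE], label = y[tr_idx])
  dval <- xgboost::xgb.DMatrix(m[val_idx, , drop = FALSE], label = y[val_idx])
  booster <- xgboost::xgb.train(
    params = list(eta = params$learning_rate,
                  max_depth = params$max_depth,
                  min_child_weight = params$min_child_weight,
                  colsample_bytree = params$colsample_bytree,
                  subsample = params$subsample,
                  objective = "reg:squarederror",
                  nthread = nthread,
                  seed = seed),
    data = dtrain, nrounds = params$n_estimators,
    evals = list(validation = dval),
    early_stopping_rounds = params$early_stopping_rounds,
    verbose = 0)
  best <- as.integer(xgboost::xgb.attr(booster, "best_iteration"))
  structure(list(booster = booster, best_iteration = best,
                 params = params, seed = seed,
                 validation_rows = val_idx, training_rows = tr_idx),
            class = "drfp_gbm")
}

#' @export
print.drfp_gbm <- function(x, ...) {
  cat(sprintf("gradient-boosting yield regressor: best iteration %d (early stopping %d rounds)\n",
              x$best_iteration, x$params$early_stopping_rounds))
  invisible(x)
}

#' Predict yields from a fitted gradient-boosting model
#'
#' Uses the trees up to the best validation round.
#'
#' @param object a `drfp_gbm`.
#' @param newdata query matrix (or `drfp_fingerprints`).
#' @param ... unused.
#' @return numeric vector of predicted yields.
#' @export
predict.drfp_gbm <- function(object, newdata, ...) {
  q <- as_fp_matrix(newdata)
  predict(object$booster, xgboost::xgb.DMatrix(q),
          iterationrange = c(1, object$best_iteration))
}
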