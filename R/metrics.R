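# Evaluation metrics for the classification and regression harnesses:
# accuracy, multiclass Matthews correlation coefficient, confusion entropy
# (CEN), and the coefficient of determination.

#' Confusion matrix with a common level set
#'
#' @param truth,predicted equal-length label vectors.
#' @return square integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    drfp_error("drfp_length_mismatch",
               sprintf("truth has %d elements, predicted has %d",
                       length(truth), length(predicted)))
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  table(factor(as.character(truth), levels = lev),
        factor(as.character(predicted), levels = lev))
}

# multiclass Matthews correlation from the confusion matrix
# (covariance form: (c*s - sum p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2)))
mcc_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  if (den == 0) return(0)
  num / den
}

# Confusion entropy (CEN): per-class entropy of the misclassification
# probabilities in log base 2(N-1), weighted by the class marginals.
# 0 for a diagonal matrix; for N = 1 the measure is defined as 0.
cen_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (n < 2) return(0)
  total <- sum(cm)
  if (total == 0) return(0)
  logb <- function(x) log(x, base = 2 * (n - 1))
  row_s <- rowSums(cm)
  col_s <- colSums(cm)
  cen_j <- numeric(n)
  for (j in seq_len(n)) {
    denom <- row_s[j] + col_s[j]
    if (denom == 0) next
    acc <- 0
    for (k in seq_len(n)) {
      if (k == j) next
      p_out <- cm[j, k] / denom   # j misclassified as k
      p_in <- cm[k, j] / denom    # k misclassified as j
      if (p_out > 0) acc <- acc - p_out * logb(p_out)
      if (p_in > 0) acc <- acc - p_in * logb(p_in)
    }
    cen_j[j] <- acc
  }
  p_j <- (row_s + col_s) / (2 * total)
  sum(p_j * cen_j)
}

#' Classification metrics: accuracy, MCC, CEN
#'
#' @param truth,predicted equal-length label vectors.
#' @return object of class `drfp_class_metrics`: list with `accuracy`, `mcc`,
#'   `cen` and the `confusion` matrix (rows = truth).
#' @examples
#' classification_metrics(c("a", "a", "b"), c("a", "b", "b"))
#' @export
classification_metrics <- function(truth, predicted) {
  cm <- confusion_matrix(truth, predicted)
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 mcc = mcc_from_confusion(cm),
                 cen = cen_from_confusion(cm),
                 confusion = cm),
            class = "drfp_class_metrics")
}

#' @export
print.drfp_class_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.4f   MCC: %.4f   CEN: %.4f\n", x$accuracy, x$mcc, x$cen))
  invisible(x)
}

#' Regression metrics: R squared (plus RMSE and MAE)
#'
#' @param truth,predicted equal-length numeric vectors; `truth` must not be
#'   constant.
#' @return object of class `drfp_reg_metrics`: list with `r_squared`, `rmse`,
#'   `mae`.
#' @examples
#' regression_metrics(c(0, 10, 20), c(0, 10, 30))$r_squared  # 0.5
#' @export
regression_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    drfp_error("drfp_length_mismatch",
               sprintf("truth has %d elements, predicted has %d",
                       length(truth), length(predicted)))
  truth <- as.numeric(truth); predicted <- as.numeric(predicted)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0)
    drfp_error("drfp_constant_truth", "truth vector is constant; R squared undefined")
  ss_res <- sum((truth - predicted)^2)
  structure(list(r_squared = 1 - ss_res / ss_tot,
                 rmse = sqrt(mean((truth - predicted)^2)),
                 mae = mean(abs(truth - predicted))),
            class = "drfp_reg_metrics")
}

#' @export
print.drfp_reg_metrics <- function(x, ...) {
  cat(sprintf("R^2: %.4f   RMSE: %.3f   MAE: %.3f\n", x$r_squared, x$rmse, x$mae))
  invisible(x)
}
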