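# Internal and external validation statistics for linear QSAR models.

#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot` with the total sum of squares about the
#' mean of the observed values.
#'
#' @param y_actual observed activities.
#' @param y_pred predicted activities, same length and order.
#' @return the coefficient of determination (can be negative for
#'   predictions worse than the observed mean).
#' @export
r2 <- function(y_actual, y_pred) {
  stopifnot(length(y_actual) == length(y_pred), length(y_actual) >= 2L)
  sst <- sum((y_actual - mean(y_actual))^2)
  if (sst == 0) stop("zero variance in observed activities", call. = FALSE)
  1 - sum((y_actual - y_pred)^2) / sst
}

#' Adjusted coefficient of determination
#'
#' `r2_adj = 1 - (1 - r2) (N - 1) / (N - c)` with `c = k + 1` variables
#' counting the regression constant, so `(0.803, N = 19, k = 2)` gives
#' 0.778.
#'
#' @param r2_value training coefficient of determination.
#' @param n training-set size.
#' @param k_descriptors number of descriptors (excluding the constant).
#' @return adjusted r squared.
#' @export
adjusted_r2 <- function(r2_value, n, k_descriptors) {
  c_vars <- k_descriptors + 1L
  if (n <= c_vars) stop("training-set size must exceed the number of",
                        " fitted parameters", call. = FALSE)
  1 - (1 - r2_value) * (n - 1) / (n - c_vars)
}

#' Root mean square error
#'
#' @param y_actual observed activities.
#' @param y_pred predicted activities.
#' @return `sqrt(mean((y_actual - y_pred)^2))`.
#' @export
rms_error <- function(y_actual, y_pred) {
  stopifnot(length(y_actual) == length(y_pred))
  sqrt(mean((y_actual - y_pred)^2))
}

#' Leave-one-out cross-validated q2
#'
#' Each training compound is removed in turn, the model refit on the
#' remainder and the removed compound predicted; `q2 = 1 - PRESS /
#' SS_tot` with `SS_tot` about the full training mean.  The default
#' `"press"` method uses the algebraically identical hat-matrix
#' shortcut (deleted residual = residual / (1 - leverage)); `"refit"`
#' performs the explicit refits.
#'
#' @param x descriptor matrix.
#' @param y named activity vector.
#' @param train_ids training compound ids.
#' @param descriptors descriptor subset of the model.
#' @param method `"press"` (hat-matrix shortcut) or `"refit"`
#'   (brute-force refits).
#' @return the cross-validated determination coefficient.
#' @export
q2_loo <- function(x, y, train_ids, descriptors = colnames(x),
                   method = c("press", "refit")) {
  method <- match.arg(method)
  .check_xy(x, y, train_ids)
  n <- length(train_ids)
  k <- length(descriptors)
  stopifnot(n > k + 2L)
  yy <- y[train_ids]
  sst <- sum((yy - mean(yy))^2)
  if (method == "press") {
    X <- cbind(1, x[train_ids, descriptors, drop = FALSE])
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) stop("rank-deficient leave-one-out fit",
                                 call. = FALSE)
    res <- qr.resid(qrx, yy)
    h <- rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
    press <- sum((res / (1 - h))^2)
  } else {
    press <- sum(vapply(seq_len(n), function(i) {
      keep <- train_ids[-i]
      fit <- fit_mlr(x, y, keep, descriptors)
      (yy[i] - predict(fit, x[train_ids[i], , drop = FALSE]))^2
    }, numeric(1)))
  }
  1 - press / sst
}

#' Leave-many-out cross-validated q2
#'
#' Repeats random deletion of `ceiling(leave_fraction * n)` training
#' compounds: the model is refit without them and the deleted
#' activities predicted.  Squared prediction errors are pooled over all
#' rounds and scaled by the deviations of the same deleted entries from
#' the full training mean.
#'
#' @inheritParams q2_loo
#' @param leave_fraction fraction of the training set deleted per round
#'   (default 0.2).
#' @param n_rounds number of deletion rounds (default 25).
#' @param seed integer seed controlling the deletions.
#' @return the leave-many-out determination coefficient, with
#'   attributes `n_rounds` and `seed`.
#' @export
q2_lmo <- function(x, y, train_ids, descriptors = colnames(x),
                   leave_fraction = 0.2, n_rounds = 25L, seed = NULL) {
  .check_xy(x, y, train_ids)
  n <- length(train_ids)
  n_out <- max(1L, ceiling(leave_fraction * n))
  stopifnot(n - n_out > length(descriptors) + 1L)
  yy <- y[train_ids]
  ybar <- mean(yy)
  .with_seed(seed, {
    press <- 0; denom <- 0
    for (r in seq_len(n_rounds)) {
      out <- sample(train_ids, n_out)
      fit <- fit_mlr(x, y, setdiff(train_ids, out), descriptors)
      pred <- predict(fit, x[out, , drop = FALSE])
      press <- press + sum((y[out] - pred)^2)
      denom <- denom + sum((y[out] - ybar)^2)
    }
    structure(1 - press / denom, n_rounds = n_rounds, seed = seed)
  })
}

#' External test-set predictivity
#'
#' `pred_r2 = 1 - sum((y_act - y_pred)^2) / sum((y_act - y_mean)^2)`
#' over the test set, with the centering mean taken from the TRAINING
#' set, so predicting the training mean for every test compound scores
#' exactly zero.
#'
#' @param model an `fq_mlr` model.
#' @param x descriptor matrix.
#' @param y named activity vector.
#' @param test_ids test compound ids (disjoint from the training set).
#' @param train_ids training ids used for the centering mean (defaults
#'   to the model's).
#' @return the external determination coefficient.
#' @export
pred_r2 <- function(model, x, y, test_ids,
                    train_ids = model$training_ids) {
  if (!length(test_ids)) stop("empty test set", call. = FALSE)
  stopifnot(length(test_ids) >= 2L)
  if (length(intersect(train_ids, test_ids))) {
    stop("training and test sets overlap", call. = FALSE)
  }
  .check_xy(x, y, test_ids)
  pred <- predict(model, x[test_ids, , drop = FALSE])
  ymean <- mean(y[train_ids])
  1 - sum((y[test_ids] - pred)^2) / sum((y[test_ids] - ymean)^2)
}

#' Assemble a full validation report
#'
#' Computes, for one model and one train/test split, the full statistic
#' set used to judge a QSAR model: training-set size and determination
#' coefficient, adjusted r2, leave-one-out and leave-many-out q2,
#' external predictivity, the overall determination coefficient over
#' the union of training and test compounds, the training RMS error and
#' the Friedman lack-of-fit.
#'
#' @param model an `fq_mlr` model.
#' @param x descriptor matrix.
#' @param y named activity vector.
#' @param train_ids,test_ids the split.
#' @param lmo_fraction,lmo_rounds,lmo_seed leave-many-out settings.
#' @param d_smooth lack-of-fit smoothing parameter.
#' @param count_intercept lack-of-fit `c`-counting convention.
#' @return an object of class `fq_validation`.
#' @export
build_report <- function(model, x, y, train_ids, test_ids,
                         lmo_fraction = 0.2, lmo_rounds = 25L,
                         lmo_seed = NULL, d_smooth = 0.5,
                         count_intercept = FALSE) {
  desc <- model$descriptor_names
  k <- length(desc)
  n <- length(train_ids)
  refit <- fit_mlr(x, y, train_ids, desc)
  sse <- sum(refit$residuals^2)
  all_ids <- c(train_ids, test_ids)
  pred_all <- predict(model, x[all_ids, , drop = FALSE])
  q2lmo <- q2_lmo(x, y, train_ids, desc, lmo_fraction, lmo_rounds,
                  lmo_seed)
  contributions <- if (k >= 2L) {
    relative_contribution(refit, x, y, train_ids)
  } else setNames(100 * sign(refit$coefficients), desc)
  structure(list(
    n_train = n,
    r2_tr = refit$r2_train,
    r2_adj = adjusted_r2(refit$r2_train, n, k),
    q2_loo = q2_loo(x, y, train_ids, desc),
    q2_lmo = as.numeric(q2lmo),
    pred_r2 = pred_r2(model, x, y, test_ids, train_ids),
    r2_all = r2(y[all_ids], pred_all),
    rms_error = rms_error(y[train_ids], refit$fitted),
    lof = lof(sse, k + if (count_intercept) 1L else 0L, k, n, d_smooth),
    contributions = contributions,
    descriptors = desc,
    train_ids = train_ids, test_ids = test_ids,
    settings = list(lmo_fraction = lmo_fraction, lmo_rounds = lmo_rounds,
                    lmo_seed = lmo_seed, d_smooth = d_smooth,
                    count_intercept = count_intercept)
  ), class = "fq_validation")
}

#' @export
print.fq_validation <- function(x, digits = 3, ...) {
  cat("QSAR validation report\n")
  cat("  descriptors:", paste(x$descriptors, collapse = ", "), "\n")
  df <- as.data.frame(x)
  rownames(df) <- NULL
  print(df, digits = digits, row.names = TRUE)
  cat("  relative contributions (%):\n")
  for (d in names(x$contributions)) {
    cat(sprintf("    %-12s %8.2f\n", d, x$contributions[[d]]))
  }
  invisible(x)
}

#' @export
as.data.frame.fq_validation <- function(x, ...) {
  data.frame(statistic = c("N", "r_tr^2", "r^2_adj", "q^2", "LMO-q^2",
                           "pred_r^2", "R^2", "RMS error", "LOF"),
             value = c(x$n_train, x$r2_tr, x$r2_adj, x$q2_loo, x$q2_lmo,
                       x$pred_r2, x$r2_all, x$rms_error, x$lof))
}

#' Write a validation report as CSV
#'
#' @param report an `fq_validation` object.
#' @param path output CSV path.
#' @export
write_validation_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
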