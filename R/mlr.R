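# Ordinary least-squares QSAR models on descriptor subsets, constrained
# train/test splitting, and the Friedman lack-of-fit score.

# Run expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is untouched.  NULL seed means use (and advance) the
# current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_xy <- function(x, y, ids) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(names(y)))
  missing_ids <- setdiff(ids, rownames(x))
  if (length(missing_ids)) stop("compound ids missing from descriptors: ",
                                paste(missing_ids, collapse = ", "),
                                call. = FALSE)
  missing_y <- setdiff(ids, names(y))
  if (length(missing_y)) stop("compound ids missing from activities: ",
                              paste(missing_y, collapse = ", "),
                              call. = FALSE)
  invisible(TRUE)
}

#' Constrained random training/test split
#'
#' Splits compounds into training (default 80 percent) and test sets by
#' rejection sampling: random splits are drawn until the test set's
#' activity range lies inside the training set's range, i.e.
#' `max(test) <= max(train)` and `min(test) >= min(train)`, so the test
#' set never requires extrapolation.
#'
#' @param y named activity vector.
#' @param test_fraction fraction of compounds in the test set
#'   (default 0.2); the test size is `round(n * test_fraction)`.
#' @param seed integer seed making the split reproducible.
#' @param max_rejections abort after this many unconstrained draws.
#' @return list with `train_ids`, `test_ids` and `rejections` (number
#'   of draws discarded before the constraints held).
#' @export
split_train_test <- function(y, test_fraction = 0.2, seed = NULL,
                             max_rejections = 10000L) {
  n <- length(y)
  stopifnot(n >= 5L, test_fraction > 0, test_fraction < 1)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("test fraction leaves no training compounds",
                        call. = FALSE)
  ids <- names(y)
  .with_seed(seed, {
    for (rejections in 0:max_rejections) {
      test_ids <- sort(sample(ids, n_test))
      train_ids <- setdiff(ids, test_ids)
      if (max(y[test_ids]) <= max(y[train_ids]) &&
          min(y[test_ids]) >= min(y[train_ids])) {
        return(list(train_ids = train_ids, test_ids = test_ids,
                    rejections = rejections))
      }
    }
    stop("no constraint-satisfying split found within ", max_rejections,
         " rejections", call. = FALSE)
  })
}

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares for `y = a_1 x_1 + ... + a_n x_n + c` on a
#' chosen descriptor subset and training set.
#'
#' @param x descriptor matrix (compounds x descriptors).
#' @param y named activity vector.
#' @param train_ids compound ids to fit on; defaults to all rows of `x`.
#' @param descriptors descriptor (column) names to include; defaults to
#'   all columns.
#' @return an object of class `fq_mlr` with components
#'   `descriptor_names`, `coefficients` (named, excluding intercept),
#'   `intercept`, `training_ids`, `fitted`, `residuals`, `sigma` and
#'   `r2_train`.
#' @export
fit_mlr <- function(x, y, train_ids = rownames(x),
                    descriptors = colnames(x)) {
  .check_xy(x, y, train_ids)
  bad <- setdiff(descriptors, colnames(x))
  if (length(bad)) stop("missing descriptor column(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  X <- x[train_ids, descriptors, drop = FALSE]
  yy <- y[train_ids]
  k <- ncol(X)
  if (length(train_ids) <= k + 1L) {
    stop("need more training compounds than coefficients", call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(Xd, yy)
  if (fit$rank < ncol(Xd)) {
    dep <- colnames(Xd)[is.na(fit$coefficients)]
    stop("rank-deficient fit; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  cf <- fit$coefficients
  res <- unname(fit$residuals)
  sst <- sum((yy - mean(yy))^2)
  structure(list(
    descriptor_names = descriptors,
    coefficients = cf[-1],
    intercept = unname(cf[1]),
    training_ids = train_ids,
    fitted = setNames(unname(fit$fitted.values), train_ids),
    residuals = setNames(res, train_ids),
    sigma = sqrt(sum(res^2) / (length(yy) - k - 1L)),
    r2_train = if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  ), class = "fq_mlr")
}

#' Construct a linear model from known coefficients
#'
#' Builds an `fq_mlr` object directly from published coefficients so a
#' published equation can be evaluated on new descriptor tables.  The two
#' regression equations of the bundled cross-reactivity study are
#' available via [paper_model()].
#'
#' @param coefficients named numeric vector (descriptor name -> slope).
#' @param intercept regression constant.
#' @param training_ids optional ids of the compounds the model was
#'   trained on, when known.
#' @return an `fq_mlr` object (without fit diagnostics).
#' @export
mlr_model <- function(coefficients, intercept, training_ids = character(0)) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(descriptor_names = names(coefficients),
                 coefficients = coefficients,
                 intercept = unname(intercept),
                 training_ids = training_ids,
                 fitted = NULL, residuals = NULL,
                 sigma = NA_real_, r2_train = NA_real_),
            class = "fq_mlr")
}

#' Published regression models of the bundled study
#'
#' The two reported equations: for the anti-ciprofloxacin system,
#' `log CR = 4.338 + 0.337 N(>CH-) - 0.075 Shadow-YZ`; for the
#' anti-clinafloxacin system,
#' `log CR = -0.225 + 1.633 N(>CH-) + 0.303 S(>CH-) - 1.749 N(Stereo)`.
#'
#' @param system `"cip"` or `"cli"`.
#' @return an `fq_mlr` object with the published coefficients.
#' @export
paper_model <- function(system = c("cip", "cli")) {
  system <- match.arg(system)
  if (system == "cip") {
    mlr_model(c("N(>CH-)" = 0.337, "Shadow-YZ" = -0.075), 4.338)
  } else {
    mlr_model(c("N(>CH-)" = 1.633, "S(>CH-)" = 0.303,
                "N(Stereo)" = -1.749), -0.225)
  }
}

#' @export
print.fq_mlr <- function(x, digits = 4, ...) {
  terms <- paste(sprintf("%+.*g x %s", digits, x$coefficients,
                         x$descriptor_names), collapse = " ")
  cat("Linear QSAR model: log CR =",
      format(x$intercept, digits = digits), terms, "\n")
  if (length(x$training_ids)) {
    cat("Training set:", length(x$training_ids), "compounds\n")
  }
  if (!is.na(x$r2_train)) {
    cat("Training r2:", format(x$r2_train, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
coef.fq_mlr <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict activities from a linear QSAR model
#'
#' @param object an `fq_mlr` model.
#' @param newdata descriptor matrix containing all model descriptors.
#' @param ... unused.
#' @return named numeric vector of predicted log10 activities.
#' @export
predict.fq_mlr <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(missing_cols)) stop("missing descriptor column(s): ",
                                 paste(missing_cols, collapse = ", "),
                                 call. = FALSE)
  X <- newdata[, object$descriptor_names, drop = FALSE]
  setNames(drop(X %*% object$coefficients) + object$intercept,
           rownames(newdata))
}

#' @export
residuals.fq_mlr <- function(object, ...) object$residuals

#' @export
fitted.fq_mlr <- function(object, ...) object$fitted

#' Simulate activities from a fitted model
#'
#' Draws `y = prediction + N(0, sigma^2)` with `sigma` the residual
#' standard error of the fit (or a supplied value, required for models
#' entered from published coefficients).
#'
#' @param object an `fq_mlr` model.
#' @param nsim number of simulated activity vectors.
#' @param seed optional integer seed.
#' @param newdata descriptor matrix to simulate at; defaults to the
#'   training rows used to fit the model.
#' @param sigma noise standard deviation override.
#' @param ... unused.
#' @return a data.frame with `nsim` columns of simulated activities.
#' @export
simulate.fq_mlr <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            sigma = object$sigma, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted)) stop("supply newdata for a model without",
                                     " stored training data", call. = FALSE)
    mu <- object$fitted
  } else {
    mu <- predict(object, newdata)
  }
  if (is.na(sigma)) stop("no residual sigma available; supply sigma",
                         call. = FALSE)
  .with_seed(seed, {
    out <- replicate(nsim, mu + rnorm(length(mu), 0, sigma))
    as.data.frame(out, row.names = names(mu))
  })
}

#' Plot observed versus fitted activities
#'
#' @param x an `fq_mlr` model fitted with [fit_mlr()].
#' @param y named observed activity vector (defaults to fitted +
#'   residuals of the training set).
#' @param ... passed to [plot.default()].
#' @method plot fq_mlr
#' @export
plot.fq_mlr <- function(x, y = NULL, ...) {
  if (is.null(y)) y <- x$fitted + x$residuals
  plot.default(y[names(x$fitted)], x$fitted,
               xlab = "observed log CR", ylab = "fitted log CR", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Friedman lack-of-fit score
#'
#' The size-penalized error `LOF = SSE / (1 - (c + d p) / N)^2` used as
#' the selection criterion in genetic function approximation: `SSE` is
#' the training sum of squared errors, `c` the number of fitted terms
#' (excluding the constant), `p` the total number of descriptors in the
#' model terms, `d` a smoothing parameter (default 0.5 here and in the
#' bundled study) and `N` the training-set size.
#'
#' @param sse training sum of squared errors.
#' @param c_terms number of model terms excluding the constant.
#' @param p_total total descriptor count over all terms.
#' @param n training-set size.
#' @param d smoothing parameter.
#' @return the lack-of-fit score.
#' @export
lof <- function(sse, c_terms, p_total, n, d = 0.5) {
  stopifnot(sse >= 0, n > 0)
  denom <- 1 - (c_terms + d * p_total) / n
  if (denom <= 0) stop("model too large for training-set size (",
                       "c + d p >= N)", call. = FALSE)
  sse / denom^2
}
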