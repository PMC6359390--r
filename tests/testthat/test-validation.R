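test_that("determination coefficient behaves at its anchor points", {
  y <- c(1, 2, 3, 4)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 4)), 0)
  expect_error(r2(rep(1, 4), y), "zero variance")
})

test_that("adjusted r2 counts the regression constant as a variable", {
  expect_equal(adjusted_r2(0.803, 19, 2), 0.778, tolerance = 5e-4)
  expect_equal(adjusted_r2(0.934, 20, 3), 0.9216, tolerance = 5e-4)
  expect_equal(adjusted_r2(1, 10, 3), 1)
  expect_error(adjusted_r2(0.9, 4, 3), "exceed")
  # strictly below r2 for any non-trivial fit
  withr::with_seed(21, {
    for (rep in 1:20) {
      r <- runif(1, 0.05, 0.95)
      n <- sample(8:40, 1)
      k <- sample(1:4, 1)
      expect_lt(adjusted_r2(r, n, k), r)
    }
  })
})

test_that("rms error scales with the residuals", {
  expect_equal(rms_error(1:4, 1:4), 0)
  expect_equal(rms_error(c(0, 0), c(1, -1)), 1)
  y <- c(0.3, -0.2, 0.6)
  p <- c(0.1, 0.1, 0.2)
  expect_equal(rms_error(y, 3 * (y - p) + y), 3 * rms_error(y, y - (y - p)),
               tolerance = 1e-12)
})

test_that("leave-one-out shortcut equals brute-force refitting", {
  for (seed in 1:50) {
    prob <- random_problem(15, 3, seed = 200 + seed)
    a <- q2_loo(prob$x, prob$y, rownames(prob$x), method = "press")
    b <- q2_loo(prob$x, prob$y, rownames(prob$x), method = "refit")
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("leave-one-out q2 is exact on noiseless data and below
           the training r2 on noisy data", {
  withr::with_seed(31, {
    x <- matrix(rnorm(60), 20, 3,
                dimnames = list(sprintf("c%02d", 1:20), c("a", "b", "c")))
    y <- setNames(drop(x %*% c(1, -2, 0.5)) + 2, rownames(x))
    expect_equal(q2_loo(x, y, rownames(x)), 1, tolerance = 1e-10)
  })
  for (seed in 1:100) {
    prob <- random_problem(14, 2, seed = 300 + seed, sigma = 1)
    fit <- fit_mlr(prob$x, prob$y)
    expect_lte(q2_loo(prob$x, prob$y, rownames(prob$x)),
               fit$r2_train + 1e-12)
  }
})

test_that("leave-many-out approaches leave-one-out as the block shrinks", {
  prob <- random_problem(20, 2, seed = 41, sigma = 0.5)
  loo <- q2_loo(prob$x, prob$y, rownames(prob$x))
  lmo <- vapply(1:30, function(s)
    as.numeric(q2_lmo(prob$x, prob$y, rownames(prob$x),
                      leave_fraction = 1 / 20, n_rounds = 60, seed = s)),
    numeric(1))
  expect_equal(mean(lmo), loo, tolerance = 0.05)
  expect_equal(as.numeric(q2_lmo(prob$x, prob$y, rownames(prob$x),
                                 n_rounds = 10, seed = 5)),
               as.numeric(q2_lmo(prob$x, prob$y, rownames(prob$x),
                                 n_rounds = 10, seed = 5)))
})

test_that("external predictivity centres on the training mean", {
  prob <- random_problem(20, 2, seed = 51)
  train <- rownames(prob$x)[1:14]
  test <- rownames(prob$x)[15:20]
  fit <- fit_mlr(prob$x, prob$y, train)
  exact <- mlr_model(setNames(prob$beta, colnames(prob$x)), 1,
                     training_ids = train)
  noiseless <- setNames(drop(prob$x %*% prob$beta) + 1, rownames(prob$x))
  expect_equal(pred_r2(exact, prob$x, noiseless, test), 1,
               tolerance = 1e-10)
  # predicting the training mean scores exactly zero
  mean_model <- mlr_model(setNames(0, colnames(prob$x)[1]),
                          mean(prob$y[train]), training_ids = train)
  expect_equal(pred_r2(mean_model, prob$x, prob$y, test), 0,
               tolerance = 1e-12)
  expect_error(pred_r2(fit, prob$x, prob$y, character(0)), "empty")
  expect_error(pred_r2(fit, prob$x, prob$y, train[1:2]), "overlap")
})

test_that("predictivity ignores descriptors with zero coefficient", {
  prob <- random_problem(20, 3, seed = 61)
  train <- rownames(prob$x)[1:15]
  test <- rownames(prob$x)[16:20]
  fit <- fit_mlr(prob$x, prob$y, train, c("d01", "d02"))
  base <- pred_r2(fit, prob$x, prob$y, test)
  padded <- mlr_model(c(fit$coefficients, d03 = 0), fit$intercept,
                      training_ids = train)
  expect_equal(pred_r2(padded, prob$x, prob$y, test), base,
               tolerance = 1e-12)
})

test_that("validation reports assemble every statistic and round-trip", {
  y <- log_activities(load_cr_table("table1_cip"))
  x <- load_descriptor_table("table2")
  sp <- split_train_test(y, 0.2, seed = 2)
  model <- paper_model("cip")
  rep <- build_report(model, x, y, sp$train_ids, sp$test_ids,
                      lmo_seed = 7)
  expect_s3_class(rep, "fq_validation")
  expect_equal(rep$n_train, 19L)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 9L)
  expect_false(anyNA(df$value))
  expect_equal(sum(abs(rep$contributions)), 100, tolerance = 1e-9)
  f <- tempfile(fileext = ".csv")
  write_validation_csv(rep, f)
  back <- read.csv(f)
  expect_equal(back$value, df$value, tolerance = 1e-12)
})

test_that("the pipeline recovers generating coefficients as noise
           vanishes", {
  errs <- vapply(c(0, 0.05, 0.2), function(sg) {
    ds <- generate_regression_dataset(
      synth_spec(n_compounds = 40, n_descriptors = 10,
                 true_support = c(2, 7), true_coefficients = c(3, -2),
                 noise_sigma = sg, seed = 77))
    fit <- fit_mlr(ds$descriptors, ds$activities,
                   descriptors = names(ds$truth$coefficients))
    max(abs(fit$coefficients - ds$truth$coefficients))
  }, numeric(1))
  expect_lt(errs[1], 1e-10)
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[3], 0.2)
})
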