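test_that("constrained splits keep the activity extremes in training", {
  y <- log_activities(load_cr_table("table1_cli"))
  for (seed in 1:10) {
    sp <- split_train_test(y, 0.2, seed = seed)
    expect_length(sp$test_ids, 5L)
    expect_lte(max(y[sp$test_ids]), max(y[sp$train_ids]))
    expect_gte(min(y[sp$test_ids]), min(y[sp$train_ids]))
    expect_true(names(y)[which.max(y)] %in% sp$train_ids)
  }
  sp1 <- split_train_test(y, 0.2, seed = 42)
  sp2 <- split_train_test(y, 0.2, seed = 42)
  expect_identical(sp1, sp2)
})

test_that("an exhausted rejection budget is an error", {
  y <- setNames(c(0, 1, 2, 3, 10), letters[1:5])
  errored <- FALSE
  for (seed in 1:25) {
    res <- tryCatch(split_train_test(y, 0.2, seed = seed,
                                     max_rejections = 0L),
                    error = function(e) {
                      expect_match(conditionMessage(e), "rejections")
                      TRUE
                    })
    if (isTRUE(res)) errored <- TRUE
  }
  expect_true(errored)
})

test_that("OLS recovers a noiseless linear model exactly", {
  withr::with_seed(5, {
    x <- matrix(rnorm(40), 20, 2,
                dimnames = list(sprintf("c%02d", 1:20), c("x1", "x2")))
    y <- setNames(2 * x[, 1] - 3 * x[, 2] + 1, rownames(x))
    fit <- fit_mlr(x, y)
    expect_equal(unname(fit$coefficients), c(2, -3), tolerance = 1e-10)
    expect_equal(fit$intercept, 1, tolerance = 1e-10)
    expect_equal(fit$r2_train, 1, tolerance = 1e-12)
  })
})

test_that("a descriptor equal to the activity gives R2 = 1", {
  withr::with_seed(6, {
    y <- setNames(rnorm(10), letters[1:10])
    x <- matrix(y, ncol = 1, dimnames = list(names(y), "self"))
    expect_equal(fit_mlr(x, y)$r2_train, 1, tolerance = 1e-12)
  })
})

test_that("rank-deficient fits fail naming the dependent columns", {
  withr::with_seed(7, {
    x <- matrix(rnorm(30), 15, 2,
                dimnames = list(sprintf("c%02d", 1:15), c("a", "b")))
    x <- cbind(x, dup = x[, "a"])
    y <- setNames(rnorm(15), rownames(x))
    expect_error(fit_mlr(x, y), "dup")
  })
})

test_that("fitted residuals satisfy the normal equations", {
  prob <- random_problem(25, 4, seed = 8)
  fit <- fit_mlr(prob$x, prob$y)
  res <- fit$residuals
  expect_lt(abs(sum(res)), 1e-8)
  for (j in seq_len(ncol(prob$x))) {
    expect_lt(abs(sum(res * prob$x[names(res), j])), 1e-8)
  }
})

test_that("published equations predict published worked examples", {
  t2 <- load_descriptor_table("table2")
  p1 <- predict(paper_model("cip"), t2)
  expect_equal(unname(p1["NAL"]), 4.338 - 0.075 * 32.42,
               tolerance = 1e-12)
  p2 <- predict(paper_model("cli"), t2)
  expect_equal(unname(p2["DIF"]), -0.225, tolerance = 1e-12)

  zero <- mlr_model(c("N(>CH-)" = 0), 1.5)
  expect_true(all(predict(zero, t2) == 1.5))
  expect_error(predict(paper_model("cip"),
                       t2[, "N(Stereo)", drop = FALSE]),
               "Shadow-YZ")
})

test_that("model JSON serialization round-trips", {
  m <- paper_model("cli")
  f <- tempfile(fileext = ".json")
  write_model_json(m, f, extra = list(seed = 3))
  back <- read_model_json(f)
  expect_equal(coef(back), coef(m))
  expect_equal(back$descriptor_names, m$descriptor_names)
})

test_that("the lack-of-fit score matches direct evaluation", {
  expect_equal(lof(0, 2, 2, 19), 0)
  expect_equal(lof(1, 0, 0, 19), 1)
  expect_equal(lof(1, 2, 2, 19, 0.5), 1 / (1 - 3 / 19)^2,
               tolerance = 1e-12)
  expect_error(lof(1, 10, 10, 12), "too large")
  # strictly increasing in SSE and in the term count
  expect_gt(lof(2, 2, 2, 19), lof(1, 2, 2, 19))
  expect_gt(lof(1, 3, 3, 19), lof(1, 2, 2, 19))
})

test_that("GFA finds the exhaustive best subset on small problems", {
  for (seed in c(2, 9)) {
    ds <- generate_regression_dataset(
      synth_spec(n_compounds = 20, n_descriptors = 10,
                 true_support = c(2, 7), seed = seed))
    g <- gfa_search(ds$descriptors, ds$activities,
                    cfg = gfa_config(generations = 60, seed = seed))
    oracle <- exhaustive_best_subset(ds$descriptors, ds$activities)
    expect_setequal(g$models[[1]]$descriptor_names, oracle$descriptors)
    expect_equal(g$lof[1], oracle$lof, tolerance = 1e-10)
  }
})

test_that("GFA with one term equals the best single descriptor", {
  y <- log_activities(load_cr_table("table1_cip"))
  x <- load_descriptor_table("table2")[names(y), ]
  g <- gfa_search(x, y, cfg = gfa_config(max_terms = 1, generations = 30,
                                         seed = 1))
  oracle <- exhaustive_best_subset(x, y, max_terms = 1)
  expect_equal(g$models[[1]]$descriptor_names, oracle$descriptors)
})

test_that("GFA is deterministic given a seed and keeps its elite", {
  ds <- generate_regression_dataset(synth_spec(n_descriptors = 8,
                                               seed = 3))
  g1 <- gfa_search(ds$descriptors, ds$activities,
                   cfg = gfa_config(generations = 25, seed = 12))
  g2 <- gfa_search(ds$descriptors, ds$activities,
                   cfg = gfa_config(generations = 25, seed = 12))
  expect_identical(lapply(g1$models, `[[`, "descriptor_names"),
                   lapply(g2$models, `[[`, "descriptor_names"))
  # best fitness never worsens across generations
  expect_true(all(diff(g1$best_history) <= 1e-12))
})

test_that("relative contributions are symmetric, signed and normalized", {
  withr::with_seed(13, {
    x <- matrix(rnorm(400), 200, 2,
                dimnames = list(sprintf("c%03d", 1:200), c("a", "b")))
    y <- setNames(x[, 1] + x[, 2] + rnorm(200, 0, 0.01), rownames(x))
    fit <- fit_mlr(x, y)
    contrib <- relative_contribution(fit, x, y)
    expect_equal(unname(contrib), c(50, 50), tolerance = 2)
  })
  prob <- random_problem(30, 3, seed = 14)
  fit <- fit_mlr(prob$x, prob$y)
  contrib <- relative_contribution(fit, prob$x, prob$y)
  expect_equal(sum(abs(contrib)), 100, tolerance = 1e-9)
  expect_equal(sign(contrib), sign(fit$coefficients),
               ignore_attr = TRUE)
})

test_that("the general contribution formula reduces to the published
           three-descriptor form", {
  for (seed in 1:5) {
    prob <- random_problem(40, 3, seed = 100 + seed, sigma = 1)
    x <- prob$x; y <- prob$y
    fit <- fit_mlr(x, y)
    contrib <- relative_contribution(fit, x, y)
    r2_of <- function(cols) fit_mlr(x, y, descriptors = cols)$r2_train
    full <- r2_of(colnames(x))
    pairs <- list(c(2, 3), c(1, 3), c(1, 2))
    denom <- 3 * full - sum(vapply(pairs, function(p)
      r2_of(colnames(x)[p]), numeric(1)))
    for (i in 1:3) {
      alpha_published <- (full - r2_of(colnames(x)[pairs[[i]]])) / denom * 100
      expect_equal(abs(contrib[[i]]), abs(alpha_published),
                   tolerance = 1e-9)
    }
  }
})
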