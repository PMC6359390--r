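# Independent oracles used across tests.

# Exhaustive best-subset search by LOF: enumerates every descriptor
# subset of size 1..max_terms and scores its OLS fit with the same
# lack-of-fit convention as the GA (c = p = subset size).
exhaustive_best_subset <- function(x, y, train_ids = rownames(x),
                                   max_terms = 4L, d_smooth = 0.5) {
  p <- ncol(x)
  best <- NULL
  best_lof <- Inf
  for (k in seq_len(min(max_terms, p))) {
    for (subset in combn(p, k, simplify = FALSE)) {
      desc <- colnames(x)[subset]
      fit <- tryCatch(fit_mlr(x, y, train_ids, desc),
                      error = function(e) NULL)
      if (is.null(fit)) next
      score <- tryCatch(
        lof(sum(fit$residuals^2), k, k, length(train_ids), d_smooth),
        error = function(e) Inf)
      if (score < best_lof) {
        best_lof <- score
        best <- desc
      }
    }
  }
  list(descriptors = best, lof = best_lof)
}

# Random OLS test problem: n x p standard normal descriptors, known
# coefficients, optional noise.
random_problem <- function(n, p, seed, sigma = 0.3) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("c%02d", 1:n),
                                sprintf("d%02d", 1:p)))
    beta <- rnorm(p)
    y <- setNames(drop(x %*% beta) + 1 + rnorm(n, 0, sigma), rownames(x))
    list(x = x, y = y, beta = beta)
  })
}

quinolones <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_compounds("quinolones26")
    cache
  }
})
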