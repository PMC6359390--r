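# Genetic function approximation: a genetic algorithm over descriptor
# subsets, scored by the Friedman lack-of-fit of their OLS fits.

#' Configuration for the genetic function approximation search
#'
#' Defaults follow common GFA practice: a population of 100 subset
#' individuals evolved for 200 generations with heavy uniform crossover
#' and light add/remove/swap mutation, at most 4 descriptors per model,
#' and lack-of-fit smoothing `d = 0.5`.
#'
#' @param population_size number of individuals.
#' @param generations number of generations.
#' @param crossover_rate probability a child is produced by uniform
#'   crossover rather than cloning.
#' @param mutation_rate probability a child is mutated.
#' @param max_terms maximum number of descriptors per model.
#' @param d_smooth lack-of-fit smoothing parameter.
#' @param count_intercept if `TRUE`, count the regression constant in
#'   the lack-of-fit `c` term as well.
#' @param seed integer seed for the search.
#' @return an object of class `fq_gfa_config`.
#' @export
gfa_config <- function(population_size = 100L, generations = 200L,
                       crossover_rate = 0.9, mutation_rate = 0.1,
                       max_terms = 4L, d_smooth = 0.5,
                       count_intercept = FALSE, seed = NULL) {
  stopifnot(population_size >= 4L, generations >= 1L, max_terms >= 1L,
            crossover_rate > 0, mutation_rate > 0, d_smooth > 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 max_terms = as.integer(max_terms),
                 d_smooth = d_smooth,
                 count_intercept = isTRUE(count_intercept),
                 seed = seed),
            class = "fq_gfa_config")
}

# LOF of the OLS fit of a descriptor subset on the training ids;
# +Inf when the fit is not estimable.
.subset_lof <- function(mask, x, y, train_ids, cfg) {
  desc <- colnames(x)[mask]
  k <- length(desc)
  if (k == 0L || length(train_ids) <= k + 1L) return(Inf)
  fit <- tryCatch(fit_mlr(x, y, train_ids, desc), error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  sse <- sum(fit$residuals^2)
  c_terms <- k + if (cfg$count_intercept) 1L else 0L
  tryCatch(lof(sse, c_terms, k, length(train_ids), cfg$d_smooth),
           error = function(e) Inf)
}

.random_mask <- function(p, max_terms) {
  k <- sample.int(min(max_terms, p), 1L)
  mask <- logical(p)
  mask[sample.int(p, k)] <- TRUE
  mask
}

# Repair a mask to 1..max_terms set bits.
.repair_mask <- function(mask, max_terms) {
  on <- which(mask)
  if (length(on) > max_terms) {
    mask[sample(on, length(on) - max_terms)] <- FALSE
  } else if (!length(on)) {
    mask[sample.int(length(mask), 1L)] <- TRUE
  }
  mask
}

.mutate_mask <- function(mask, max_terms) {
  p <- length(mask)
  on <- which(mask); off <- which(!mask)
  op <- sample(c("add", "remove", "swap"), 1L)
  if (op == "add" && length(off) && length(on) < max_terms) {
    mask[sample(off, 1L)] <- TRUE
  } else if (op == "remove" && length(on) > 1L) {
    mask[sample(on, 1L)] <- FALSE
  } else if (length(on) && length(off)) {
    mask[sample(on, 1L)] <- FALSE
    mask[sample(off, 1L)] <- TRUE
  }
  mask
}

#' Genetic function approximation over descriptor subsets
#'
#' Evolves a population of descriptor subsets (individuals are bitmasks
#' with at most `max_terms` bits set).  Fitness is the negative
#' Friedman lack-of-fit of the subset's OLS fit on the training set.
#' Parents are chosen by binary tournament; children are produced by
#' uniform crossover and add/remove/swap mutation; the best individual
#' survives unchanged (elitism of one).  If the population collapses to
#' copies of a single subset it is re-seeded with fresh random
#' individuals (keeping the elite).  The search is deterministic given
#' `cfg$seed`.
#'
#' @param x descriptor matrix (normally after
#'   [preprocess_descriptors()]).
#' @param y named activity vector.
#' @param train_ids training compound ids (default: all rows).
#' @param cfg a [gfa_config()].
#' @return an object of class `fq_gfa`: a list with `models` (the final
#'   population, deduplicated, refit and sorted by ascending LOF),
#'   `lof` (their scores), `best_history` (best LOF per generation) and
#'   `config`.
#' @export
gfa_search <- function(x, y, train_ids = rownames(x), cfg = gfa_config()) {
  .check_xy(x, y, train_ids)
  p <- ncol(x)
  stopifnot(p >= 1L)
  .with_seed(cfg$seed, {
    pop <- replicate(cfg$population_size, .random_mask(p, cfg$max_terms))
    pop <- matrix(pop, nrow = p)
    scores <- apply(pop, 2, .subset_lof, x, y, train_ids, cfg)
    best_history <- numeric(cfg$generations)
    for (g in seq_len(cfg$generations)) {
      elite <- which.min(scores)
      newpop <- matrix(FALSE, p, cfg$population_size)
      newpop[, 1] <- pop[, elite]
      for (k in 2:cfg$population_size) {
        pick <- function() {
          cand <- sample.int(cfg$population_size, 2L)
          cand[which.min(scores[cand])]
        }
        a <- pop[, pick()]
        if (runif(1) < cfg$crossover_rate) {
          b <- pop[, pick()]
          take <- runif(p) < 0.5
          child <- ifelse(take, a, b)
        } else child <- a
        if (runif(1) < cfg$mutation_rate) {
          child <- .mutate_mask(child, cfg$max_terms)
        }
        newpop[, k] <- .repair_mask(child, cfg$max_terms)
      }
      pop <- newpop
      scores <- apply(pop, 2, .subset_lof, x, y, train_ids, cfg)
      best_history[g] <- min(scores)
      if (length(unique(apply(pop, 2, paste, collapse = ""))) == 1L &&
          g < cfg$generations) {
        message("GFA population degenerate at generation ", g,
                "; re-seeding")
        keep <- pop[, which.min(scores), drop = FALSE]
        pop <- cbind(keep, matrix(
          replicate(cfg$population_size - 1L, .random_mask(p, cfg$max_terms)),
          nrow = p))
        scores <- apply(pop, 2, .subset_lof, x, y, train_ids, cfg)
      }
    }
    keys <- apply(pop, 2, paste, collapse = "")
    uniq <- !duplicated(keys) & is.finite(scores)
    ord <- order(scores[uniq])
    masks <- pop[, uniq, drop = FALSE][, ord, drop = FALSE]
    models <- lapply(seq_len(ncol(masks)), function(k) {
      fit_mlr(x, y, train_ids, colnames(x)[masks[, k]])
    })
    structure(list(models = models, lof = sort(scores[uniq]),
                   best_history = best_history, config = cfg,
                   train_ids = train_ids),
              class = "fq_gfa")
  })
}

#' @export
print.fq_gfa <- function(x, n = 5, ...) {
  cat("Genetic function approximation:", length(x$models),
      "distinct models,", length(x$train_ids), "training compounds\n")
  show <- head(seq_along(x$models), n)
  for (k in show) {
    cat(sprintf("  [%d] LOF %.4g: %s\n", k, x$lof[k],
                paste(x$models[[k]]$descriptor_names, collapse = " + ")))
  }
  invisible(x)
}

#' Relative contribution of each descriptor to a model
#'
#' Quantifies descriptor importance by determination-coefficient loss:
#' `alpha_i = (R2_full - R2_without_i) / sum_j (R2_full - R2_without_j)
#' * 100`, every sub-model refit by OLS on the training set.  For a
#' three-descriptor model this reduces algebraically to
#' `alpha(x1) = (R2(x1,x2,x3) - R2(x2,x3)) /
#' (3 R2(x1,x2,x3) - R2(x1,x2) - R2(x1,x3) - R2(x2,x3)) * 100`.
#' Each contribution carries the sign of its regression coefficient,
#' so the magnitudes sum to 100.
#'
#' @param model an `fq_mlr` with at least two descriptors.
#' @param x descriptor matrix.
#' @param y named activity vector.
#' @param train_ids training compound ids (defaults to the model's).
#' @return named numeric vector of signed percent contributions.
#' @export
relative_contribution <- function(model, x, y,
                                  train_ids = model$training_ids) {
  desc <- model$descriptor_names
  if (length(desc) < 2L) stop("model must have at least two descriptors",
                              call. = FALSE)
  if (!length(train_ids)) train_ids <- rownames(x)
  full <- fit_mlr(x, y, train_ids, desc)$r2_train
  drops <- vapply(desc, function(d) {
    full - fit_mlr(x, y, train_ids, setdiff(desc, d))$r2_train
  }, numeric(1))
  denom <- sum(drops)
  if (abs(denom) < .Machine$double.eps^0.5) {
    stop("descriptors jointly uninformative", call. = FALSE)
  }
  alpha <- drops / denom * 100
  alpha * sign(model$coefficients[desc]) * sign(alpha)
}
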