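# High-level pipeline entry points: re-evaluate the published models on
# the bundled tables, and run the full selection pipeline on any data.

#' Re-evaluate a published cross-reactivity model on the bundled tables
#'
#' Evaluates the published regression equation of the chosen assay system
#' (see [paper_model()]) on the bundled descriptor table against the
#' bundled measured log activities, reporting the overall determination
#' coefficient, the specificity count, and the per-compound
#' predicted-versus-actual pairs.  With `refit = TRUE` the model's
#' descriptor subset is also refit over `n_splits` constrained random
#' train/test splits, giving the seed-wise distribution of the
#' split-dependent statistics (training r2, leave-one-out q2, external
#' predictivity), since the original split membership is not published.
#'
#' @param system `"cip"` (anti-ciprofloxacin antibody, FPIA) or
#'   `"cli"` (anti-clinafloxacin antibody, ELISA).
#' @param impute_cr CR percent imputed for censored "<LOD" entries
#'   (default 0.5, the midpoint of the censoring interval).
#' @param refit also run the split/refit distribution study.
#' @param n_splits number of seeded splits when `refit = TRUE`.
#' @param seed base seed; split `k` uses `seed + k - 1`.
#' @param out_dir optional directory to write CSV reports to.
#' @return an object of class `fq_reproduction`.
#' @export
reproduce_model <- function(system = c("cip", "cli"), impute_cr = 0.5,
                            refit = FALSE, n_splits = 50L, seed = 1L,
                            out_dir = NULL) {
  system <- match.arg(system)
  table <- load_cr_table(paste0("table1_", system))
  y <- log_activities(table, "impute", impute_cr)
  x <- load_descriptor_table("table2")
  model <- paper_model(system)
  ids <- names(y)
  pred <- predict(model, x[ids, , drop = FALSE])
  pairs <- data.frame(compound_id = ids, actual = unname(y),
                      predicted = unname(pred),
                      imputed = unname(attr(y, "imputed")))
  out <- list(system = system,
              system_id = attr(table, "system_id"),
              impute_cr = impute_cr,
              model = model,
              n_compounds = length(ids),
              n_censored = sum(attr(y, "imputed")),
              r2_overall = r2(y, pred),
              n_specific = count_specific(table),
              n_tested = sum(table$status != "not_tested"),
              pairs = pairs)
  if (refit) {
    stats <- t(vapply(seq_len(n_splits), function(k) {
      sp <- split_train_test(y, 0.2, seed = seed + k - 1L)
      fit <- fit_mlr(x, y, sp$train_ids, model$descriptor_names)
      c(r2_tr = fit$r2_train,
        q2 = q2_loo(x, y, sp$train_ids, model$descriptor_names),
        pred_r2 = pred_r2(fit, x, y, sp$test_ids))
    }, numeric(3)))
    out$refit_stats <- as.data.frame(stats)
    out$refit_seed <- seed
  }
  out <- structure(out, class = "fq_reproduction")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(pairs, file.path(out_dir,
                               paste0(system, "_pred_vs_actual.csv")),
              row.names = FALSE, quote = FALSE)
    if (refit) {
      write.csv(out$refit_stats,
                file.path(out_dir, paste0(system, "_refit_stats.csv")),
                row.names = FALSE, quote = FALSE)
    }
  }
  out
}

#' @export
print.fq_reproduction <- function(x, ...) {
  cat("Published-model re-evaluation:", x$system_id, "\n")
  cat("  censor policy: '<LOD' imputed at CR =", x$impute_cr,
      sprintf("(%d censored of %d compounds)\n", x$n_censored,
              x$n_compounds))
  cat(sprintf("  overall R2 (published equation, %d compounds): %.3f\n",
              x$n_compounds, x$r2_overall))
  cat(sprintf("  specific to %d of %d tested compounds (CR > 1%%)\n",
              x$n_specific, x$n_tested))
  if (!is.null(x$refit_stats)) {
    cat("  refit distribution over", nrow(x$refit_stats),
        "constrained splits (seed", x$refit_seed, "):\n")
    print(t(apply(x$refit_stats, 2, quantile,
                  probs = c(0, 0.25, 0.5, 0.75, 1))), digits = 3)
  }
  invisible(x)
}

#' Run the full QSAR selection pipeline
#'
#' End-to-end modelling on user data: censor-policy handling, descriptor
#' preprocessing, constrained train/test split, genetic function
#' approximation, and validation of the best model.  All stochastic
#' stages derive from the supplied seed, so a rerun with the same
#' inputs is identical.
#'
#' @param x descriptor matrix.
#' @param table an `fq_crtable`, or a named numeric activity vector.
#' @param impute_cr censoring imputation (see [log_activities()]).
#' @param sparse_frac,r_cut preprocessing filters (see
#'   [preprocess_descriptors()]).
#' @param test_fraction test-set fraction for the split.
#' @param cfg a [gfa_config()]; its seed is overridden by `seed`.
#' @param seed master seed for split, search and validation.
#' @param out_dir optional directory for CSV artifacts.
#' @return a list with `split`, `preprocessing`, `search` (the
#'   `fq_gfa`), `model` (best model) and `report`
#'   (its `fq_validation`).
#' @export
run_qsar_pipeline <- function(x, table, impute_cr = 0.5,
                              sparse_frac = 0.1, r_cut = 0.5,
                              test_fraction = 0.2, cfg = gfa_config(),
                              seed = 1L, out_dir = NULL) {
  y <- if (inherits(table, "fq_crtable")) {
    log_activities(table, "impute", impute_cr)
  } else table
  if (is.null(names(y))) stop("activities must be named", call. = FALSE)
  x <- x[intersect(rownames(x), names(y)), , drop = FALSE]
  prep <- preprocess_descriptors(x, y, sparse_frac, r_cut)
  sp <- split_train_test(y[rownames(prep$matrix)], test_fraction,
                         seed = seed)
  cfg$seed <- seed + 1L
  search <- gfa_search(prep$matrix, y, sp$train_ids, cfg)
  model <- search$models[[1]]
  report <- build_report(model, prep$matrix, y, sp$train_ids,
                         sp$test_ids, lmo_seed = seed + 2L,
                         d_smooth = cfg$d_smooth,
                         count_intercept = cfg$count_intercept)
  out <- list(split = sp, preprocessing = prep$report, search = search,
              model = model, report = report, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_validation_csv(report, file.path(out_dir, "validation.csv"))
    write_model_json(model, file.path(out_dir, "model.json"),
                     extra = list(seed = seed))
  }
  out
}

#' Serialize a linear model to JSON
#'
#' Writes descriptor names, coefficients, intercept and training ids as
#' a plain JSON record; [read_model_json()] restores the `fq_mlr`.
#'
#' @param model an `fq_mlr`.
#' @param path output path.
#' @param extra optional named list stored alongside (seeds, config).
#' @export
write_model_json <- function(model, path, extra = list()) {
  rec <- c(list(descriptor_names = model$descriptor_names,
                coefficients = unname(model$coefficients),
                intercept = model$intercept,
                training_ids = model$training_ids), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  mlr_model(setNames(rec$coefficients, rec$descriptor_names),
            rec$intercept,
            training_ids = as.character(rec$training_ids))
}
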