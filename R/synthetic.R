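# Synthetic data generators mirroring the statistical structure of the
# measured tables: a sparse linear signal on a descriptor matrix of
# small counts and continuous columns, Gaussian noise on log CR, and
# left-censoring of low cross-reactivities.

#' Specification for synthetic QSAR data
#'
#' Describes a data-generating process of the form
#' `log CR = intercept + sum_i a_i x_i + N(0, sigma^2)` over a
#' descriptor matrix with a correlated nuisance block.  Descriptors are
#' drawn from a Gaussian copula: half of the columns are thresholded
#' into small counts (0-3, emulating group-count descriptors), the
#' rest are continuous standard-normal columns (regression recovery is
#' invariant to column scale, so continuous descriptors are
#' generated scale-free).
#'
#' @param n_compounds number of synthetic compounds.
#' @param n_descriptors number of descriptor columns.
#' @param true_support column indices carrying the signal.
#' @param true_coefficients slopes for the support columns.
#' @param intercept regression constant of the truth.
#' @param noise_sigma Gaussian noise standard deviation, log-CR units.
#' @param descriptor_correlation pairwise latent correlation of the
#'   nuisance block, in `[0, 1)`.
#' @param censor_lod CR percent below which entries are reported as
#'   censored by [generate_censored_cr_table()].
#' @param seed integer seed.
#' @return an object of class `fq_synthspec`.
#' @export
synth_spec <- function(n_compounds = 20L, n_descriptors = 30L,
                       true_support = c(2L, 7L),
                       true_coefficients = c(3, -2), intercept = 0,
                       noise_sigma = 0.1, descriptor_correlation = 0.3,
                       censor_lod = 1, seed = 1L) {
  stopifnot(all(true_support >= 1L), all(true_support <= n_descriptors),
            length(true_support) == length(true_coefficients),
            noise_sigma >= 0,
            descriptor_correlation >= 0, descriptor_correlation < 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 true_support = as.integer(true_support),
                 true_coefficients = true_coefficients,
                 intercept = intercept, noise_sigma = noise_sigma,
                 descriptor_correlation = descriptor_correlation,
                 censor_lod = censor_lod, seed = seed),
            class = "fq_synthspec")
}

#' Generate a synthetic regression dataset
#'
#' Draws a descriptor matrix and activities from the process described
#' by a [synth_spec()].  Nuisance columns (those outside the true
#' support) share a latent equicorrelated Gaussian factor with
#' correlation `descriptor_correlation`; support columns are
#' independent.  Count-like columns (every odd column) are produced by
#' thresholding the latent Gaussian at fixed quantiles into `0:3`, so
#' correlation control and discreteness coexist.  Output is
#' deterministic given the spec (seed included).
#'
#' @param spec a [synth_spec()].
#' @return list with `descriptors` (a [descriptor_matrix()]),
#'   `activities` (named numeric log-CR vector) and `truth`
#'   (the generating model as an `fq_mlr`).
#' @export
generate_regression_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "fq_synthspec"))
  n <- spec$n_compounds; p <- spec$n_descriptors
  ids <- sprintf("S%02d", seq_len(n))
  dnames <- sprintf("D%02d", seq_len(p))
  .with_seed(spec$seed, {
    rho <- spec$descriptor_correlation
    shared <- rnorm(n)
    latent <- matrix(rnorm(n * p), n, p)
    nuis <- setdiff(seq_len(p), spec$true_support)
    if (rho > 0 && length(nuis)) {
      latent[, nuis] <- sqrt(rho) * shared +
        sqrt(1 - rho) * latent[, nuis]
    }
    vals <- latent
    count_like <- seq_len(p) %% 2L == 1L
    # thresholds chosen so counts 0..3 appear with decreasing frequency,
    # like methantriyl or stereocentre counts do
    br <- c(-Inf, qnorm(c(0.45, 0.75, 0.92)), Inf)
    vals[, count_like] <- as.numeric(cut(latent[, count_like], br,
                                         labels = FALSE)) - 1
    dimnames(vals) <- list(ids, dnames)
    beta <- setNames(spec$true_coefficients, dnames[spec$true_support])
    ymu <- spec$intercept +
      drop(vals[, spec$true_support, drop = FALSE] %*%
             spec$true_coefficients)
    yy <- ymu + rnorm(n, 0, spec$noise_sigma)
    list(descriptors = descriptor_matrix(vals, "computed"),
         activities = setNames(yy, ids),
         truth = mlr_model(beta, spec$intercept, training_ids = ids))
  })
}

#' Generate a left-censored cross-reactivity table
#'
#' Converts the activities of [generate_regression_dataset()] back to
#' the CR percent scale (`CR = 10^y`) and applies the censoring rule:
#' values below `censor_lod` are reported as below the limit of
#' detection, as "<1" cells are in real assay tables.
#'
#' @param spec a [synth_spec()].
#' @return list with `table` (an `fq_crtable`) plus the `descriptors`
#'   and `activities` of the underlying dataset.
#' @export
generate_censored_cr_table <- function(spec = synth_spec()) {
  ds <- generate_regression_dataset(spec)
  cr <- 10^ds$activities
  censored <- spec$censor_lod > 0 & cr < spec$censor_lod
  tab <- data.frame(
    compound_id = names(ds$activities),
    status = ifelse(censored, "below_lod", "measured"),
    cr_percent = ifelse(censored, NA_real_, cr),
    lod_percent = ifelse(censored, spec$censor_lod, NA_real_),
    stringsAsFactors = FALSE)
  table <- structure(tab, system_id = sprintf("synthetic (seed %s)",
                                              spec$seed),
                     class = c("fq_crtable", "data.frame"))
  c(list(table = table), ds)
}

#' Generate a random cloud of spheres as a pseudo-molecule
#'
#' Produces an [fq_compound]-like record carrying only 3D coordinates
#' (no structure), for exercising [shadow_area()] against analytic
#' expectations: one atom gives an exact disk, zero spread collapses
#' the union to one disk, and wide spread makes disk areas additive.
#'
#' @param n_atoms number of spheres.
#' @param element element symbol determining the van-der-Waals radius.
#' @param spread standard deviation of the Gaussian centres, Angstrom.
#' @param seed integer seed.
#' @return an object of class `fq_compound` with `coords3d` set and no
#'   SMILES.
#' @export
generate_sphere_cloud <- function(n_atoms = 1L, element = "C", spread = 3,
                                  seed = 1L) {
  stopifnot(n_atoms >= 1L, spread >= 0)
  .with_seed(seed, {
    xyz <- matrix(rnorm(3 * n_atoms, 0, spread), ncol = 3)
    structure(list(id = sprintf("cloud%d", n_atoms),
                   name = "synthetic sphere cloud", smiles = NA_character_,
                   coords3d = data.frame(element = element,
                                         x = xyz[, 1], y = xyz[, 2],
                                         z = xyz[, 3]),
                   hydrogens = TRUE, radii_source = "bondi"),
              class = "fq_compound")
  })
}
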