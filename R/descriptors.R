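# Graph-based molecular descriptors: methantriyl counts, tetrahedral
# stereocentre counts, and Kier-Hall electro-topological state sums.

.as_mol <- function(x) {
  if (inherits(x, "fq_compound")) mol_graph(x$smiles, id = x$id)
  else if (is.character(x) && length(x) == 1L) mol_graph(x)
  else stop("expected an fq_compound or a SMILES string", call. = FALSE)
}

# Predicate for methantriyl (>CH-) carbons: exactly one hydrogen and
# three single bonds to heavy atoms, no multiple bond at the carbon.
.is_methantriyl <- function(mol) {
  mol$elements == "C" & mol$n_h == 1L & .mol_degree(mol) == 3L &
    !.has_multiple_bond(mol)
}

#' Count methantriyl (>CH-) groups
#'
#' A methantriyl group is a carbon bearing exactly one hydrogen and
#' three single bonds to heavy atoms.  Aromatic and otherwise
#' multiply-bonded carbons are excluded.
#'
#' @param mol an [fq_compound] or SMILES string.
#' @return integer count, the `N(>CH-)` descriptor.
#' @examples
#' count_methantriyl("CC(C)C") # isobutane: 1
#' @export
count_methantriyl <- function(mol) {
  sum(.is_methantriyl(.as_mol(mol)))
}

#' Count tetrahedral stereo atoms
#'
#' Counts carbons that are actual or potential tetrahedral
#' stereocentres: sp3 carbons with four substituents (implicit
#' hydrogens included) whose four branches are pairwise distinguishable.
#' Both assigned and unassigned centres count, so racemates score the
#' same as single enantiomers.  Branch equivalence is decided by
#' Morgan-style symmetry classes of the molecular graph.
#'
#' @param mol an [fq_compound] or SMILES string.
#' @return integer count, the `N(Stereo)` descriptor.
#' @examples
#' count_stereo_atoms("C[C@@H](O)CC") # butan-2-ol: 1
#' @export
count_stereo_atoms <- function(mol) {
  m <- .as_mol(mol)
  n <- length(m$elements)
  deg <- .mol_degree(m)
  cand <- which(m$elements == "C" & m$n_h <= 1L & !.has_multiple_bond(m) &
                  (deg + m$n_h) == 4L)
  if (!length(cand)) return(0L)
  cls <- .symmetry_classes(m)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  sum(vapply(cand, function(i) {
    nb <- cls[adj[[i]]]
    anyDuplicated(nb) == 0L  # implicit H (if any) is a unique 4th branch
  }, logical(1)))
}

#' Kier-Hall electro-topological state indices
#'
#' Computes, over the heavy-atom graph, the intrinsic state
#' `I_i = ((2/L_i)^2 * deltav_i + 1) / delta_i` (with `L` the principal
#' quantum number, `deltav = Zv - h` the valence connectivity and
#' `delta` the simple heavy-atom connectivity) and the E-state
#' `S_i = I_i + sum_j (I_i - I_j) / (d_ij + 1)^2`, where `d_ij` is the
#' topological (bond-count) distance.  For a single-atom molecule there
#' are no perturbation terms and `S = I` (flagged `degenerate`).
#'
#' @param mol an [fq_compound] or SMILES string.
#' @return a list with `intrinsic` (`I_i`), `estate` (`S_i`),
#'   `methantriyl` (logical selector for >CH- carbons),
#'   `selected_sum` (sum of `S_i` over >CH- carbons) and `degenerate`.
#' @export
estate_indices <- function(mol) {
  m <- .as_mol(mol)
  n <- length(m$elements)
  if (n > 1L && igraph::count_components(m$graph) > 1L) {
    stop("disconnected molecular graph", call. = FALSE)
  }
  info <- .element_row(m$elements)
  delta <- .mol_degree(m)
  deltav <- info$Zv - m$n_h
  I <- ((2 / info$L)^2 * deltav + 1) / pmax(delta, 1L)
  if (n == 1L) {
    S <- I
    degenerate <- TRUE
  } else {
    d <- igraph::distances(m$graph)
    # Pairwise field effect: antisymmetric, so perturbations sum to zero
    # over the whole molecule.
    dI <- outer(I, I, "-")
    pert <- dI / (d + 1)^2
    diag(pert) <- 0
    S <- I + rowSums(pert)
    degenerate <- FALSE
  }
  sel <- .is_methantriyl(m)
  list(intrinsic = I, estate = S, methantriyl = sel,
       selected_sum = sum(S[sel]), degenerate = degenerate)
}

#' Sum of E-state indices over methantriyl carbons
#'
#' The `S(>CH-)` descriptor: sum of per-atom E-state values over the
#' carbons selected by [count_methantriyl()]'s predicate; 0 when the
#' molecule has no such carbon.
#'
#' @inheritParams count_methantriyl
#' @return numeric descriptor value.
#' @export
sum_estate_methantriyl <- function(mol) {
  estate_indices(mol)$selected_sum
}

#' Descriptor registry and computation
#'
#' `descriptor_registry()` returns the name-to-function map of natively
#' computed descriptors; `compute_descriptors()` evaluates a selection
#' of them over a compound collection, yielding a descriptor matrix
#' with provenance `"computed"` that can be column-bound with supplied
#' tables.  `Shadow-YZ` requires 3D coordinates on each record (see
#' [align_canonical()]) and is therefore not in the default selection.
#'
#' @param compounds a list of [fq_compound] records.
#' @param descriptors names of registry descriptors to compute.
#' @return `compute_descriptors()`: a [descriptor_matrix()].
#' @export
compute_descriptors <- function(compounds,
                                descriptors = c("N(>CH-)", "S(>CH-)",
                                                "N(Stereo)")) {
  reg <- descriptor_registry()
  unknown <- setdiff(descriptors, names(reg))
  if (length(unknown)) stop("unknown descriptor(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  ids <- vapply(compounds, `[[`, character(1), "id")
  vals <- vapply(descriptors, function(d) {
    vapply(compounds, function(cc) as.numeric(reg[[d]](cc)), numeric(1))
  }, numeric(length(compounds)))
  vals <- matrix(vals, nrow = length(compounds),
                 dimnames = list(ids, descriptors))
  descriptor_matrix(vals, "computed")
}

#' @rdname compute_descriptors
#' @export
descriptor_registry <- function() {
  list(
    "N(>CH-)"   = count_methantriyl,
    "S(>CH-)"   = sum_estate_methantriyl,
    "N(Stereo)" = count_stereo_atoms,
    "Shadow-YZ" = function(cc) shadow_area(align_canonical(cc),
                                           shadow_spec("YZ"))
  )
}

#' Filter a descriptor matrix before model building
#'
#' Standard QSAR preprocessing: drop constant columns, drop columns
#' with too few nonzero entries, then scan all remaining pairs with
#' `|Pearson r| > r_cut` and drop, from each such pair, the member less
#' correlated (in absolute value) with the activity; on a tie the
#' earlier column is kept.
#'
#' @param m a descriptor matrix.
#' @param y named activity vector covering the matrix rows.
#' @param sparse_frac minimum fraction of nonzero entries a column must
#'   have (default 0.1).
#' @param r_cut correlation threshold above which one of a pair is
#'   dropped (default 0.5).
#' @return a list with `matrix` (the filtered descriptor matrix) and
#'   `report`, a list with elements `dropped_constant`,
#'   `dropped_sparse`, and `dropped_correlated` (data.frame with
#'   columns `kept`, `dropped`, `r`).
#' @export
preprocess_descriptors <- function(m, y, sparse_frac = 0.1, r_cut = 0.5) {
  stopifnot(all(rownames(m) %in% names(y)))
  prov0 <- attr(m, "provenance")
  y <- y[rownames(m)]
  const <- apply(m, 2, function(v) length(unique(v)) == 1L)
  dropped_constant <- colnames(m)[const]
  m <- m[, !const, drop = FALSE]
  sparse <- colMeans(m != 0) < sparse_frac
  dropped_sparse <- colnames(m)[sparse]
  m <- m[, !sparse, drop = FALSE]
  dropped_correlated <- data.frame(kept = character(0),
                                   dropped = character(0), r = numeric(0))
  if (ncol(m) >= 2L) {
    active <- rep(TRUE, ncol(m))
    ry <- abs(apply(m, 2, function(v) suppressWarnings(cor(v, y))))
    ry[is.na(ry)] <- 0
    for (a in seq_len(ncol(m) - 1L)) {
      if (!active[a]) next
      for (b in seq((a + 1L), ncol(m))) {
        if (!active[a] || !active[b]) next
        r <- suppressWarnings(cor(m[, a], m[, b]))
        if (!is.na(r) && abs(r) > r_cut) {
          drop_idx <- if (ry[b] < ry[a] ||
                          (ry[b] == ry[a])) b else a
          keep_idx <- if (drop_idx == a) b else a
          active[drop_idx] <- FALSE
          dropped_correlated <- rbind(dropped_correlated, data.frame(
            kept = colnames(m)[keep_idx], dropped = colnames(m)[drop_idx],
            r = r))
        }
      }
    }
    m <- m[, active, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("all descriptor columns dropped", call. = FALSE)
  list(matrix = descriptor_matrix(m, if (is.null(prov0)) "supplied"
                                  else prov0[colnames(m)]),
       report = list(dropped_constant = dropped_constant,
                     dropped_sparse = dropped_sparse,
                     dropped_correlated = dropped_correlated))
}
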