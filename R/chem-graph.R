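# Heavy-atom molecular graphs derived from SMILES via ChemmineR/OpenBabel.
#
# All descriptor code in this package works on a plain list representation:
#   elements : character vector of element symbols, heavy atoms only
#   bonds    : data.frame(i, j, order) with kekulized integer bond orders
#   n_h      : implicit hydrogen count per heavy atom
#   graph    : igraph object (unweighted, undirected)
# Implicit hydrogens are filled in from standard neutral valences, which is
# sufficient for the uncharged drug-like molecules this package targets.

# Element data used for hydrogen filling and E-state intrinsic states:
# Z = atomic number, Zv = valence electrons, L = principal quantum number.
.element_table <- data.frame(
  symbol  = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  Z       = c(1, 6, 7, 8, 9, 15, 16, 17, 35, 53),
  Zv      = c(1, 4, 5, 6, 7, 5, 6, 7, 7, 7),
  L       = c(1, 2, 2, 2, 2, 3, 3, 3, 4, 5),
  valence = c(1, 4, 3, 2, 1, 3, 2, 1, 1, 1),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  idx <- match(symbol, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  .element_table[idx, , drop = FALSE]
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Internal backend for all graph-based descriptors.  The SMILES is
#' converted to a kekulized connection table through ChemmineR/OpenBabel
#' and implicit hydrogens are inferred from standard neutral valences.
#' Results are memoised per SMILES string.
#'
#' @param smiles a single SMILES string.
#' @param id identifier used in error messages.
#' @return a list with `elements`, `bonds`, `n_h` and `graph` (igraph).
#' @keywords internal
mol_graph <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("mol:", smiles)
  cached <- .fqsar_cache[[key]]
  if (!is.null(cached)) return(cached)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("cannot parse structure for '", id, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) == 1L && identical(rownames(ab), "0")) {
    # ChemmineR cannot represent single-atom SDFs; read the V2000
    # connection table directly in that case
    parsed <- .sdf_text_graph(smiles, id)
    ab <- parsed$ab
    bb <- parsed$bb
  } else {
    bb <- as.matrix(ChemmineR::bondblock(sdf[[1]]))
  }
  # molecules without bonds yield a stub bond block of zeros
  if (ncol(bb) < 3L || nrow(bb) == 0L || all(bb[, 1:2] == 0)) {
    bb <- matrix(integer(0), 0, 3)
  }
  n <- nrow(ab)
  if (n == 0L) stop("cannot parse structure for '", id, "': no atoms",
                    call. = FALSE)
  elements <- sub("_\\d+$", "", rownames(ab))
  keep <- elements != "H"
  if (!all(keep)) {
    # explicit hydrogens: merge into implicit counts
    hmap <- cumsum(keep)
    extra_h <- integer(sum(keep))
    bonds_all <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
    keep_bond <- keep[bonds_all$i] & keep[bonds_all$j]
    for (r in which(!keep_bond)) {
      heavy <- if (keep[bonds_all$i[r]]) bonds_all$i[r] else bonds_all$j[r]
      extra_h[hmap[heavy]] <- extra_h[hmap[heavy]] + 1L
    }
    bonds <- bonds_all[keep_bond, , drop = FALSE]
    bonds$i <- hmap[bonds$i]; bonds$j <- hmap[bonds$j]
    elements <- elements[keep]
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    extra_h <- integer(n)
  }
  n <- length(elements)
  info <- .element_row(elements)
  order_sum <- integer(n)
  if (nrow(bonds)) {
    tab <- tapply(c(bonds$order, bonds$order), c(bonds$i, bonds$j), sum)
    order_sum[as.integer(names(tab))] <- as.integer(tab)
  }
  # explicit hydrogens suppress the corresponding implicit ones
  n_h <- pmax(0L, info$valence - order_sum - extra_h) + extra_h

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  }
  mol <- list(elements = elements, bonds = bonds, n_h = as.integer(n_h),
              graph = g)
  assign(key, mol, envir = .fqsar_cache)
  mol
}

# Fallback V2000 reader for molecules ChemmineR cannot represent
# (single atoms).  Returns atom and bond blocks in ChemmineR layout.
.sdf_text_graph <- function(smiles, id) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("cannot parse structure for '", id, "'", call. = FALSE)
  }
  txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  na <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  if (is.na(na) || na < 1L) {
    stop("cannot parse structure for '", id, "'", call. = FALSE)
  }
  atom_lines <- lines[4 + seq_len(na)]
  el <- trimws(substr(atom_lines, 32, 34))
  ab <- matrix(0, na, 3, dimnames = list(paste(el, seq_len(na), sep = "_"),
                                         NULL))
  for (k in seq_len(na)) {
    ab[k, ] <- as.numeric(c(substr(atom_lines[k], 1, 10),
                            substr(atom_lines[k], 11, 20),
                            substr(atom_lines[k], 21, 30)))
  }
  bb <- matrix(integer(0), 0, 3)
  if (!is.na(nb) && nb > 0L) {
    bond_lines <- lines[4 + na + seq_len(nb)]
    bb <- cbind(as.integer(substr(bond_lines, 1, 3)),
                as.integer(substr(bond_lines, 4, 6)),
                as.integer(substr(bond_lines, 7, 9)))
  }
  list(ab = ab, bb = bb)
}

# Heavy-atom degree per atom.
.mol_degree <- function(mol) {
  igraph::degree(mol$graph)
}

# Per-atom indicator: any bond of order >= 2 at the atom.
.has_multiple_bond <- function(mol) {
  out <- logical(length(mol$elements))
  multi <- mol$bonds[mol$bonds$order >= 2L, , drop = FALSE]
  out[unique(c(multi$i, multi$j))] <- TRUE
  out
}

# Morgan-style symmetry classes by iterative invariant refinement.
# Atoms in the same graph-automorphism orbit always share a class; the
# converse holds for all but pathologically regular graphs.
.symmetry_classes <- function(mol) {
  n <- length(mol$elements)
  inv0 <- paste(mol$elements, .mol_degree(mol), mol$n_h, sep = ":")
  cls <- match(inv0, unique(inv0))
  if (n <= 1L) return(cls)
  adj <- lapply(seq_len(n), function(i) integer(0))
  ord <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]; o <- mol$bonds$order[r]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  repeat {
    key <- vapply(seq_len(n), function(i) {
      nb <- sort(paste(ord[[i]], cls[adj[[i]]], sep = "-"))
      paste(cls[i], paste(nb, collapse = ","), sep = "|")
    }, character(1))
    new_cls <- match(key, unique(key))
    if (length(unique(new_cls)) == length(unique(cls))) return(new_cls)
    cls <- new_cls
  }
}
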