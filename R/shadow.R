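# Molecular shadow areas: canonical alignment of the quinolone core and
# rasterized projection of van-der-Waals spheres onto a coordinate plane.

# Bondi van-der-Waals radii (Angstrom).
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Bondi van-der-Waals radii
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
bondi_radii <- function() .bondi_radii

#' Specification of a shadow projection
#'
#' @param plane projection plane, one of `"XY"`, `"XZ"`, `"YZ"`.
#' @param grid_step raster pitch in Angstrom (default 0.02, which keeps
#'   single-disk areas within well under 1 percent of the analytic
#'   value).
#' @param radius_set name of the van-der-Waals radius set
#'   (only `"bondi"` is built in).
#' @return an object of class `fq_shadowspec`.
#' @export
shadow_spec <- function(plane = c("YZ", "XY", "XZ"), grid_step = 0.02,
                        radius_set = "bondi") {
  plane <- match.arg(plane)
  stopifnot(grid_step > 0)
  structure(list(plane = plane, grid_step = grid_step,
                 radius_set = radius_set), class = "fq_shadowspec")
}

# 10-atom bicyclic core of 4-oxo-quinoline / naphthyridone systems:
# N1, C2, C3, C4, C4a, C5..C8, C8a, with ring positions 5-8 allowed to
# be C or N (naphthyridones, pyridopyrimidines).  Matched by subgraph
# isomorphism; anchored by the C4 exocyclic carbonyl oxygen and the C3
# carboxyl carbon.
.core_pattern <- function() {
  # vertices 1..10 = N1 C2 C3 C4 C4a C5 C6 C7 C8 C8a
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 10), c(10, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 10))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# Find the heavy-atom indices of the quinolone core in canonical order
# N1, C2, C3, C4, C4a, C5, C6, C7, C8, C8a.
.find_core <- function(mol) {
  pat <- .core_pattern()
  maps <- igraph::subgraph_isomorphisms(pat, mol$graph, method = "vf2")
  adj <- igraph::as_adj_list(mol$graph)
  for (mp in maps) {
    idx <- as.integer(mp)
    if (mol$elements[idx[1]] != "N") next
    if (any(mol$elements[idx[2:5]] != "C")) next
    if (!all(mol$elements[idx[6:10]] %in% c("C", "N"))) next
    # C4 must carry an exocyclic double-bonded oxygen
    c4 <- idx[4]
    exo <- setdiff(as.integer(adj[[c4]]), idx)
    has_oxo <- any(vapply(exo, function(o) {
      mol$elements[o] == "O" &&
        any((mol$bonds$i == c4 & mol$bonds$j == o |
             mol$bonds$j == c4 & mol$bonds$i == o) & mol$bonds$order == 2L)
    }, logical(1)))
    if (!has_oxo) next
    # C3 must carry an exocyclic carboxyl carbon
    c3 <- idx[3]
    exo3 <- setdiff(as.integer(adj[[c3]]), idx)
    has_carboxyl <- any(vapply(exo3, function(cc) {
      if (mol$elements[cc] != "C") return(FALSE)
      nb <- as.integer(adj[[cc]])
      sum(mol$elements[nb] == "O") >= 2L
    }, logical(1)))
    if (!has_carboxyl) next
    return(list(idx = idx, oxo = exo[which(mol$elements[exo] == "O")[1]]))
  }
  stop("quinolone core not found (pattern: bicyclic N1/C2/C3/C4(=O)",
       "/C4a..C8a ring system with a C3 carboxyl)", call. = FALSE)
}

#' Align a 3D structure to the canonical quinolone frame
#'
#' Places the shared bicyclic 4-oxo-quinoline (or naphthyridone) core in
#' a canonical coordinate frame: core centroid at the origin, core
#' best-fit plane as the XY plane, long in-plane core axis as X.  The
#' frame is made unambiguous by requiring the ring nitrogen N1 to have
#' positive X and the C4 carbonyl oxygen positive Y; Z completes a
#' right-handed system.  The transform is rigid, so canonical
#' coordinates are invariant (to numerical precision) under any proper
#' rigid motion of the input.
#'
#' @param mol3d an [fq_compound] with 3D coordinates whose atom order
#'   matches the parsed structure (heavy atoms first if hydrogens are
#'   present).
#' @return the compound with transformed coordinates.
#' @export
align_canonical <- function(mol3d) {
  stopifnot(inherits(mol3d, "fq_compound"))
  if (is.null(mol3d$coords3d)) stop("no 3D coordinates present",
                                    call. = FALSE)
  m <- .as_mol(mol3d)
  xyz <- as.matrix(mol3d$coords3d[, c("x", "y", "z")])
  n_heavy <- length(m$elements)
  heavy_el <- mol3d$coords3d$element != "H"
  if (sum(heavy_el) != n_heavy) {
    stop("coordinate atom count does not match structure", call. = FALSE)
  }
  heavy_rows <- which(heavy_el)
  core <- .find_core(m)
  core_xyz <- xyz[heavy_rows[core$idx], , drop = FALSE]
  ctr <- colMeans(core_xyz)
  cc <- sweep(core_xyz, 2, ctr)
  pc <- eigen(crossprod(cc), symmetric = TRUE)
  R <- pc$vectors[, order(pc$values, decreasing = TRUE)]
  new_core <- cc %*% R
  if (new_core[1, 1] < 0) R[, 1] <- -R[, 1]        # N1 on positive X
  oxo_row <- heavy_rows[core$oxo]
  oxo_y <- ((xyz[oxo_row, ] - ctr) %*% R)[2]
  if (oxo_y < 0) R[, 2] <- -R[, 2]                  # carbonyl O positive Y
  R[, 3] <- .cross3(R[, 1], R[, 2])            # right-handed Z
  out <- sweep(xyz, 2, ctr) %*% R
  mol3d$coords3d$x <- out[, 1]
  mol3d$coords3d$y <- out[, 2]
  mol3d$coords3d$z <- out[, 3]
  mol3d
}

# plain 3-vector cross product
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Area of the molecular shadow on a coordinate plane
#'
#' Projects the van-der-Waals sphere of every atom onto the requested
#' plane and computes the area of the union of the resulting disks on a
#' raster of pitch `grid_step`.  The estimate converges to the exact
#' union area as the pitch decreases.  Structures should normally be
#' aligned with [align_canonical()] first so the plane is meaningful.
#'
#' @param mol3d an [fq_compound] with 3D coordinates.
#' @param spec an [shadow_spec()] object.
#' @param radii optional named radius override (element -> Angstrom).
#' @return shadow area in square Angstrom.
#' @export
shadow_area <- function(mol3d, spec = shadow_spec("YZ"), radii = NULL) {
  stopifnot(inherits(mol3d, "fq_compound"),
            inherits(spec, "fq_shadowspec"))
  if (is.null(mol3d$coords3d)) stop("no 3D coordinates present",
                                    call. = FALSE)
  if (is.null(radii)) {
    radii <- switch(spec$radius_set, bondi = .bondi_radii,
                    stop("unknown radius set: ", spec$radius_set,
                         call. = FALSE))
  }
  el <- mol3d$coords3d$element
  if (!all(el %in% names(radii))) {
    stop("missing van-der-Waals radius for element(s): ",
         paste(setdiff(unique(el), names(radii)), collapse = ", "),
         call. = FALSE)
  }
  r <- unname(radii[el])
  axes <- switch(spec$plane, XY = c("x", "y"), XZ = c("x", "z"),
                 YZ = c("y", "z"))
  u <- mol3d$coords3d[[axes[1]]]
  v <- mol3d$coords3d[[axes[2]]]
  h <- spec$grid_step
  gu <- seq(min(u - r) - h, max(u + r) + h, by = h)
  gv <- seq(min(v - r) - h, max(v + r) + h, by = h)
  covered <- matrix(FALSE, length(gu), length(gv))
  for (k in seq_along(u)) {
    iu <- which(abs(gu - u[k]) <= r[k])
    iv <- which(abs(gv - v[k]) <= r[k])
    if (!length(iu) || !length(iv)) next
    du2 <- (gu[iu] - u[k])^2
    dv2 <- (gv[iv] - v[k])^2
    covered[iu, iv] <- covered[iu, iv] | outer(du2, dv2, "+") <= r[k]^2
  }
  sum(covered) * h * h
}

#' Generate 3D coordinates for a compound
#'
#' Embeds the structure in 3D through OpenBabel (via the ChemmineOB
#' package) and attaches the coordinates to the record.  This gives a
#' reasonable low-energy geometry for shadow projections; it performs
#' no conformational search, so shadow areas from embedded geometries
#' are approximate.
#'
#' @param compound an [fq_compound].
#' @return the compound with `coords3d` filled in (hydrogens included).
#' @export
embed_3d <- function(compound) {
  stopifnot(inherits(compound, "fq_compound"))
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required for 3D embedding", call. = FALSE)
  }
  sdf <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(compound$smiles, " ", compound$id, "\n"),
    options = data.frame(names = "gen3d", args = ""))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  ab <- ChemmineR::atomblock(sdfset[[1]])
  compound$coords3d <- data.frame(
    element = sub("_\\d+$", "", rownames(ab)),
    x = ab[, 1], y = ab[, 2], z = ab[, 3])
  compound$hydrogens <- any(compound$coords3d$element == "H")
  compound
}
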