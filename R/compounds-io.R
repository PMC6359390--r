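# Loading and serializing compound structures and data tables.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "fqsar")
  if (!nzchar(p)) stop("bundled fixture file not found: ", file, call. = FALSE)
  p
}

.fixtures <- list(
  quinolones26 = "quinolones26.csv",
  table1_cip   = "table1_cip.csv",
  table1_cli   = "table1_cli.csv",
  table2       = "table2.csv"
)

#' Construct a compound record
#'
#' A compound record couples a short identifier with a structure given
#' as SMILES and, optionally, 3D coordinates (element, x, y, z in
#' Angstrom, heavy atoms only unless `hydrogens = TRUE`).
#'
#' @param id short compound code, e.g. `"CIP"`.
#' @param smiles SMILES string of the structure.
#' @param name free-text compound name.
#' @param coords3d optional data.frame with columns `element`, `x`, `y`,
#'   `z`; row order must follow the heavy-atom order of the parsed
#'   structure.
#' @param hydrogens whether `coords3d` includes hydrogen positions.
#' @return an object of class `fq_compound`.
#' @export
fq_compound <- function(id, smiles, name = id, coords3d = NULL,
                        hydrogens = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(coords3d)) {
    stopifnot(is.data.frame(coords3d),
              all(c("element", "x", "y", "z") %in% names(coords3d)))
  }
  structure(list(id = id, name = name, smiles = smiles,
                 coords3d = coords3d, hydrogens = isTRUE(hydrogens),
                 radii_source = "bondi"),
            class = "fq_compound")
}

#' @export
print.fq_compound <- function(x, ...) {
  cat("<fq_compound> ", x$id, " (", x$name, ")\n", sep = "")
  cat("  SMILES: ", x$smiles, "\n", sep = "")
  if (!is.null(x$coords3d)) {
    cat("  3D coordinates: ", nrow(x$coords3d), " atoms (",
        if (x$hydrogens) "with" else "heavy atoms only, no", " hydrogens)\n",
        sep = "")
  }
  invisible(x)
}

#' Load compound structures
#'
#' Reads compounds from a bundled fixture, a CSV file with columns
#' `id,name,smiles`, a SMILES file (one molecule per line, SMILES first,
#' whitespace-separated identifier second), or an SDF (V2000) file.
#' The bundled fixture `"quinolones26"` contains the 26 quinolones of
#' the bundled cross-reactivity study as isomeric SMILES.
#'
#' @param source fixture name (`"quinolones26"`) or path to a
#'   `.csv`, `.smi`/`.smiles` or `.sdf` file.
#' @return a named list of [fq_compound] records.
#' @export
load_compounds <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% names(.fixtures)) {
    source <- .fixture_path(.fixtures[[source]])
  }
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  ext <- tolower(tools::file_ext(source))
  recs <- switch(ext,
    "csv" = {
      tab <- read.csv(source, stringsAsFactors = FALSE)
      stopifnot(all(c("id", "smiles") %in% names(tab)))
      if (is.null(tab$name)) tab$name <- tab$id
      mapply(fq_compound, tab$id, tab$smiles, tab$name, SIMPLIFY = FALSE)
    },
    "smi" = , "smiles" = {
      lines <- trimws(readLines(source, warn = FALSE))
      lines <- lines[nzchar(lines)]
      if (!length(lines)) {
        warning("empty SMILES file: ", source)
        list()
      } else {
        lapply(seq_along(lines), function(k) {
          parts <- strsplit(lines[k], "\\s+")[[1]]
          id <- if (length(parts) >= 2L) parts[2L] else paste0("mol", k)
          fq_compound(id, parts[1L],
                      name = if (length(parts) >= 2L)
                        paste(parts[-1L], collapse = " ") else id)
        })
      }
    },
    "sdf" = {
      sdfs <- ChemmineR::read.SDFset(source)
      lapply(seq_along(sdfs), function(k) {
        sdf <- sdfs[[k]]
        id <- ChemmineR::header(sdf)[["Molecule_Name"]]
        if (is.null(id) || !nzchar(id)) id <- paste0("mol", k)
        smi <- tryCatch(as.character(ChemmineR::sdf2smiles(sdfs[k])),
                        error = function(e)
                          stop("unparsable structure '", id, "': ",
                               conditionMessage(e), call. = FALSE))
        ab <- ChemmineR::atomblock(sdf)
        coords <- data.frame(element = sub("_\\d+$", "", rownames(ab)),
                             x = ab[, 1], y = ab[, 2], z = ab[, 3])
        hyd <- any(coords$element == "H")
        fq_compound(id, smi, coords3d = coords, hydrogens = hyd)
      })
    },
    stop("unsupported structure file type: .", ext, call. = FALSE)
  )
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  # fail early on unparsable SMILES, naming the offending record
  for (r in recs) mol_graph(r$smiles, id = r$id)
  setNames(recs, ids)
}

#' Load a cross-reactivity table
#'
#' Reads per-compound cross-reactivity percentages for one immunoassay
#' system.  Cells may be a positive number (measured), `"<X"` (below the
#' limit of detection X percent, left-censored) or `"-"` (not tested).
#' The bundled fixtures `"table1_cip"` (anti-ciprofloxacin antibody,
#' FPIA tracer system) and `"table1_cli"` (anti-clinafloxacin antibody,
#' ELISA) hold the measured values for the 26 bundled quinolones.
#' Any Cyrillic homoglyph of "C" in the system name is normalized to
#' ASCII on load.
#'
#' @param source fixture name or path to a CSV file with columns
#'   `compound_id,cr`.
#' @param system_id label for the assay system.
#' @return a data.frame of class `fq_crtable` with columns
#'   `compound_id`, `status` (`"measured"`, `"below_lod"`,
#'   `"not_tested"`), `cr_percent` and `lod_percent`.
#' @export
load_cr_table <- function(source, system_id = NULL) {
  stopifnot(is.character(source), length(source) == 1L)
  if (is.null(system_id)) {
    system_id <- switch(source,
                        table1_cip = "CIP-113/PAZ-FITC",
                        table1_cli = "CLI-132/CLI-C5-OVA, ELISA",
                        source)
  }
  system_id <- gsub("С", "C", gsub("с", "c", system_id))
  if (source %in% names(.fixtures)) source <- .fixture_path(.fixtures[[source]])
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  tab <- read.csv(source, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("compound_id", "cr") %in% names(tab))) {
    stop("cross-reactivity CSV must have columns compound_id, cr",
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty table", call. = FALSE)
  if (anyDuplicated(tab$compound_id)) stop("duplicate compound id(s)",
                                           call. = FALSE)
  cell <- trimws(tab$cr)
  status <- character(nrow(tab))
  cr <- lod <- rep(NA_real_, nrow(tab))
  for (k in seq_along(cell)) {
    v <- cell[k]
    if (v == "-") {
      status[k] <- "not_tested"
    } else if (grepl("^<", v)) {
      status[k] <- "below_lod"
      lod[k] <- as.numeric(sub("^<", "", v))
      if (is.na(lod[k]) || lod[k] <= 0)
        stop("unknown token in cr column: '", v, "'", call. = FALSE)
    } else {
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x)) stop("unknown token in cr column: '", v, "'",
                         call. = FALSE)
      if (x <= 0) stop("cross-reactivity must be positive, got ", x,
                       " for ", tab$compound_id[k], call. = FALSE)
      status[k] <- "measured"
      cr[k] <- x
    }
  }
  out <- data.frame(compound_id = tab$compound_id, status = status,
                    cr_percent = cr, lod_percent = lod,
                    stringsAsFactors = FALSE)
  structure(out, system_id = system_id,
            class = c("fq_crtable", "data.frame"))
}

#' @export
print.fq_crtable <- function(x, ...) {
  cat("Cross-reactivity table, system: ", attr(x, "system_id"), "\n",
      sep = "")
  cat("  measured: ", sum(x$status == "measured"),
      ", below LOD: ", sum(x$status == "below_lod"),
      ", not tested: ", sum(x$status == "not_tested"), "\n\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a cross-reactivity table to CSV
#'
#' Inverse of [load_cr_table()]; censored and untested entries are
#' written back as `"<lod"` and `"-"` so a round trip reproduces the
#' table exactly.
#'
#' @param table an `fq_crtable`.
#' @param path output CSV path.
#' @export
write_cr_table <- function(table, path) {
  cell <- ifelse(table$status == "measured",
                 format(table$cr_percent, trim = TRUE, digits = 15),
                 ifelse(table$status == "below_lod",
                        paste0("<", format(table$lod_percent, trim = TRUE,
                                           digits = 15)),
                        "-"))
  write.csv(data.frame(compound_id = table$compound_id, cr = cell),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a descriptor matrix
#'
#' A descriptor matrix is a dense numeric matrix (compounds in rows,
#' named descriptors in columns) carrying a per-column provenance flag:
#' `"computed"` (derived from structure by this package) or
#' `"supplied"` (read from a table).
#'
#' @param values numeric matrix with compound ids as rownames and
#'   unique descriptor names as colnames.
#' @param provenance `"computed"` or `"supplied"`, recycled per column.
#' @return the matrix with a `provenance` attribute.
#' @export
descriptor_matrix <- function(values, provenance = "supplied") {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyNA(values)) stop("descriptor matrix contains missing values",
                          call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate descriptor names",
                                            call. = FALSE)
  if (anyDuplicated(rownames(values))) stop("duplicate compound ids",
                                            call. = FALSE)
  provenance <- rep_len(provenance, ncol(values))
  stopifnot(all(provenance %in% c("computed", "supplied")))
  attr(values, "provenance") <- setNames(provenance, colnames(values))
  values
}

#' Load a descriptor table
#'
#' Reads a compound-by-descriptor CSV (first column `compound_id`,
#' remaining columns numeric).  The bundled fixture `"table2"` holds the
#' four descriptors of the bundled study -- `N(>CH-)`, `S(>CH-)`,
#' `N(Stereo)` and `Shadow-YZ` -- for the 26 quinolones.
#'
#' @param source fixture name or CSV path.
#' @return a descriptor matrix (see [descriptor_matrix()]) with
#'   provenance `"supplied"`.
#' @export
load_descriptor_table <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% names(.fixtures)) source <- .fixture_path(.fixtures[[source]])
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  tab <- read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty table", call. = FALSE)
  stopifnot(names(tab)[1] == "compound_id")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("descriptor table cells must be numeric",
                              call. = FALSE)
  rownames(vals) <- tab$compound_id
  descriptor_matrix(vals, "supplied")
}

#' Write a descriptor matrix to CSV
#'
#' @param x a descriptor matrix.
#' @param path output CSV path.
#' @export
write_descriptor_table <- function(x, path) {
  df <- data.frame(compound_id = rownames(x), check.names = FALSE)
  for (j in colnames(x)) df[[j]] <- format(x[, j], trim = TRUE, digits = 15)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
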