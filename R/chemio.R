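# Reading, writing and validating 3D structures.
#
# A molecule is a light S3 object: an id, a data.frame of atoms
# (element, period, group, x, y, z) in file order, and provenance.

#' Construct a molecule object
#'
#' @param id Chemical identifier string.
#' @param elements Character vector of chemical symbols, one per atom.
#' @param coords Numeric matrix, n x 3, coordinates in angstrom.
#' @param provenance Optional list describing the source (file, format).
#' @return An object of class `vt_molecule`.
#' @export
molecule <- function(id, elements, coords, provenance = list(source = "constructed")) {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be a length(elements) x 3 matrix")
  }
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  pg <- t(vapply(elements, periodic_position, c(period = 0, group = 0)))
  atoms <- data.frame(
    element = vapply(elements, normalize_element, ""),
    period = as.integer(pg[, "period"]),
    group = as.integer(pg[, "group"]),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (nrow(atoms) > 1L) {
    d <- stats::dist(coords)
    if (min(d) < 1e-6) stop("two atoms at identical coordinates (within 1e-6 angstrom)")
  }
  structure(list(id = id, atoms = atoms, provenance = provenance),
            class = "vt_molecule")
}

#' @export
print.vt_molecule <- function(x, ...) {
  cat("<vt_molecule>", x$id, "-", nrow(x$atoms), "atoms (",
      paste(names(sort(table(x$atoms$element), decreasing = TRUE)), collapse = " "),
      ")\n")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

atom_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Read one molecule from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolving each atom's element from
#' the element column (77-78) and falling back to the atom name when the
#' column is blank. Atom order is preserved from the file. Files without any
#' hydrogen are accepted with a warning, since many structure dumps omit
#' them.
#'
#' @param path Path to a PDB file containing a single molecule.
#' @param id Chemical identifier; defaults to the file name without extension.
#' @return A `vt_molecule`.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  elements <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    el <- at$elesy[i]
    if (is.na(el) || !nzchar(trimws(el))) el <- element_from_atom_name(at$elety[i])
    el <- normalize_element(el)
    if (is.na(match(el, .periodic_table$symbol))) {
      stop("record ", i, " (atom name '", trimws(at$elety[i]),
           "'): unresolvable element symbol '", el, "'")
    }
    elements[i] <- el
  }
  if (!any(elements == "H")) {
    warning("PDB file '", basename(path), "' contains no hydrogens; ",
            "accepting heavy-atom-only structure")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  molecule(id, elements, cbind(at$x, at$y, at$z),
           provenance = list(source = path, format = "pdb"))
}

# Atom-name fallback: strip digits, try two-letter then one-letter symbol.
element_from_atom_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", trimws(name))
  if (!nzchar(nm)) stop("atom record with empty name; cannot resolve element")
  two <- normalize_element(substr(nm, 1, 2))
  if (nchar(nm) >= 2 && !is.na(match(two, .periodic_table$symbol))) return(two)
  one <- normalize_element(substr(nm, 1, 1))
  if (!is.na(match(one, .periodic_table$symbol))) return(one)
  stop("cannot resolve an element from atom name '", name, "'")
}

#' Write a molecule to a canonical PDB file
#'
#' Emits HETATM records with coordinates to three decimals and the element
#' symbol in columns 77-78, so that `read_pdb(write_pdb(m))` round-trips
#' elements exactly and coordinates to 1e-3 angstrom.
#'
#' @param mol A `vt_molecule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(mol, path) {
  stopifnot(inherits(mol, "vt_molecule"))
  a <- mol$atoms
  counts <- integer(0)
  name <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    counts[el] <- if (is.na(counts[el])) 1L else counts[el] + 1L
    name[i] <- paste0(el, counts[el])
  }
  lines <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), substr(name, 1, 4), "LIG", "A", 1L,
    a$x, a$y, a$z, 1, 0, toupper(a$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Convert an SDF file to PDB using Open Babel
#'
#' A thin, explicit adapter around the external `obabel` converter: never
#' invoked silently by the readers. Fails if the converter is not on PATH.
#'
#' @param sdf_path Input SDF file.
#' @param pdb_path Output PDB path; defaults to the SDF path with a .pdb
#'   extension.
#' @return The PDB path, invisibly.
#' @export
sdf_to_pdb <- function(sdf_path, pdb_path = sub("\\.sdf$", ".pdb", sdf_path)) {
  if (!file.exists(sdf_path)) stop("no such file: ", sdf_path)
  if (Sys.which("obabel") == "") stop("Open Babel ('obabel') not found on PATH")
  status <- system2("obabel", c(shQuote(sdf_path), "-O", shQuote(pdb_path)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(pdb_path)) {
    stop("obabel conversion failed for ", sdf_path)
  }
  invisible(pdb_path)
}
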