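#' Molecular structure container
#'
#' A minimal container for one molecular geometry: element symbols, Cartesian
#' coordinates (Angstrom) and per-atom masses and van der Waals radii filled
#' from the element table. Atom order is significant throughout the package:
#' the reactant and transition-state structures of a reaction must list the
#' same atoms in the same order.
#'
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstrom (anything coercible: a 3-column data.frame or a length-3n
#'   vector filled by rows).
#' @param label Free-text label (e.g. file name or reaction tag).
#' @param masses Optional numeric vector of atomic masses (amu); defaults to
#'   the standard atomic weights from [element_mass()].
#' @param vdw_radii Optional numeric vector of radii (Angstrom); defaults to
#'   [element_vdw_radius()].
#' @param vdw_fallback Optional fallback radius for elements missing from
#'   the vdW table (passed to [element_vdw_radius()]).
#' @param element_data Element table, see [element_table()].
#' @return An object of class `molecular_structure`: a list with fields
#'   `label`, `elements`, `coordinates`, `masses`, `vdw_radii`.
#' @export
#' @examples
#' h2 <- molecular_structure(c("H", "H"),
#'                           rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' h2
molecular_structure <- function(elements, coordinates, label = "",
                                masses = NULL, vdw_radii = NULL,
                                vdw_fallback = NULL,
                                element_data = element_table()) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecular structure needs at least one atom")
  coordinates <- as.matrix(coordinates)
  if (is.null(dim(coordinates)) || ncol(coordinates) == 1L) {
    coordinates <- matrix(as.numeric(coordinates), ncol = 3L, byrow = TRUE)
  }
  storage.mode(coordinates) <- "double"
  if (nrow(coordinates) != n || ncol(coordinates) != 3L) {
    stop("coordinates must be an n x 3 matrix matching ", n, " atoms")
  }
  if (!all(is.finite(coordinates))) stop("coordinates must all be finite")
  if (is.null(masses)) {
    masses <- unname(element_mass(elements, table = element_data))
  }
  if (is.null(vdw_radii)) {
    vdw_radii <- unname(element_vdw_radius(elements, table = element_data,
                                           fallback = vdw_fallback))
  }
  masses <- as.numeric(masses)
  vdw_radii <- as.numeric(vdw_radii)
  if (length(masses) != n || length(vdw_radii) != n) {
    stop("masses and vdw_radii must have one entry per atom")
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all atomic masses must be finite and > 0")
  }
  if (any(!is.finite(vdw_radii)) || any(vdw_radii < 0)) {
    stop("all vdW radii must be finite and >= 0")
  }
  dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
  structure(
    list(label = label, elements = elements, coordinates = coordinates,
         masses = masses, vdw_radii = vdw_radii),
    class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat("Molecular structure", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat("  atoms:", length(x$elements), "(",
      paste(names(sort(table(x$elements), decreasing = TRUE)),
            sort(table(x$elements), decreasing = TRUE),
            sep = "", collapse = " "), ")\n")
  cat("  mass: ", format(sum(x$masses), digits = 6), "amu\n")
  invisible(x)
}

n_atoms <- function(structure) length(structure$elements)

#' Read a molecular geometry from an XYZ file
#'
#' Parses the XMOL XYZ dialect: first line the atom count, second line a
#' free comment, then one `symbol x y z` line per atom with coordinates in
#' Angstrom. Atom order is preserved. Masses and vdW radii are filled from
#' the element table.
#'
#' @param path Path to an XYZ file.
#' @inheritParams molecular_structure
#' @return A [molecular_structure()].
#' @export
read_xyz <- function(path, vdw_fallback = NULL,
                     element_data = element_table()) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ parse error in ", path, ": empty file")
  count <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(count) || count < 1L) {
    stop("XYZ parse error in ", path,
         ", line 1: expected a positive atom count, got '", lines[1L], "'")
  }
  body <- lines[-(1:2)]
  body_nonblank <- which(nzchar(trimws(body)))
  if (length(body_nonblank) < count) {
    stop("XYZ parse error in ", path, ": header announces ", count,
         " atoms but only ", length(body_nonblank), " atom lines found")
  }
  elements <- character(count)
  coords <- matrix(NA_real_, count, 3L)
  for (i in seq_len(count)) {
    lineno <- 2L + body_nonblank[i]
    tok <- strsplit(trimws(body[body_nonblank[i]]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) {
      stop("XYZ parse error in ", path, ", line ", lineno,
           ": expected 'symbol x y z'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error in ", path, ", line ", lineno,
           ": non-numeric coordinates")
    }
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  bad <- !(elements %in% element_data$symbol)
  if (any(bad)) {
    stop("XYZ parse error in ", path, ", line ",
         2L + body_nonblank[which(bad)[1L]], ": unknown element symbol '",
         elements[which(bad)[1L]], "'")
  }
  molecular_structure(elements, coords,
                      label = if (nchar(lines[2L] %||% "")) trimws(lines[2L])
                              else basename(path),
                      vdw_fallback = vdw_fallback,
                      element_data = element_data)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a molecular geometry to an XYZ file
#'
#' Inverse of [read_xyz()]; coordinates are printed with 10 decimals so a
#' write/read round trip preserves them well beyond 6 printed decimals.
#'
#' @param structure A [molecular_structure()].
#' @param path Output file path.
#' @param comment Comment for line 2 (defaults to the structure label).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = structure$label) {
  stopifnot(inherits(structure, "molecular_structure"))
  n <- n_atoms(structure)
  lines <- c(
    as.character(n),
    if (is.null(comment)) "" else gsub("[\r\n]", " ", comment),
    sprintf("%-3s %16.10f %16.10f %16.10f", structure$elements,
            structure$coordinates[, 1L], structure$coordinates[, 2L],
            structure$coordinates[, 3L]))
  writeLines(lines, path)
  invisible(path)
}
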