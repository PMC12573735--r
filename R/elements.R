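# Embedded element data: standard atomic weights and van der Waals radii.
# The shipped table (inst/extdata/element_data.tsv) covers H through Rn and
# combines the Bondi (1964) radii with the Mantina et al. (2009) main-group
# extensions; d-/f-block elements absent from both compilations carry the
# RDKit periodic-table values. The table is a plain-text TSV so it can be
# inspected and swapped for cross-checks.

.element_cache <- new.env(parent = emptyenv())

#' Element data table
#'
#' Returns the element table used for atomic masses and van der Waals radii.
#' By default the table shipped with the package is used; a user-supplied
#' table (same columns) can be given either directly via `path` or globally
#' through `options(ballmill.element_table = "<path>")`, e.g. to test the
#' sensitivity of the molecular radius to the vdW compilation.
#'
#' @param path Optional path to a TSV file with columns `symbol`,
#'   `mass_amu`, `vdw_radius_angstrom` (additional columns are kept).
#' @return A data.frame with one row per element.
#' @export
#' @examples
#' head(element_table())
element_table <- function(path = NULL) {
  if (is.null(path)) path <- getOption("ballmill.element_table", NULL)
  if (is.null(path)) {
    path <- system.file("extdata", "element_data.tsv", package = "ballmill")
  }
  key <- normalizePath(path, mustWork = TRUE)
  if (is.null(.element_cache[[key]])) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("symbol", "mass_amu", "vdw_radius_angstrom")
    if (!all(need %in% names(tab))) {
      stop("element table ", path, " must have columns: ",
           paste(need, collapse = ", "))
    }
    .element_cache[[key]] <- tab
  }
  .element_cache[[key]]
}

#' Standard atomic weight of an element
#'
#' @param symbol Character vector of element symbols (case sensitive,
#'   e.g. "H", "Cl").
#' @param table Element table, see [element_table()].
#' @return Numeric vector of masses in amu.
#' @export
#' @examples
#' element_mass("H")   # 1.008
#' element_mass("C")   # 12.011
element_mass <- function(symbol, table = element_table()) {
  idx <- match(symbol, table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  m <- table$mass_amu[idx]
  names(m) <- symbol
  m
}

#' Van der Waals radius of an element
#'
#' Used as the per-atom padding \eqn{\delta_i} when building the reference
#' molecular sphere. Elements absent from the table either raise an error
#' (default) or, when `fallback` is given, return that radius with a warning.
#'
#' @inheritParams element_mass
#' @param fallback Optional radius in Angstrom returned (with a warning) for
#'   symbols absent from the table.
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' element_vdw_radius("H")  # 1.20
#' element_vdw_radius("C")  # 1.70
element_vdw_radius <- function(symbol, table = element_table(),
                               fallback = NULL) {
  idx <- match(symbol, table$symbol)
  if (anyNA(idx)) {
    missing <- unique(symbol[is.na(idx)])
    if (is.null(fallback)) {
      stop("no van der Waals radius tabulated for: ",
           paste(missing, collapse = ", "),
           " (supply `fallback` to use a default radius)")
    }
    warning("no van der Waals radius tabulated for ",
            paste(missing, collapse = ", "), "; using fallback ",
            fallback, " Angstrom")
  }
  r <- table$vdw_radius_angstrom[idx]
  if (!is.null(fallback)) r[is.na(idx)] <- fallback
  names(r) <- symbol
  r
}
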