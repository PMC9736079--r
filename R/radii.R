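#' Load a van der Waals radius set
#'
#' Reads an element -> vdW radius (Angstrom) table. The packaged default is a
#' Bondi-style set covering H, C, N, O, S, P, the halogens, and common
#' biologically relevant metals.
#'
#' @param path TSV file with columns `element` and `radius`; default is the
#'   packaged table.
#' @return Named numeric vector of radii, class `radius_set`.
#' @export
load_radius_set <- function(path = .extdata("vdw_radii.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(tab)))
    stop("radius table must have columns 'element' and 'radius'")
  if (any(tab$radius <= 0)) stop("radii must be positive")
  r <- setNames(tab$radius, tab$element)
  class(r) <- "radius_set"
  r
}

#' Assign per-atom van der Waals radii
#'
#' Attaches radii from a [load_radius_set()] table to every atom of a protein
#' structure or ligand pose. Elements absent from the set are an explicit
#' error (never silently defaulted).
#'
#' @param x A `protein_structure` or `ligand_pose`.
#' @param radii A `radius_set`; default the packaged table.
#' @return `x` with `atoms$radius` populated; otherwise unchanged.
#' @export
assign_radii <- function(x, radii = load_radius_set()) {
  el <- x$atoms$element
  missing <- setdiff(unique(el), names(radii))
  if (length(missing))
    stop("no van der Waals radius for element(s): ",
         paste(missing, collapse = ", "))
  x$atoms$radius <- unname(radii[el])
  x
}

# Normalize an element symbol: "CL"/"cl" -> "Cl", " C" -> "C"
.norm_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}
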