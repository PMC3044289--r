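#' Construct an atom table
#'
#' Atoms are plain tibbles throughout pharmint: one row per atom with
#' Cartesian coordinates in Angstrom, an element symbol, and an interaction
#' type used by the energy terms.  All heavy atoms must carry one of the six
#' interaction types; hydrogens are tolerated but ignored by every geometric
#' computation.
#'
#' @param id integer atom identifiers, unique within a molecule.
#' @param name short atom names (e.g. `"CA"`, `"OG"`, `"O1"`).
#' @param element element symbols (`"C"`, `"N"`, ...).
#' @param x,y,z coordinates in Angstrom; must be finite.
#' @param interaction_type one of `"donor"`, `"acceptor"`,
#'   `"donor_acceptor"`, `"nonpolar"`, `"cation"`, `"anion"`, or `NA` before
#'   typing.
#' @param formal_charge integer formal charges (default 0).
#' @return a tibble with one row per atom.
#' @export
atom_table <- function(id, name, element, x, y, z,
                       interaction_type = NA_character_,
                       formal_charge = 0L) {
  atoms <- tibble::tibble(
    id = as.integer(id), name = as.character(name),
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    interaction_type = as.character(interaction_type),
    formal_charge = as.integer(formal_charge)
  )
  validate_atoms(atoms)
  atoms
}

INTERACTION_TYPES <- c("donor", "acceptor", "donor_acceptor",
                       "nonpolar", "cation", "anion")

validate_atoms <- function(atoms) {
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (any(!nzchar(atoms$element))) abort("atom elements must be non-empty")
  if (anyDuplicated(atoms$id)) abort("atom ids must be unique")
  typed <- atoms$interaction_type
  bad <- !is.na(typed) & !typed %in% INTERACTION_TYPES
  if (any(bad)) {
    abort(paste0("unknown interaction_type: ",
                 paste(unique(typed[bad]), collapse = ", ")))
  }
  invisible(atoms)
}

#' Keep heavy (non-hydrogen) atoms
#' @param atoms an atom tibble.
#' @return the heavy-atom subset.
#' @export
heavy_atoms <- function(atoms) {
  dplyr::filter(atoms, toupper(.data$element) != "H")
}

#' Element class used for atomic composition
#'
#' Heavy atoms are bucketed into `{C, N, O, S, P, halogen, other}`.
#'
#' @param element character vector of element symbols.
#' @return character vector of classes.
#' @export
element_class <- function(element) {
  el <- toupper(element)
  dplyr::case_when(
    el %in% c("C", "N", "O", "S", "P") ~ el,
    el %in% c("F", "CL", "BR", "I") ~ "halogen",
    TRUE ~ "other"
  )
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# all pairwise distances between two coordinate matrices (rows x rows)
cross_distances <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
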