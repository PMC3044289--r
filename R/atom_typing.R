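# Interaction-type assignment.
#
# Protein atoms are typed from a residue template table (implicit hydrogens:
# the donor/acceptor character of each named heavy atom in the 20 standard
# amino acids is known without building hydrogen coordinates).  Ligand atoms
# are typed from elements and bonds.

backbone_names <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HXT")

# side-chain template: (resname, atom name) -> interaction type.
# Atoms not listed default to nonpolar (C, S) by element rules.
sidechain_template <- function() {
  tribble_ <- tibble::tribble
  tribble_(
    ~resname, ~name, ~interaction_type,
    "SER", "OG",  "donor_acceptor",
    "THR", "OG1", "donor_acceptor",
    "TYR", "OH",  "donor_acceptor",
    "CYS", "SG",  "nonpolar",
    "ASP", "OD1", "anion",
    "ASP", "OD2", "anion",
    "GLU", "OE1", "anion",
    "GLU", "OE2", "anion",
    "ASN", "OD1", "acceptor",
    "ASN", "ND2", "donor",
    "GLN", "OE1", "acceptor",
    "GLN", "NE2", "donor",
    "LYS", "NZ",  "cation",
    "ARG", "NE",  "cation",
    "ARG", "NH1", "cation",
    "ARG", "NH2", "cation",
    "HIS", "ND1", "donor_acceptor",
    "HIS", "NE2", "donor_acceptor",
    "TRP", "NE1", "donor"
  )
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Assign interaction types to protein atoms via residue templates
#'
#' Backbone N is a donor (acceptor for proline, which carries no amide H),
#' backbone O an acceptor and a terminal OXT a carboxylate anion.  Side
#' chains follow a fixed template: hydroxyls are donor/acceptor, carboxylate
#' oxygens anions, guanidinium/ammonium nitrogens cations, amide O/N
#' acceptor/donor, histidine ring nitrogens donor/acceptor, and everything
#' else (C, S) nonpolar.  Unknown residue names fall back to all-nonpolar
#' with a warning.
#'
#' @param atoms protein atom tibble with `resname` and `name` columns.
#' @return the tibble with `interaction_type` (and `formal_charge`) filled.
#' @export
assign_protein_types <- function(atoms) {
  tpl <- sidechain_template()
  unknown <- setdiff(unique(atoms$resname[atoms$record == "ATOM"]),
                     STANDARD_AA)
  if (length(unknown) > 0) {
    warn(paste0("unknown residue name(s) typed nonpolar: ",
                paste(unknown, collapse = ", ")))
  }
  atoms |>
    dplyr::left_join(tpl, by = c("resname", "name"),
                     suffix = c("", ".tpl")) |>
    dplyr::mutate(
      interaction_type = dplyr::case_when(
        !is.na(.data$interaction_type.tpl) ~ .data$interaction_type.tpl,
        .data$name == "N" & .data$resname == "PRO" ~ "acceptor",
        .data$name == "N" ~ "donor",
        .data$name == "O" ~ "acceptor",
        .data$name == "OXT" ~ "anion",
        TRUE ~ "nonpolar"
      ),
      formal_charge = dplyr::case_when(
        .data$interaction_type == "cation" ~ 1L,
        .data$interaction_type == "anion" ~ -1L,
        TRUE ~ 0L
      )
    ) |>
    dplyr::select(-"interaction_type.tpl")
}

#' Assign interaction types to ligand atoms from elements and bonds
#'
#' Rules (heavy atoms; explicit hydrogens are used when present, otherwise
#' hydrogens are implied from free valence):
#' * O bonded to an H, or a terminal single-bonded O (hydroxyl-like):
#'   donor/acceptor.  Carbonyl and ether/ester O: acceptor.  Terminal O on a
#'   C or P carrying two or more terminal oxygens (carboxylate, phosphate),
#'   or O with negative formal charge: anion.
#' * N with positive formal charge or in a guanidinium group: cation.  N
#'   with an attached or implied H (fewer than 3 heavy neighbours, no double
#'   bond): donor.  Otherwise (unprotonated): acceptor.
#' * C, S, P, halogens and anything else: nonpolar.
#'
#' MOL2 SYBYL types, when supplied, refine the element rules
#' (`O.co2` -> anion, `N.4` -> cation).
#'
#' @param atoms ligand atom tibble.
#' @param bonds bond tibble (`from`, `to`, `order`).
#' @param sybyl optional character vector of SYBYL atom types, parallel to
#'   `atoms`.
#' @return `atoms` with `interaction_type` and `formal_charge` filled.
#' @export
assign_atom_types <- function(atoms, bonds = empty_bonds(), sybyl = NULL) {
  n <- nrow(atoms)
  el <- toupper(atoms$element)
  type <- rep("nonpolar", n)

  deg_heavy <- integer(n); deg_h <- integer(n); has_double <- logical(n)
  if (nrow(bonds) > 0) {
    ii <- match(bonds$from, atoms$id); jj <- match(bonds$to, atoms$id)
    h_i <- el[jj] == "H"; h_j <- el[ii] == "H"
    for (k in seq_len(nrow(bonds))) {
      if (el[jj[k]] == "H") deg_h[ii[k]] <- deg_h[ii[k]] + 1L
      else deg_heavy[ii[k]] <- deg_heavy[ii[k]] + 1L
      if (el[ii[k]] == "H") deg_h[jj[k]] <- deg_h[jj[k]] + 1L
      else deg_heavy[jj[k]] <- deg_heavy[jj[k]] + 1L
    }
    dbl <- bonds$order %in% c("2", "3", "ar", "am", "2.0")
    has_double[unique(c(ii[dbl], jj[dbl]))] <- TRUE
  }

  # terminal oxygens per heavy neighbour (for carboxylate/phosphate)
  neighbours <- function(i) {
    if (nrow(bonds) == 0) return(integer())
    ii <- match(bonds$from, atoms$id); jj <- match(bonds$to, atoms$id)
    c(jj[ii == i], ii[jj == i])
  }
  is_terminal_o <- el == "O" & deg_heavy == 1L

  for (i in seq_len(n)) {
    if (el[i] == "O") {
      nb <- neighbours(i)
      nb <- nb[el[nb] != "H"]
      acid_centre <- length(nb) == 1 && el[nb] %in% c("C", "P", "S") &&
        sum(is_terminal_o[neighbours(nb)]) >= 2
      if (atoms$formal_charge[i] < 0 || (acid_centre && is_terminal_o[i])) {
        type[i] <- "anion"              # carboxylate / phosphate / sulfate O
      } else if (deg_h[i] > 0 || (deg_heavy[i] <= 1 && !has_double[i])) {
        type[i] <- "donor_acceptor"     # hydroxyl (explicit or implied H)
      } else {
        type[i] <- "acceptor"           # carbonyl / ether / ester
      }
    } else if (el[i] == "N") {
      nb <- neighbours(i); nb <- nb[el[nb] != "H"]
      guanidinium <- any(vapply(nb, function(c0) {
        el[c0] == "C" && sum(el[neighbours(c0)] == "N") >= 3
      }, logical(1)))
      if (atoms$formal_charge[i] > 0 || guanidinium) {
        type[i] <- "cation"
      } else if (deg_h[i] > 0 || (deg_heavy[i] < 3 && !has_double[i])) {
        type[i] <- "donor"
      } else {
        type[i] <- "acceptor"
      }
    }
  }

  if (!is.null(sybyl)) {
    type[sybyl == "O.co2"] <- "anion"
    type[sybyl == "N.4"] <- "cation"
  }
  type[el == "H"] <- "nonpolar"

  atoms$interaction_type <- type
  atoms$formal_charge <- dplyr::case_when(
    type == "cation" & atoms$formal_charge <= 0L ~ 1L,
    type == "anion" & atoms$formal_charge >= 0L ~ -1L,
    TRUE ~ atoms$formal_charge
  )
  atoms
}
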