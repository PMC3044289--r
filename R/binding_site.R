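#' Split one residue into main-chain and side-chain groups
#'
#' The main-chain group holds the backbone atoms (N, CA, C, O, OXT and their
#' attached hydrogens); everything else is the side-chain group.  Both
#' groups are always returned, so a glycine contributes an empty side-chain
#' group and every residue yields exactly two profile columns.
#'
#' @param residue_atoms atom tibble of a single residue (with `name`).
#' @return list with elements `main` and `side`, each an atom tibble.
#' @export
split_residue_groups <- function(residue_atoms) {
  is_main <- residue_atoms$name %in% backbone_names
  list(main = residue_atoms[is_main, , drop = FALSE],
       side = residue_atoms[!is_main, , drop = FALSE])
}

#' Derive the binding site from a bound reference ligand
#'
#' Retains every residue with at least one heavy atom within `radius` of any
#' heavy atom of the reference ligand, and splits each retained residue into
#' its main-chain and side-chain groups.  The group order -- (chain, residue
#' number) ascending, main before side -- is fixed and defines the column
#' order of all interaction profiles built from this site.
#'
#' @param protein a `protein_structure`.
#' @param reference a `ligand_pose` (e.g. the co-crystallised ligand, see
#'   [het_as_pose()]).
#' @param radius inclusion radius in Angstrom (default 8.0, enclosing a
#'   typical contact shell).
#' @return an object of class `binding_site`: list with `groups` (tibble:
#'   `group`, `chain`, `resno`, `resname`, `part`, `label`, `n_atoms`),
#'   `atoms` (flat atom tibble with a `group` column), `radius_used`,
#'   `reference`.
#' @export
extract_binding_site <- function(protein, reference, radius = 8.0) {
  if (radius <= 0) abort("radius must be positive")
  ref <- heavy_atoms(reference$atoms)
  if (nrow(ref) == 0) abort("reference ligand has no heavy atoms")

  prot <- dplyr::filter(protein$atoms, .data$record == "ATOM")
  if (nrow(prot) == 0) abort("protein has no ATOM records")
  ph <- heavy_atoms(prot)
  d <- cross_distances(coords_matrix(ph), coords_matrix(ref))
  ph$min_dist <- apply(d, 1, min)

  near <- ph |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resname) |>
    dplyr::summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= radius) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
  if (nrow(near) == 0) {
    abort(paste0("no residue within ", radius,
                 " Angstrom of the reference ligand; try a larger radius"))
  }

  group_rows <- list(); atom_rows <- list(); g <- 0L
  for (r in seq_len(nrow(near))) {
    key <- near[r, ]
    res_atoms <- dplyr::filter(prot,
      .data$chain == key$chain, .data$resno == key$resno,
      .data$insert == key$insert, .data$resname == key$resname)
    parts <- split_residue_groups(res_atoms)
    for (part in c("main", "side")) {
      g <- g + 1L
      lab <- group_label(key$chain, key$resno, key$resname, part)
      group_rows[[g]] <- tibble::tibble(
        group = g, chain = key$chain, resno = key$resno,
        resname = key$resname, part = part, label = lab,
        n_atoms = nrow(parts[[part]]))
      if (nrow(parts[[part]]) > 0) {
        pa <- parts[[part]]
        pa$group <- g
        pa$label <- lab
        atom_rows[[length(atom_rows) + 1L]] <- pa
      }
    }
  }
  structure(list(groups = dplyr::bind_rows(group_rows),
                 atoms = dplyr::bind_rows(atom_rows),
                 radius_used = radius,
                 reference = reference$compound_id),
            class = "binding_site")
}

group_label <- function(chain, resno, resname, part) {
  sprintf("%s:%s%d:%s", chain, resname, resno,
          ifelse(part == "main", "M", "S"))
}

#' Parse binding-site group labels
#'
#' Inverse of the `chain:RESNAMEnumber:part` labelling used for profile
#' columns (e.g. `"A:GLU353:S"`).
#'
#' @param label character vector of group labels.
#' @return tibble with `chain`, `resname`, `resno`, `part` columns.
#' @export
parse_group_label <- function(label) {
  m <- regmatches(label, regexec("^([^:]+):([A-Za-z]+)(-?\\d+):([MS])$", label))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) abort(paste0("malformed group label: ",
                             paste(label[bad], collapse = ", ")))
  tibble::tibble(
    chain = vapply(m, `[`, character(1), 2),
    resname = vapply(m, `[`, character(1), 3),
    resno = as.integer(vapply(m, `[`, character(1), 4)),
    part = ifelse(vapply(m, `[`, character(1), 5) == "M", "main", "side")
  )
}

#' @export
print.binding_site <- function(x, ...) {
  cat("<binding_site> ", nrow(x$groups), " residue groups (",
      nrow(x$groups) / 2, " residues) within ", x$radius_used,
      " Angstrom of ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Write a binding-site definition to TSV
#'
#' One row per residue group: chain, residue number, residue name, part and
#' the comma-joined atom names of the group.
#'
#' @param site a `binding_site`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site <- function(site, path) {
  atom_names <- site$atoms |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(atoms = paste(.data$name, collapse = ","),
                     .groups = "drop")
  out <- site$groups |>
    dplyr::left_join(atom_names, by = "group") |>
    dplyr::mutate(atoms = dplyr::coalesce(.data$atoms, "")) |>
    dplyr::select("chain", resnum = "resno", "resname", "part", "atoms")
  readr::write_tsv(out, path)
  invisible(path)
}
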