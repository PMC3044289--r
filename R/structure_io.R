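WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

#' Read a protein structure from a PDB file
#'
#' Parses one model of a PDB file into a protein structure: an atom tibble
#' with residue bookkeeping columns plus per-atom interaction types assigned
#' from a residue template table (implicit hydrogens; see
#' [assign_protein_types()]).  Waters are removed; when alternate locations
#' are present only the highest-occupancy location is kept (ties: first
#' occurring).
#'
#' @param path path to a PDB file.
#' @param model model number to extract (default 1).
#' @return an object of class `protein_structure`: a list with `atoms`
#'   (tibble: `chain`, `resno`, `insert`, `resname`, `record`, `id`, `name`,
#'   `element`, `x`, `y`, `z`, `interaction_type`, `formal_charge`),
#'   `source` and `model`.
#' @export
read_protein <- function(path, model = 1L) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    abort(paste0("model ", model, " requested but file has ", n_models))
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at <- tibble::as_tibble(pdb$atom)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at <- dplyr::filter(at, !.data$resid %in% WATER_RESNAMES)
  if (nrow(at) == 0) abort(paste0("no non-water atoms in ", path))

  # alternate locations: keep highest occupancy, tie -> first occurring
  at$.row <- seq_len(nrow(at))
  at$o[is.na(at$o)] <- 1
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid,
                    .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.row, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)

  element <- ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                    element_from_name(at$elety), at$elesy)
  atoms <- tibble::tibble(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    record = at$type,
    id = as.integer(at$eleno),
    name = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    interaction_type = NA_character_,
    formal_charge = 0L
  )
  atoms <- assign_protein_types(atoms)
  structure(list(atoms = atoms, source = path, model = as.integer(model)),
            class = "protein_structure")
}

element_from_name <- function(name) {
  stripped <- gsub("[0-9'\"]", "", name)
  two <- toupper(substr(stripped, 1, 2))
  el <- substr(stripped, 1, 1)
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")]
  toupper(el)
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("<protein_structure> ", nrow(x$atoms), " atoms, ", nrow(res),
      " residues (", x$source, ", model ", x$model, ")\n", sep = "")
  invisible(x)
}

#' Residue table of a protein structure
#' @param protein a `protein_structure`.
#' @return tibble with one row per residue in file order.
#' @export
residue_table <- function(protein) {
  dplyr::distinct(protein$atoms, .data$chain, .data$resno, .data$insert,
                  .data$resname)
}

#' Construct a ligand pose
#'
#' @param compound_id non-empty compound identifier.
#' @param atoms atom tibble (see [atom_table()]).
#' @param bonds tibble with columns `from`, `to` (atom ids) and `order`;
#'   may be empty.
#' @param pose_index 0-based pose counter within the compound.
#' @return an object of class `ligand_pose`.
#' @export
ligand_pose <- function(compound_id, atoms, bonds = empty_bonds(),
                        pose_index = 0L) {
  if (!nzchar(compound_id)) abort("compound_id must be non-empty")
  validate_atoms(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) > 0 &&
      !all(c(bonds$from, bonds$to) %in% atoms$id)) {
    abort("bond endpoints must be existing atom ids")
  }
  structure(list(compound_id = compound_id,
                 pose_index = as.integer(pose_index),
                 atoms = atoms, bonds = bonds),
            class = "ligand_pose")
}

empty_bonds <- function() {
  tibble::tibble(from = integer(), to = integer(), order = character())
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose> ", x$compound_id, " (pose ", x$pose_index, "): ",
      nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Read docked ligand poses from an SDF or MOL2 file
#'
#' Multi-record files yield one pose per record.  The compound id is taken
#' from the record name; records sharing a name get pose indices 0, 1, ...
#' in occurrence order.  Interaction types are assigned from elements and
#' bonds via [assign_atom_types()].  Records with zero atoms are skipped
#' with a warning; an empty file gives an empty list with a warning.
#'
#' @param path path to a `.sdf`/`.sd`/`.mol` or `.mol2` file.
#' @param format `"auto"` (by extension), `"sdf"` or `"mol2"`.
#' @return list of `ligand_pose` objects.
#' @export
read_poses <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("pose file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mol2", "ml2")) "mol2" else "sdf"
  }
  poses <- if (format == "sdf") read_poses_sdf(path) else read_poses_mol2(path)
  index_poses(poses)
}

index_poses <- function(poses) {
  if (length(poses) == 0) return(poses)
  ids <- vapply(poses, function(p) p$compound_id, character(1))
  idx <- stats::ave(seq_along(ids), ids, FUN = seq_along) - 1L
  purrr::map2(poses, idx, function(p, i) { p$pose_index <- as.integer(i); p })
}

read_poses_sdf <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(txt)))) {
    warn(paste0("empty pose file: ", path))
    return(list())
  }
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) abort(paste0(
                       "failed to parse SDF '", path, "': ",
                       conditionMessage(e))))
  n_at <- vapply(seq_along(sdfset), function(i) {
    ab <- ChemmineR::atomblock(sdfset[[i]])
    if (is.null(dim(ab))) 0L else nrow(ab)
  }, integer(1))
  if (any(n_at == 0)) {
    warn(paste0(sum(n_at == 0), " SDF record(s) with no atoms skipped in ",
                path))
  }
  purrr::map(unname(which(n_at > 0)), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || is.na(nm) || !nzchar(trimws(nm))) {
      nm <- paste0("record_", i)
    }
    element <- sub("_\\d+$", "", rownames(ab))
    atoms <- atom_table(
      id = seq_len(nrow(ab)),
      name = rownames(ab),
      element = element,
      x = ab[, 1], y = ab[, 2], z = ab[, 3]
    )
    no_bonds <- is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3 ||
      all(bb[, 1:2] == 0)   # bond-free records parse as a zero row
    bonds <- if (no_bonds) empty_bonds() else
      tibble::tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                     order = as.character(bb[, 3]))
    atoms <- assign_atom_types(atoms, bonds)
    ligand_pose(trimws(nm), atoms, bonds)
  })
}

read_poses_mol2 <- function(path) {
  txt <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", txt)
  if (length(starts) == 0) {
    warn(paste0("no MOL2 records in ", path))
    return(list())
  }
  ends <- c(starts[-1] - 1L, length(txt))
  purrr::map2(seq_along(starts), seq_along(starts), function(k, ...) {
    chunk <- txt[starts[k]:ends[k]]
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(chunk, tmp)
    mol <- tryCatch(bio3d::read.mol2(tmp),
                    error = function(e) abort(paste0(
                      "failed to parse MOL2 record ", k, " of '", path,
                      "': ", conditionMessage(e))))
    if (is.null(mol$atom) || nrow(mol$atom) == 0) {
      warn(paste0("MOL2 record ", k, " has no atoms; skipped"))
      return(NULL)
    }
    sybyl <- mol$atom$elety
    atoms <- atom_table(
      id = as.integer(mol$atom$eleno),
      name = mol$atom$elena,
      element = toupper(sub("\\..*$", "", sybyl)),
      x = mol$atom$x, y = mol$atom$y, z = mol$atom$z
    )
    bonds <- if (is.null(mol$bond) || nrow(mol$bond) == 0) empty_bonds() else
      tibble::tibble(from = as.integer(mol$bond$origin),
                     to = as.integer(mol$bond$target),
                     order = as.character(mol$bond$type))
    atoms <- assign_atom_types(atoms, bonds, sybyl = sybyl)
    nm <- if (!is.null(mol$name) && nzchar(trimws(mol$name))) trimws(mol$name)
          else paste0("record_", k)
    ligand_pose(nm, atoms, bonds)
  }) |> purrr::compact()
}

#' In-place RMSD between two poses of the same compound
#'
#' Root-mean-square deviation over matched heavy atoms in the docking frame
#' (no superposition, the convention for pose-accuracy assessment).  Atoms
#' are matched by input order after asserting identical element sequences.
#'
#' @param pose_a,pose_b `ligand_pose` objects with matched atom order.
#' @return RMSD in Angstrom.
#' @seealso [docking_success()] for the 2.0 Angstrom success criterion.
#' @export
pose_rmsd <- function(pose_a, pose_b) {
  a <- heavy_atoms(pose_a$atoms); b <- heavy_atoms(pose_b$atoms)
  if (nrow(a) != nrow(b)) {
    abort(paste0("atom-count mismatch: ", nrow(a), " vs ", nrow(b)))
  }
  if (!identical(toupper(a$element), toupper(b$element))) {
    abort("element sequences differ; poses must share atom order")
  }
  d2 <- (a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2
  sqrt(mean(d2))
}

#' Docking success under the RMSD criterion
#'
#' A docked pose counts as a success when its in-place RMSD to the reference
#' pose is at or below `threshold` (default 2.0 Angstrom).
#'
#' @inheritParams pose_rmsd
#' @param threshold success cutoff in Angstrom.
#' @return logical.
#' @export
docking_success <- function(pose_a, pose_b, threshold = 2.0) {
  pose_rmsd(pose_a, pose_b) <= threshold
}

#' Extract a HETATM group of a protein structure as a reference ligand
#'
#' Convenience for deriving the binding site from a bound ligand already
#' present in the PDB file.
#'
#' @param protein a `protein_structure`.
#' @param resname HETATM residue name of the ligand (e.g. `"EST"`).
#' @return a `ligand_pose` holding the HETATM atoms.
#' @export
het_as_pose <- function(protein, resname) {
  at <- dplyr::filter(protein$atoms, .data$resname == !!resname)
  if (nrow(at) == 0) abort(paste0("no HETATM residue named ", resname))
  atoms <- atom_table(id = at$id, name = at$name, element = at$element,
                      x = at$x, y = at$y, z = at$z,
                      interaction_type = dplyr::coalesce(at$interaction_type,
                                                         "nonpolar"))
  ligand_pose(resname, atoms)
}

#' Write poses to a multi-record SDF (V2000) file
#'
#' Minimal V2000 emitter used by the synthetic fixtures; files written here
#' are read back through the standard SDF parser.
#'
#' @param poses list of `ligand_pose` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_poses_sdf <- function(poses, path) {
  blocks <- purrr::map_chr(poses, function(p) {
    a <- p$atoms; b <- p$bonds
    lines <- c(
      p$compound_id, "  pharmint", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              a$x, a$y, a$z, a$element),
      if (nrow(b) > 0) sprintf("%3d%3d%3d  0", match(b$from, a$id),
                               match(b$to, a$id),
                               bond_order_code(b$order)),
      "M  END", "$$$$"
    )
    paste(lines, collapse = "\n")
  })
  writeLines(blocks, path)
  invisible(path)
}

bond_order_code <- function(order) {
  code <- suppressWarnings(as.integer(order))
  code[is.na(code)] <- 1L
  pmin(pmax(code, 1L), 3L)
}
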