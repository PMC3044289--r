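# Fixtures are built in code at test time: tiny PDB/SDF/MOL2 texts, toy
# poses, and small profile matrices.

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fixture <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1.00, alt = "", element = NULL) {
  element <- element %||% substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resno, x, y, z, occ, 0, element)
}

# two residues: SER 1 (complete with OG) and GLY 2
two_residue_pdb <- function() {
  c(
    pdb_atom_line(1, "N",  "SER", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1.5, 0.0, 0.0),
    pdb_atom_line(3, "C",  "SER", "A", 1, 2.2, 1.3, 0.0),
    pdb_atom_line(4, "O",  "SER", "A", 1, 1.6, 2.4, 0.0),
    pdb_atom_line(5, "CB", "SER", "A", 1, 2.3, -1.2, 0.0),
    pdb_atom_line(6, "OG", "SER", "A", 1, 3.7, -1.0, 0.0),
    pdb_atom_line(7, "N",  "GLY", "A", 2, 3.5, 1.4, 0.0),
    pdb_atom_line(8, "CA", "GLY", "A", 2, 4.3, 2.6, 0.0),
    pdb_atom_line(9, "C",  "GLY", "A", 2, 5.8, 2.4, 0.0),
    pdb_atom_line(10, "O", "GLY", "A", 2, 6.4, 1.3, 0.0),
    "END"
  )
}

benzene_ring_coords <- function(r = 1.39) {
  ang <- (0:5) * pi / 3
  cbind(r * cos(ang), r * sin(ang), 0)
}

benzene_sdf_record <- function(name = "benzene") {
  xyz <- benzene_ring_coords()
  c(name, "  fixture", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], "C"),
    "  1  2  2  0", "  2  3  1  0", "  3  4  2  0",
    "  4  5  1  0", "  5  6  2  0", "  6  1  1  0",
    "M  END", "$$$$")
}

benzene_mol2_record <- function(name = "benzene") {
  xyz <- benzene_ring_coords()
  c("@<TRIPOS>MOLECULE", name, " 6 6 0 0 0", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%d C%d %.4f %.4f %.4f C.ar 1 BNZ 0.0", 1:6, 1:6,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    "@<TRIPOS>BOND",
    sprintf("%d %d %d ar", 1:6, 1:6, c(2:6, 1)))
}

# a bare pose from coordinates (all atoms typed explicitly)
make_pose <- function(id, coords, types = "nonpolar", elements = "C",
                      pose_index = 0L) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  types <- rep_len(types, n); elements <- rep_len(elements, n)
  ligand_pose(id, atom_table(seq_len(n), paste0(elements, seq_len(n)),
                             elements, coords[, 1], coords[, 2], coords[, 3],
                             interaction_type = types),
              pose_index = pose_index)
}

profile_from_matrix <- function(m, type = "H") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("CPD%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) {
    colnames(m) <- pharmint:::synthetic_group_labels(ceiling(ncol(m) / 2))[seq_len(ncol(m))]
  }
  pharmint:::new_interaction_profile(type, m)
}

# decomposition tibble built directly from an energy matrix (rows =
# compounds, cols = site group labels), one channel
decomp_from_energies <- function(e, type = "H", labels = colnames(e)) {
  rows <- rownames(e) %||% sprintf("CPD%03d", seq_len(nrow(e)))
  all_types <- c("E", "H", "V")
  out <- tidyr::expand_grid(compound_id = rows, group = seq_along(labels),
                            type = all_types) |>
    dplyr::mutate(label = labels[group], pose_index = 0L, energy = 0)
  for (i in seq_len(nrow(e))) for (j in seq_len(ncol(e))) {
    sel <- out$compound_id == rows[i] & out$group == j & out$type == type
    out$energy[sel] <- e[i, j]
  }
  out |>
    dplyr::group_by(compound_id) |>
    dplyr::mutate(total = sum(energy)) |>
    dplyr::ungroup() |>
    dplyr::select(compound_id, pose_index, group, label, type, energy, total)
}
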