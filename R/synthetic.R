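# Synthetic fixtures with known ground truth: planted binary profiles,
# geometric toy pockets with engineered contacts, and a screening benchmark
# of actives vs energy-matched decoys.  Everything is seeded and
# reproducible; all randomness flows through withr::with_seed.

#' Specification for a planted binary profile
#'
#' Profiles are independent Bernoulli matrices: background cells are 1 with
#' probability `p_bg`, planted (conserved) columns with probability
#' `p_cons`.  The defaults mirror a screening-scale study: 1000 compounds,
#' 10 interacting residues (20 groups per channel), background interaction
#' probability 0.05, planted conservation 0.6.
#'
#' @param n_compounds number of profile rows.
#' @param n_residues number of binding-site residues K (columns = 2K).
#' @param planted tibble with columns `type` (`"E"`, `"H"`, `"V"`) and
#'   `column` (1-based index into the 2K columns); default: H columns
#'   1, 3, 5, 7.
#' @param p_cons interaction probability of planted columns.
#' @param p_bg background interaction probability; must satisfy
#'   `0 <= p_bg < p_cons <= 1`.
#' @param seed RNG seed.
#' @return a `planted_profile_spec` list.
#' @export
planted_profile_spec <- function(n_compounds = 1000, n_residues = 10,
                                 planted = tibble::tibble(
                                   type = "H", column = c(1L, 3L, 5L, 7L)),
                                 p_cons = 0.6, p_bg = 0.05, seed = 33) {
  if (!(p_bg >= 0 && p_bg < p_cons && p_cons <= 1)) {
    abort("need 0 <= p_bg < p_cons <= 1")
  }
  if (any(planted$column > 2 * n_residues)) {
    abort("planted column index exceeds 2K")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_residues = as.integer(n_residues),
                 planted = planted, p_cons = p_cons, p_bg = p_bg,
                 seed = seed),
            class = "planted_profile_spec")
}

#' Generate planted interaction profiles
#'
#' @param spec a [planted_profile_spec()].
#' @return list with `profiles` (named list of `interaction_profile`s for
#'   E, H, V) and `truth` (tibble: `type`, `column`, `group`, `planted`).
#' @export
generate_profile <- function(spec) {
  n <- spec$n_compounds; k2 <- 2L * spec$n_residues
  cols <- synthetic_group_labels(spec$n_residues)
  rows <- sprintf("CPD%04d", seq_len(n))
  profiles <- withr::with_seed(spec$seed, {
    purrr::map(c(E = "E", H = "H", V = "V"), function(ch) {
      p <- rep(spec$p_bg, k2)
      p[spec$planted$column[spec$planted$type == ch]] <- spec$p_cons
      m <- matrix(rbinom(n * k2, 1L, rep(p, each = n)), nrow = n,
                  dimnames = list(rows, cols))
      new_interaction_profile(ch, m)
    })
  })
  truth <- tidyr::expand_grid(type = c("E", "H", "V"),
                              column = seq_len(k2)) |>
    dplyr::mutate(group = cols[.data$column]) |>
    dplyr::left_join(dplyr::mutate(spec$planted, planted = TRUE),
                     by = c("type", "column")) |>
    dplyr::mutate(planted = !is.na(.data$planted))
  list(profiles = profiles, truth = truth)
}

synthetic_group_labels <- function(n_residues) {
  as.vector(vapply(seq_len(n_residues), function(i) {
    c(group_label("A", i, "SER", "main"), group_label("A", i, "SER", "side"))
  }, character(2)))
}

#' Planted-column recovery experiment
#'
#' Repeatedly generates a planted profile, mines the planted channel, and
#' checks whether every planted column is called pharmacological while no
#' background column of that channel is.  Measures the mining operating
#' point under controlled conditions.
#'
#' @param spec a [planted_profile_spec()]; its `seed` field is ignored in
#'   favour of per-replicate seeds.
#' @param n_seeds number of replicates.
#' @param n_shuffles shuffles per null model.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return tibble with one row per replicate: `seed`, `all_planted_called`,
#'   `any_background_called`, `success`.
#' @export
recovery_experiment <- function(spec = planted_profile_spec(),
                                n_seeds = 100, n_shuffles = 1000,
                                seed = 1000) {
  channel <- unique(spec$planted$type)
  if (length(channel) != 1) abort("recovery experiment expects one planted channel")
  purrr::map_dfr(seq_len(n_seeds), function(r) {
    s <- spec; s$seed <- seed + r
    gen <- generate_profile(s)
    prefs <- mine_profile(gen$profiles[[channel]], n_shuffles = n_shuffles,
                          seed = seed + r)
    truth <- dplyr::filter(gen$truth, .data$type == channel)
    called <- prefs$call[match(truth$group, prefs$group)]
    all_planted <- all(called[truth$planted])
    any_bg <- any(called[!truth$planted])
    tibble::tibble(seed = s$seed, all_planted_called = all_planted,
                   any_background_called = any_bg,
                   success = all_planted && !any_bg)
  })
}

#' Specification for a synthetic ring pocket
#'
#' Serine residues are placed on a ring of radius `ring_radius` with their
#' side-chain hydroxyl oxygens (the "probe" atoms) pointing at the centre.
#' Backbone atoms sit further out, beyond the interaction cutoff of any
#' centrally-placed ligand atom, so an engineered contact touches exactly
#' one residue group.
#'
#' @param n_residues number of ring residues (default 12).
#' @param ring_radius probe-ring radius in Angstrom (default 14; large
#'   enough that a contact atom at ~3 Angstrom from one probe is beyond the
#'   6 Angstrom potential cutoff of every other site atom).
#' @return a `pocket_spec` list.
#' @export
pocket_spec <- function(n_residues = 12, ring_radius = 14) {
  if (n_residues < 2) abort("need at least 2 residues")
  structure(list(n_residues = as.integer(n_residues),
                 ring_radius = ring_radius),
            class = "pocket_spec")
}

#' Generate a synthetic pocket and engineered contact poses
#'
#' Each pose is described by a contact table: rows `(residue, distance)`
#' place one ligand oxygen (donor/acceptor) at exactly `distance` Angstrom
#' from that residue's side-chain hydroxyl probe, along the ray to the ring
#' centre.  Filler carbon atoms near the centre pad the molecule without
#' creating contacts.  With the default potential, a contact distance
#' inside the hydrogen-bond well (2.6--3.1 Angstrom) yields exactly the H
#' well depth for that side-chain group.
#'
#' @param spec a [pocket_spec()].
#' @param contact_tables named list (names = compound ids); each element a
#'   tibble with columns `residue` (1-based ring index) and `distance`
#'   (Angstrom from the probe).  An empty tibble gives an "all-off" pose.
#' @param n_filler filler carbon atoms per pose (default 3).
#' @param dir optional directory; when given, `pocket.pdb` and `poses.sdf`
#'   are written there.
#' @return list with `protein` (`protein_structure`), `poses` (list of
#'   `ligand_pose`), `spec`, and the file paths when `dir` was given.
#' @export
generate_pocket <- function(spec = pocket_spec(), contact_tables,
                            n_filler = 3, dir = NULL) {
  k <- spec$n_residues; r0 <- spec$ring_radius
  theta <- 2 * pi * (seq_len(k) - 1) / k
  u <- cbind(cos(theta), sin(theta))

  # serine geometry along the inward ray: probe OG at r0, CB at r0+3.5,
  # CA at r0+6, N/C/O around CA
  atom_rows <- list(); id <- 0L
  add <- function(resno, name, element, radial, offset = c(0, 0, 0)) {
    id <<- id + 1L
    pos <- c(u[resno, ] * radial, 0) + offset
    tibble::tibble(chain = "A", resno = resno, insert = "", resname = "SER",
                   record = "ATOM", id = id, name = name, element = element,
                   x = pos[1], y = pos[2], z = pos[3],
                   interaction_type = NA_character_, formal_charge = 0L)
  }
  for (i in seq_len(k)) {
    atom_rows[[length(atom_rows) + 1L]] <- dplyr::bind_rows(
      add(i, "N", "N", r0 + 6, c(0, 0, 1.2)),
      add(i, "CA", "C", r0 + 6),
      add(i, "C", "C", r0 + 7, c(0, 0, -1.0)),
      add(i, "O", "O", r0 + 8, c(0, 0, -1.6)),
      add(i, "CB", "C", r0 + 3.5),
      add(i, "OG", "O", r0)
    )
  }
  atoms <- assign_protein_types(dplyr::bind_rows(atom_rows))
  protein <- structure(list(atoms = atoms, source = "<synthetic>",
                            model = 1L), class = "protein_structure")

  if (is.null(names(contact_tables)) || any(!nzchar(names(contact_tables)))) {
    abort("contact_tables must be a named list (names = compound ids)")
  }
  poses <- purrr::imap(contact_tables, function(ct, cid) {
    ct <- tibble::as_tibble(ct)
    if (nrow(ct) > 0 && any(ct$residue < 1 | ct$residue > k)) {
      abort(paste0("contact residue out of range for ", cid))
    }
    xs <- ys <- zs <- numeric(0); els <- character(0); types <- character(0)
    if (nrow(ct) > 0) {
      pos <- u[ct$residue, , drop = FALSE] * (r0 - ct$distance)
      xs <- pos[, 1]; ys <- pos[, 2]; zs <- rep(0, nrow(ct))
      els <- rep("O", nrow(ct)); types <- rep("donor_acceptor", nrow(ct))
    }
    if (n_filler > 0) {
      ang <- 2 * pi * seq_len(n_filler) / n_filler
      xs <- c(xs, 1.5 * cos(ang)); ys <- c(ys, 1.5 * sin(ang))
      zs <- c(zs, rep(0, n_filler))
      els <- c(els, rep("C", n_filler))
      types <- c(types, rep("nonpolar", n_filler))
    }
    n_at <- length(xs)
    if (n_at == 0) abort(paste0("pose ", cid, " would have no atoms"))
    atoms <- atom_table(id = seq_len(n_at),
                        name = paste0(els, seq_len(n_at)),
                        element = els, x = xs, y = ys, z = zs,
                        interaction_type = types)
    bonds <- if (n_at > 1) {
      tibble::tibble(from = seq_len(n_at - 1), to = seq_len(n_at - 1) + 1L,
                     order = "1")
    } else empty_bonds()
    ligand_pose(cid, atoms, bonds)
  })

  out <- list(protein = protein, poses = unname(poses), spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pdb_path <- file.path(dir, "pocket.pdb")
    sdf_path <- file.path(dir, "poses.sdf")
    a <- protein$atoms
    bio3d::write.pdb(file = pdb_path,
                     xyz = as.vector(t(coords_matrix(a))),
                     resno = a$resno, resid = a$resname, eleno = a$id,
                     elety = a$name, chain = a$chain,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
    write_poses_sdf(out$poses, sdf_path)
    out$pdb_path <- pdb_path
    out$sdf_path <- sdf_path
  }
  out
}

#' Binding site of a synthetic pocket
#'
#' Builds a central pseudo-ligand and extracts the site with a radius that
#' reaches the side-chain probes of every ring residue, so all 2K residue
#' groups become profile columns in ring order.
#'
#' @param pocket result of [generate_pocket()].
#' @return a `binding_site`.
#' @export
pocket_site <- function(pocket) {
  r0 <- pocket$spec$ring_radius
  centre <- ligand_pose("centre", atom_table(1, "C1", "C", 0, 0, 0,
                                             "nonpolar"))
  extract_binding_site(pocket$protein, centre, radius = r0 + 8.5)
}

#' Synthetic screening benchmark: actives vs energy-matched decoys
#'
#' Builds a ring pocket with `n_planted` designated pharmacological
#' side-chain groups and one engineered hydrogen-bond contact set per
#' compound.  Every compound gets exactly `n_contacts` contacts (identical
#' contact geometry distribution), so the docked total energies of actives
#' and decoys are statistically matched and only the *placement* differs:
#'
#' * actives contact all `n_planted` planted probes, plus random
#'   background probes up to `n_contacts`;
#' * decoys contact each planted probe with probability `p_decoy_hit`
#'   (default 0.55, so the planted columns are conserved across the
#'   library, which is what makes them minable without knowing the
#'   actives), with the remaining contacts on random background probes.
#'
#' Contact distances are drawn uniformly from the flat hydrogen-bond well
#' (2.95--3.10 Angstrom), so each contact contributes the full H well depth
#' plus a small variable van der Waals term that breaks energy ties.
#'
#' @param n_actives,n_decoys library composition (defaults 10 / 990,
#'   a typical seeded-screening design).
#' @param seed RNG seed.
#' @param n_residues ring size (default 12).
#' @param n_planted number of planted pharmacological groups (default 3).
#' @param n_contacts contacts per compound (default 5).
#' @param p_decoy_hit decoy contact probability at each planted probe.
#' @return list with `pocket`, `site`, `poses`, `truth` (tibble:
#'   `compound_id`, `active`), `planted_groups` (site group indices of the
#'   planted side chains).
#' @export
benchmark_set <- function(n_actives = 10, n_decoys = 990, seed = 42,
                          n_residues = 12, n_planted = 3, n_contacts = 5,
                          p_decoy_hit = 0.55) {
  if (n_actives < 1 || n_decoys < 1) abort("need at least one active and one decoy")
  if (n_planted >= n_residues) abort("n_planted must be < n_residues")
  if (n_contacts > n_residues) abort("n_contacts must be <= n_residues")
  spec <- pocket_spec(n_residues = n_residues)
  planted <- seq_len(n_planted)
  background <- setdiff(seq_len(n_residues), planted)

  n_total <- n_actives + n_decoys
  tables <- withr::with_seed(seed, {
    ids <- sprintf("CPD%04d", sample.int(n_total))  # shuffled ids
    out <- vector("list", n_total)
    names(out) <- ids
    active_flag <- c(rep(TRUE, n_actives), rep(FALSE, n_decoys))
    for (i in seq_len(n_total)) {
      if (active_flag[i]) {
        res <- c(planted,
                 sample(background, n_contacts - n_planted))
      } else {
        hits <- planted[runif(n_planted) < p_decoy_hit]
        res <- c(hits, sample(background, n_contacts - length(hits)))
      }
      out[[i]] <- tibble::tibble(residue = res,
                                 distance = runif(length(res), 2.95, 3.10))
    }
    list(tables = out, active = active_flag)
  })
  pocket <- generate_pocket(spec, tables$tables)
  site <- pocket_site(pocket)
  lbl <- site$groups
  planted_groups <- lbl$group[lbl$part == "side" & lbl$resno %in% planted]
  list(pocket = pocket, site = site, poses = pocket$poses,
       truth = tibble::tibble(compound_id = names(tables$tables),
                              active = tables$active),
       planted_groups = planted_groups)
}
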