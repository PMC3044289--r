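# Piecewise-linear pairwise potential.
#
# Each interaction channel (E, H, V) uses a trapezoid parameterised by four
# knot distances d0 < d1 < d2 < d3 and a (negative) well depth: a linear
# clash ramp rising to +clash_penalty as the distance goes below d0 to 0, a
# descent from 0 at d0 to the well depth at d1, a flat well between d1 and
# d2, linear decay back to 0 at d3, and exactly 0 beyond d3.  The function
# is continuous and piecewise linear in the distance.

#' Default potential parameters
#'
#' Channel defaults are chosen so that one ideal hydrogen bond contributes
#' -2.5 kcal/mol (exactly the E/H profile threshold) while several van der
#' Waals contacts are needed to reach the -4 kcal/mol V threshold:
#' * H: knots 2.3, 2.6, 3.1, 3.6 Angstrom, depth -2.5
#' * V: knots 2.9, 3.3, 4.5, 6.0 Angstrom, depth -0.4 per pair
#' * E: knots 2.5, 3.0, 4.5, 6.0 Angstrom, depth -2.5 (attractive between
#'   opposite charges; the well is sign-flipped for like charges)
#' * clash penalty +20 kcal/mol
#'
#' All values are configuration, not physical constants; see
#' [read_potential_params()] to load them from YAML.
#'
#' @return a `potential_params` list with components `E`, `H`, `V` (each
#'   `knots`, `depth`) and `clash_penalty`.
#' @export
potential_params <- function() {
  structure(list(
    H = list(knots = c(2.3, 2.6, 3.1, 3.6), depth = -2.5),
    V = list(knots = c(2.9, 3.3, 4.5, 6.0), depth = -0.4),
    E = list(knots = c(2.5, 3.0, 4.5, 6.0), depth = -2.5),
    clash_penalty = 20
  ), class = "potential_params")
}

validate_potential_params <- function(params) {
  for (ch in c("E", "H", "V")) {
    k <- params[[ch]]$knots
    if (length(k) != 4 || any(diff(k) <= 0)) {
      abort(paste0("channel ", ch, ": knots must be 4 strictly increasing"))
    }
    if (params[[ch]]$depth >= 0) {
      abort(paste0("channel ", ch, ": well depth must be negative"))
    }
  }
  if (params$clash_penalty < 0) abort("clash_penalty must be >= 0")
  invisible(params)
}

#' Load potential parameters from a YAML file
#'
#' The file may override any subset of the defaults; structure mirrors
#' [potential_params()] (`H:`, `V:`, `E:` with `knots` and `depth`, plus
#' `clash_penalty`).
#'
#' @param path YAML file path.
#' @return a `potential_params` list.
#' @export
read_potential_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- potential_params()
  for (ch in intersect(names(cfg), c("E", "H", "V"))) {
    if (!is.null(cfg[[ch]]$knots)) params[[ch]]$knots <- as.numeric(cfg[[ch]]$knots)
    if (!is.null(cfg[[ch]]$depth)) params[[ch]]$depth <- as.numeric(cfg[[ch]]$depth)
  }
  if (!is.null(cfg$clash_penalty)) params$clash_penalty <- as.numeric(cfg$clash_penalty)
  validate_potential_params(params)
}

# vectorised trapezoid; attractive part only is sign-flipped for `flip`
piecewise_energy <- function(d, knots, depth, clash_penalty) {
  e <- numeric(length(d))
  i <- d < knots[1]
  e[i] <- clash_penalty * (knots[1] - d[i]) / knots[1]
  i <- d >= knots[1] & d < knots[2]
  e[i] <- depth * (d[i] - knots[1]) / (knots[2] - knots[1])
  i <- d >= knots[2] & d <= knots[3]
  e[i] <- depth
  i <- d > knots[3] & d < knots[4]
  e[i] <- depth * (knots[4] - d[i]) / (knots[4] - knots[3])
  e
}

h_capable_1 <- c("donor", "donor_acceptor")
h_capable_2 <- c("acceptor", "donor_acceptor")

pair_eligible <- function(type_a, type_b, channel) {
  switch(channel,
    H = (type_a %in% h_capable_1 & type_b %in% h_capable_2) |
        (type_a %in% h_capable_2 & type_b %in% h_capable_1),
    E = type_a %in% c("cation", "anion") & type_b %in% c("cation", "anion"),
    V = rep(TRUE, length(type_a)),
    abort(paste0("unknown channel: ", channel))
  )
}

#' Pairwise interaction energy between two atoms
#'
#' Evaluates the channel's trapezoid at the Euclidean distance between the
#' two atoms.  Ineligible pairs (e.g. two nonpolar atoms in the H channel)
#' return 0.  For the electrostatic channel the attractive well is
#' sign-flipped when both atoms carry the same charge sign, so like charges
#' are repulsive; the short-range clash penalty keeps its sign.  A pair of
#' two donor/acceptor atoms counts once.
#'
#' @param atom_a,atom_b single-row atom tibbles (or lists with `x`, `y`,
#'   `z`, `interaction_type`).
#' @param channel `"E"`, `"H"` or `"V"`.
#' @param params a `potential_params` list.
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(atom_a, atom_b, channel, params = potential_params()) {
  if (!pair_eligible(atom_a$interaction_type, atom_b$interaction_type,
                     channel)) {
    return(0)
  }
  d <- sqrt((atom_a$x - atom_b$x)^2 + (atom_a$y - atom_b$y)^2 +
              (atom_a$z - atom_b$z)^2)
  ch <- params[[channel]]
  e <- piecewise_energy(d, ch$knots, ch$depth, params$clash_penalty)
  if (channel == "E" &&
      atom_a$interaction_type == atom_b$interaction_type && e < 0) {
    e <- -e
  }
  e
}

#' Decompose a docked pose into per-residue-group channel energies
#'
#' Sums [pair_energy()] over every eligible (ligand heavy atom, site atom)
#' pair, per residue group and channel.  Groups or channels with no contact
#' are reported as exact zeros, so the result always holds
#' `2K x 3` rows per pose and the `total` equals the sum of all entries.
#'
#' @param pose a `ligand_pose`.
#' @param site a `binding_site`.
#' @param params a `potential_params` list.
#' @return a tibble (class `energy_decomposition`) with columns
#'   `compound_id`, `pose_index`, `group`, `label`, `type`, `energy`,
#'   `total`.
#' @export
decompose_energy <- function(pose, site, params = potential_params()) {
  if (nrow(site$groups) == 0) abort("binding site is empty")
  grid <- tidyr::expand_grid(
    group = site$groups$group,
    type = c("E", "H", "V")
  ) |>
    dplyr::left_join(site$groups[, c("group", "label")], by = "group")

  lig <- heavy_atoms(pose$atoms)
  if (nrow(lig) == 0) {
    warn(paste0("pose ", pose$compound_id, " has no heavy atoms"))
    energies <- rep(0, nrow(grid))
  } else {
    sa <- heavy_atoms(site$atoms)
    d <- cross_distances(coords_matrix(lig), coords_matrix(sa))
    energies <- purrr::map(c("E", "H", "V"), function(channel) {
      ch <- params[[channel]]
      elig <- outer(lig$interaction_type, sa$interaction_type,
                    function(a, b) pair_eligible(a, b, channel))
      e <- piecewise_energy(d, ch$knots, ch$depth, params$clash_penalty)
      dim(e) <- dim(d)
      if (channel == "E") {
        same_sign <- outer(lig$interaction_type, sa$interaction_type, "==")
        e[same_sign & e < 0] <- -e[same_sign & e < 0]
      }
      e[!elig] <- 0
      by_group <- colSums(e)            # per site atom
      rowsum(by_group, sa$group)        # per group, sorted by group id
    })
    names(energies) <- c("E", "H", "V")
    energies <- purrr::map_dbl(seq_len(nrow(grid)), function(r) {
      eg <- energies[[grid$type[r]]]
      v <- eg[match(grid$group[r], as.integer(rownames(eg))), 1]
      if (is.na(v)) 0 else v
    })
  }
  out <- grid
  out$compound_id <- pose$compound_id
  out$pose_index <- pose$pose_index
  out$energy <- energies
  out$total <- sum(energies)
  out <- out[, c("compound_id", "pose_index", "group", "label", "type",
                 "energy", "total")]
  class(out) <- c("energy_decomposition", class(out))
  out
}

#' Decompose many poses, optionally keeping the best pose per compound
#'
#' @param poses list of `ligand_pose` objects.
#' @param site a `binding_site`.
#' @param params a `potential_params` list.
#' @param pose_policy `"best"` keeps, per compound, the pose with the lowest
#'   total energy (ties: lowest pose index); `"all"` keeps every pose.
#' @return an `energy_decomposition` tibble covering the kept poses.
#' @export
batch_decompose <- function(poses, site, params = potential_params(),
                            pose_policy = c("best", "all")) {
  pose_policy <- match.arg(pose_policy)
  if (length(poses) == 0) {
    out <- decompose_energy(ligand_pose("x", atom_table(1, "C1", "C", 0, 0, 0,
                                                        "nonpolar")), site,
                            params)[0, ]
    return(out)
  }
  decomp <- dplyr::bind_rows(purrr::map(poses, decompose_energy,
                                        site = site, params = params))
  if (pose_policy == "best") {
    keep <- decomp |>
      dplyr::distinct(.data$compound_id, .data$pose_index, .data$total) |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::arrange(.data$total, .data$pose_index, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
    decomp <- dplyr::semi_join(decomp, keep,
                               by = c("compound_id", "pose_index"))
  }
  class(decomp) <- c("energy_decomposition", setdiff(class(decomp),
                                                     "energy_decomposition"))
  decomp
}

#' Per-pose total energies of a decomposition
#' @param decomp an `energy_decomposition` tibble.
#' @return tibble with `compound_id`, `pose_index`, `total`.
#' @export
energy_totals <- function(decomp) {
  dplyr::distinct(tibble::as_tibble(decomp), .data$compound_id,
                  .data$pose_index, .data$total)
}

#' Write an energy decomposition to TSV
#' @param decomp an `energy_decomposition` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energies <- function(decomp, path) {
  readr::write_tsv(tibble::as_tibble(decomp), path)
  invisible(path)
}
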