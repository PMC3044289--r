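at <- function(x, y, z, type) {
  list(x = x, y = y, z = z, interaction_type = type)
}

test_that("pair energy follows the configured trapezoid", {
  p <- potential_params()
  donor <- function(d) at(d, 0, 0, "donor")
  acc <- at(0, 0, 0, "acceptor")
  k <- p$H$knots
  # flat well
  expect_equal(pair_energy(donor(mean(k[2:3])), acc, "H", p), p$H$depth)
  expect_equal(pair_energy(donor(k[2]), acc, "H", p), p$H$depth)
  # zero beyond the cutoff, exactly
  expect_identical(pair_energy(donor(k[4] + 0.01), acc, "H", p), 0)
  # ramps interpolate linearly
  expect_equal(pair_energy(donor((k[1] + k[2]) / 2), acc, "H", p),
               p$H$depth / 2)
  expect_equal(pair_energy(donor((k[3] + k[4]) / 2), acc, "H", p),
               p$H$depth / 2)
  # clash is positive
  expect_gt(pair_energy(donor(k[1] / 2), acc, "H", p), 0)
  # symmetric in the argument order
  expect_equal(pair_energy(acc, donor(2.8), "H", p),
               pair_energy(donor(2.8), acc, "H", p))
})

test_that("pair energy is continuous at the knots", {
  p <- potential_params()
  for (ch in c("E", "H", "V")) {
    k <- p[[ch]]$knots
    f <- function(d) pharmint:::piecewise_energy(d, k, p[[ch]]$depth,
                                                 p$clash_penalty)
    for (knot in k) {
      expect_equal(f(knot - 1e-9), f(knot + 1e-9), tolerance = 1e-6)
    }
  }
})

test_that("pair eligibility: channel rules and like-charge repulsion", {
  p <- potential_params()
  d_well <- mean(p$E$knots[2:3])
  cation <- at(0, 0, 0, "cation"); anion <- at(d_well, 0, 0, "anion")
  cation2 <- at(d_well, 0, 0, "cation")
  expect_equal(pair_energy(cation, anion, "E", p), p$E$depth)
  expect_equal(pair_energy(cation, cation2, "E", p), -p$E$depth)  # repulsive
  # nonpolar pairs only interact through V
  np1 <- at(0, 0, 0, "nonpolar"); np2 <- at(3.5, 0, 0, "nonpolar")
  expect_identical(pair_energy(np1, np2, "H", p), 0)
  expect_identical(pair_energy(np1, np2, "E", p), 0)
  expect_equal(pair_energy(np1, np2, "V", p), p$V$depth)
  # donor/donor pairs are H-ineligible; donor_acceptor pairs count once
  d1 <- at(0, 0, 0, "donor"); d2 <- at(2.8, 0, 0, "donor")
  expect_identical(pair_energy(d1, d2, "H", p), 0)
  da1 <- at(0, 0, 0, "donor_acceptor"); da2 <- at(2.8, 0, 0, "donor_acceptor")
  expect_equal(pair_energy(da1, da2, "H", p), p$H$depth)
})

test_that("single engineered H contact decomposes to the well depth", {
  pocket <- generate_pocket(pocket_spec(n_residues = 4),
                            list(one = tibble::tibble(residue = 2,
                                                      distance = 2.85)))
  site <- pocket_site(pocket)
  decomp <- decompose_energy(pocket$poses[[1]], site)
  h <- dplyr::filter(decomp, type == "H")
  target <- dplyr::filter(site$groups, resno == 2, part == "side")$group
  expect_equal(h$energy[h$group == target], potential_params()$H$depth)
  expect_true(all(h$energy[h$group != target] == 0))
  # conservation: total equals the sum over all groups and channels
  expect_equal(decomp$total[1], sum(decomp$energy))
})

test_that("all-off poses decompose to exact zeros", {
  pocket <- generate_pocket(pocket_spec(n_residues = 4),
                            list(off = tibble::tibble(residue = integer(),
                                                      distance = numeric())))
  decomp <- decompose_energy(pocket$poses[[1]], pocket_site(pocket))
  expect_true(all(decomp$energy == 0))
  expect_equal(unique(decomp$total), 0)
})

test_that("decomposition equals a brute-force pair loop", {
  pocket <- generate_pocket(
    pocket_spec(n_residues = 5),
    list(m = tibble::tibble(residue = c(1, 3, 4),
                            distance = c(2.7, 3.0, 3.3))))
  site <- pocket_site(pocket)
  pose <- pocket$poses[[1]]
  decomp <- decompose_energy(pose, site)
  p <- potential_params()
  lig <- heavy_atoms(pose$atoms)
  sa <- heavy_atoms(site$atoms)
  for (ch in c("E", "H", "V")) {
    for (g in site$groups$group) {
      expected <- 0
      ga <- sa[sa$group == g, ]
      if (nrow(ga) > 0) {
        for (i in seq_len(nrow(lig))) for (j in seq_len(nrow(ga))) {
          expected <- expected + pair_energy(lig[i, ], ga[j, ], ch, p)
        }
      }
      got <- decomp$energy[decomp$group == g & decomp$type == ch]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("rigid translation of pose and site leaves energies unchanged", {
  pocket <- generate_pocket(
    pocket_spec(n_residues = 4),
    list(m = tibble::tibble(residue = c(1, 2), distance = c(2.8, 3.2))))
  site <- pocket_site(pocket)
  pose <- pocket$poses[[1]]
  d0 <- decompose_energy(pose, site)
  shift <- c(5.5, -2.0, 11.0)
  pose$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(pose$atoms[, c("x", "y", "z")]), 2, shift, "+")
  site$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(site$atoms[, c("x", "y", "z")]), 2, shift, "+")
  d1 <- decompose_energy(pose, site)
  expect_equal(d1$energy, d0$energy, tolerance = 1e-10)
})

test_that("batch decomposition keeps the best pose with the stated tie rule", {
  # three poses of one compound: totals become more negative with more
  # contacts; engineer a tie by repeating the same contact table
  ct <- list(
    tibble::tibble(residue = 1, distance = 2.85),
    tibble::tibble(residue = c(1, 2), distance = c(2.85, 2.85)),
    tibble::tibble(residue = c(1, 2), distance = c(2.85, 2.85)))
  names(ct) <- rep("cpd", 3)
  pocket <- generate_pocket(pocket_spec(n_residues = 4), ct)
  poses <- pharmint:::index_poses(pocket$poses)
  site <- pocket_site(pocket)
  best <- batch_decompose(poses, site, pose_policy = "best")
  expect_equal(unique(best$compound_id), "cpd")
  expect_equal(unique(best$pose_index), 1L)  # first of the tied minima
  all_rows <- batch_decompose(poses, site, pose_policy = "all")
  expect_equal(nrow(all_rows), 3 * nrow(site$groups) * 3)
})

test_that("potential parameters load from YAML with overrides", {
  path <- write_fixture(c("H:", "  depth: -3.0", "clash_penalty: 15"), ".yaml")
  p <- read_potential_params(path)
  expect_equal(p$H$depth, -3.0)
  expect_equal(p$clash_penalty, 15)
  expect_equal(p$V$knots, potential_params()$V$knots)
  bad <- write_fixture(c("H:", "  knots: [3, 2, 4, 5]"), ".yaml")
  expect_error(read_potential_params(bad), "increasing")
})
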