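test_that("planted profiles obey the spec probabilities exactly at 0/1", {
  spec <- planted_profile_spec(n_compounds = 20, n_residues = 3,
                               planted = tibble::tibble(type = "H",
                                                        column = c(1L, 4L)),
                               p_cons = 1, p_bg = 0, seed = 5)
  gen <- generate_profile(spec)
  h <- gen$profiles$H$matrix
  expect_true(all(h[, c(1, 4)] == 1))
  expect_true(all(h[, -c(1, 4)] == 0))
  expect_true(all(gen$profiles$E$matrix == 0))
  expect_equal(sum(gen$truth$planted), 2)
})

test_that("planted column frequency concentrates near p_cons", {
  spec <- planted_profile_spec(n_compounds = 1000, n_residues = 5,
                               planted = tibble::tibble(type = "H",
                                                        column = 2L),
                               p_cons = 0.6, p_bg = 0.05, seed = 17)
  h <- generate_profile(spec)$profiles$H$matrix
  expect_lt(abs(mean(h[, 2]) - 0.6), 3 * sqrt(0.6 * 0.4 / 1000))
  expect_lt(abs(mean(h[, -2]) - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("generation is seed-reproducible", {
  spec <- planted_profile_spec(n_compounds = 50, n_residues = 4, seed = 9)
  g1 <- generate_profile(spec); g2 <- generate_profile(spec)
  expect_identical(g1$profiles$H$matrix, g2$profiles$H$matrix)
  expect_error(planted_profile_spec(p_cons = 0.3, p_bg = 0.5), "p_bg")
})

test_that("pocket geometry isolates each engineered contact", {
  pocket <- generate_pocket(
    pocket_spec(n_residues = 6),
    list(two = tibble::tibble(residue = c(1, 4), distance = c(2.85, 3.0))))
  site <- pocket_site(pocket)
  expect_equal(nrow(site$groups), 12)
  decomp <- decompose_energy(pocket$poses[[1]], site)
  h <- dplyr::filter(decomp, type == "H", energy != 0)
  targets <- dplyr::filter(site$groups, resno %in% c(1, 4), part == "side")
  expect_setequal(h$group, targets$group)
  expect_true(all(h$energy == potential_params()$H$depth))
})

test_that("pocket files re-read without loss of atom counts", {
  dir <- withr::local_tempdir()
  pocket <- generate_pocket(
    pocket_spec(n_residues = 4),
    list(m1 = tibble::tibble(residue = 2, distance = 3.0)),
    dir = dir)
  prot <- read_protein(pocket$pdb_path)
  expect_equal(nrow(prot$atoms), nrow(pocket$protein$atoms))
  poses <- read_poses(pocket$sdf_path)
  expect_length(poses, 1)
  expect_equal(nrow(poses[[1]]$atoms), nrow(pocket$poses[[1]]$atoms))
})

test_that("end-to-end: engineered contacts recover the exact profile bits", {
  ct <- list(
    hit1 = tibble::tibble(residue = 1, distance = 2.85),
    hit13 = tibble::tibble(residue = c(1, 3), distance = c(2.85, 2.85)),
    none = tibble::tibble(residue = integer(), distance = numeric()))
  pocket <- generate_pocket(pocket_spec(n_residues = 4), ct)
  site <- pocket_site(pocket)
  decomp <- batch_decompose(pharmint:::index_poses(pocket$poses), site)
  prof <- build_profile(decomp, site, "H")
  side <- function(r) dplyr::filter(site$groups, resno == r,
                                    part == "side")$label
  expect_equal(unname(prof$matrix["hit1", side(1)]), 1L)
  expect_equal(unname(prof$matrix["hit13", side(3)]), 1L)
  expect_equal(sum(prof$matrix["none", ]), 0L)
  expect_equal(sum(prof$matrix), 3L)
})

test_that("benchmark set composition, reproducibility and truth labels", {
  b1 <- benchmark_set(n_actives = 3, n_decoys = 17, seed = 8,
                      n_residues = 6, n_planted = 2, n_contacts = 3)
  expect_equal(nrow(b1$truth), 20)
  expect_equal(sum(b1$truth$active), 3)
  expect_length(b1$poses, 20)
  expect_length(b1$planted_groups, 2)
  b2 <- benchmark_set(n_actives = 3, n_decoys = 17, seed = 8,
                      n_residues = 6, n_planted = 2, n_contacts = 3)
  expect_equal(b2$truth, b1$truth)

  # actives hit every planted side-chain group
  decomp <- batch_decompose(b1$poses, b1$site)
  prof <- build_profile(decomp, b1$site, "H")
  actives <- b1$truth$compound_id[b1$truth$active]
  planted_labels <- b1$site$groups$label[match(b1$planted_groups,
                                               b1$site$groups$group)]
  expect_true(all(prof$matrix[actives, planted_labels] == 1))
})
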