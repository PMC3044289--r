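toy_dist <- function() {
  m <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  stats::as.dist(m)
}

test_that("atomic composition: fractions over element classes", {
  benzene <- make_pose("bnz", benzene_ring_coords())
  comp <- atomic_composition(benzene)
  expect_equal(comp$C, 1.0)
  expect_equal(sum(comp[, -1]), 1.0)

  ethanol <- make_pose("eth", rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0)),
                       elements = c("C", "C", "O"))
  comp <- atomic_composition(ethanol)
  expect_equal(comp$C, 2 / 3)
  expect_equal(comp$O, 1 / 3)

  halo <- make_pose("cl", rbind(c(0, 0, 0), c(1.8, 0, 0)),
                    elements = c("C", "Cl"))
  expect_equal(atomic_composition(halo)$halogen, 0.5)
})

test_that("profile distance: Euclidean on concatenated binary rows", {
  m <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1))
  rownames(m) <- c("x", "y", "z")
  d <- profile_distance(profile_from_matrix(m))
  dm <- as.matrix(d)
  expect_equal(dm["x", "y"], 0)
  expect_equal(dm["x", "z"], 2)      # differs in 4 positions -> sqrt(4)
  expect_equal(dm["x", "z"], dm["z", "x"])
})

test_that("distances satisfy the metric axioms on random instances", {
  withr::with_seed(29, {
    m <- matrix(rbinom(10 * 8, 1, 0.5), nrow = 10,
                dimnames = list(sprintf("c%02d", 1:10), NULL))
    colnames(m) <- pharmint:::synthetic_group_labels(4)
    dm <- as.matrix(profile_distance(profile_from_matrix(m)))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    for (trial in 1:20) {
      ijk <- sample(10, 3)
      expect_lte(dm[ijk[1], ijk[3]],
                 dm[ijk[1], ijk[2]] + dm[ijk[2], ijk[3]] + 1e-12)
    }
  })
})

test_that("UPGMA on the 3-point toy matches the hand computation", {
  tree <- hierarchical_cluster(toy_dist())
  expect_equal(tree$height, c(1, 4))   # (A,B) at 1, then C at (4+4)/2
  expect_equal(tree$merge[1, ], c(-2, -1))
  labels_first <- tree$labels[-tree$merge[1, ]]
  expect_setequal(labels_first, c("A", "B"))
  cut2 <- cut_tree(tree, k = 2)
  expect_equal(cut2$cluster[cut2$compound_id == "A"],
               cut2$cluster[cut2$compound_id == "B"])
  expect_false(cut2$cluster[cut2$compound_id == "C"] ==
                 cut2$cluster[cut2$compound_id == "A"])
})

test_that("identical items merge first at height zero", {
  m <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), nrow = 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  tree <- hierarchical_cluster(stats::as.dist(m))
  expect_equal(tree$height[1], 0)
})

test_that("agreement with stats::hclust on distinct random distances", {
  withr::with_seed(37, {
    x <- matrix(rnorm(8 * 5), nrow = 8,
                dimnames = list(letters[1:8], NULL))
  })
  d <- stats::dist(x)
  for (linkage in c("average", "complete", "single")) {
    mine <- hierarchical_cluster(d, linkage = linkage)
    ref <- stats::hclust(d, method = linkage)
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    expect_equal(cutree(mine, k = 3)[mine$labels],
                 cutree(ref, k = 3)[mine$labels])
  }
})

test_that("merge heights are monotone and order-invariant under ties", {
  withr::with_seed(31, {
    m <- matrix(rbinom(12 * 6, 1, 0.4), nrow = 12,
                dimnames = list(sprintf("c%02d", 1:12), NULL))
    colnames(m) <- pharmint:::synthetic_group_labels(3)
  })
  d <- profile_distance(profile_from_matrix(m))  # binary data: many ties
  tree <- hierarchical_cluster(d)
  expect_true(all(diff(tree$height) >= -1e-12))

  perm <- withr::with_seed(4, sample(12))
  dperm <- stats::as.dist(as.matrix(d)[perm, perm])
  tree2 <- hierarchical_cluster(dperm)
  expect_equal(tree2$height, tree$height)
  # same flat clusters at every k, compared as label partitions
  for (k in c(2, 4, 6)) {
    c1 <- cut_tree(tree, k = k); c2 <- cut_tree(tree2, k = k)
    part <- function(ct) unname(split(ct$compound_id, ct$cluster)) |>
      lapply(sort) |> (\(x) x[order(vapply(x, `[`, "", 1))])()
    expect_equal(part(c1), part(c2))
  }
})

test_that("cut_tree honours k bounds and trivial cuts", {
  tree <- hierarchical_cluster(toy_dist())
  expect_equal(dplyr::n_distinct(cut_tree(tree, k = 3)$cluster), 3)
  expect_equal(dplyr::n_distinct(cut_tree(tree, k = 1)$cluster), 1)
  expect_error(cut_tree(tree, k = 5), "1..3")
  expect_error(cut_tree(tree), "exactly one")
})

test_that("newick export round-trips topology and quotes odd labels", {
  tree <- hierarchical_cluster(toy_dist())
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(tree, path, format = "newick")
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # A and B are siblings in the exported tree, with heights as branch lengths
  coph <- ape::cophenetic.phylo(phy)
  expect_lt(coph["A", "B"], coph["A", "C"])
  expect_equal(coph["A", "B"], 2 * 1, tolerance = 1e-9)   # 2 x merge height
  expect_equal(coph["A", "C"], 2 * 4, tolerance = 1e-9)

  m <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), nrow = 3)
  dimnames(m) <- list(c("cpd one", "cpd two", "C"), c("cpd one", "cpd two", "C"))
  tree2 <- hierarchical_cluster(stats::as.dist(m))
  export_dendrogram(tree2, path, format = "newick")
  expect_match(readLines(path), "'cpd one'", fixed = TRUE)
})

test_that("CDT/GTR export has the right row arithmetic", {
  withr::with_seed(61, {
    m <- matrix(rbinom(5 * 4, 1, 0.5), nrow = 5,
                dimnames = list(sprintf("c%d", 1:5), NULL))
    colnames(m) <- pharmint:::synthetic_group_labels(2)
  })
  prof <- profile_from_matrix(m)
  tree <- hierarchical_cluster(profile_distance(prof))
  base <- withr::local_tempfile()
  paths <- export_dendrogram(tree, paste0(base, ".cdt"), format = "cdt_gtr",
                             data = prof$matrix)
  cdt <- readLines(paths[1]); gtr <- readLines(paths[2])
  expect_equal(length(cdt) - 1, 5)   # header + one row per leaf
  expect_equal(length(gtr), 4)       # n - 1 merges
  expect_match(cdt[1], "^GID\tNAME\tGWEIGHT")
})

test_that("cluster representatives take the best combined score", {
  clusters <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
                             cluster = c(1, 1, 2, 2))
  scores <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
                           combined = c(-5, -9, -2, -2))
  reps <- select_representatives(clusters, scores)
  expect_equal(reps$compound_id[reps$is_representative], c("b", "c"))
})
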