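# Independent oracle for the matrix-shuffle null: under a uniform
# permutation of all N*2K cells, the number of ones landing in one column
# is hypergeometric (draws = N cells out of T = N*2K containing M ones).
hyper_mu_sigma <- function(n_rows, n_cols, n_ones) {
  t_cells <- n_rows * n_cols
  mu_count <- n_rows * n_ones / t_cells
  var_count <- n_rows * (n_ones / t_cells) * (1 - n_ones / t_cells) *
    (t_cells - n_rows) / (t_cells - 1)
  list(mu = mu_count / n_rows, sigma = sqrt(var_count) / n_rows)
}

test_that("shuffle null matches the hypergeometric closed form", {
  n_sh <- 10000
  cases <- list(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), nrow = 4))  # 4x2, 4 ones
  withr::with_seed(101, cases[[2]] <- matrix(rbinom(24, 1, 0.3), nrow = 6))
  for (m in cases) {
    prof <- profile_from_matrix(m)
    null <- shuffle_null(prof, n_shuffles = n_sh, seed = 7)
    oracle <- hyper_mu_sigma(nrow(m), ncol(m), sum(m))
    se_mu <- oracle$sigma / sqrt(n_sh)
    se_sigma <- oracle$sigma / sqrt(2 * n_sh)
    expect_true(all(abs(null$mu - oracle$mu) < 3 * se_mu))
    expect_true(all(abs(null$sigma - oracle$sigma) < 3 * se_sigma))
  }
})

test_that("shuffle null is seeded, reproducible, and conserves ones", {
  withr::with_seed(3, m <- matrix(rbinom(40, 1, 0.4), nrow = 8))
  prof <- profile_from_matrix(m)
  n1 <- shuffle_null(prof, n_shuffles = 50, seed = 12)
  n2 <- shuffle_null(prof, n_shuffles = 50, seed = 12)
  expect_equal(n1$mu, n2$mu)
  expect_equal(n1$sigma, n2$sigma)
  # total ones conserved per shuffle => mean of column sums = M / 2K exactly
  expect_equal(sum(n1$mu) * nrow(m), sum(m), tolerance = 1e-12)
})

test_that("degenerate profiles give zero-variance nulls with a warning", {
  zeros <- profile_from_matrix(matrix(0L, 4, 4))
  expect_warning(null <- shuffle_null(zeros, n_shuffles = 10), "degenerate")
  expect_true(all(null$mu == 0))
  expect_true(all(null$sigma == 0))
})

test_that("preferences match an independent brute-force recomputation", {
  # oracle coded with explicit loops and its own shuffling, sharing no code
  # with the implementation
  withr::with_seed(23, m <- matrix(rbinom(24, 1, 0.35), nrow = 6))
  m[, 2] <- c(1, 1, 1, 1, 1, 0)  # one clearly conserved column
  n_sh <- 10000
  prof <- profile_from_matrix(m)
  prefs <- compute_preferences(prof, shuffle_null(prof, n_shuffles = n_sh,
                                                  seed = 31))

  f_obs <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, j]
    f_obs[j] <- s / nrow(m)
  }
  freq <- matrix(0, n_sh, ncol(m))
  withr::with_seed(97, {
    for (s in seq_len(n_sh)) {
      shuffled <- matrix(sample(as.vector(m)), nrow = nrow(m))
      for (j in seq_len(ncol(m))) {
        freq[s, j] <- sum(shuffled[, j]) / nrow(m)
      }
    }
  })
  mu_o <- colMeans(freq); sd_o <- apply(freq, 2, sd)
  z_o <- (f_obs - mu_o) / sd_o
  w_o <- z_o / max(z_o)

  # MC tolerance: 3 SE on mu propagated through z and w
  se_z <- 3 * (1 / sqrt(n_sh) + abs(z_o) / sqrt(2 * n_sh))
  expect_true(all(abs(prefs$z - z_o) < se_z + 1e-9))
  expect_true(all(abs(prefs$w - w_o) < 0.05))
  # the z_max column scores exactly 1
  expect_equal(max(prefs$w), 1.0)
  expect_equal(which.max(prefs$w), which.max(z_o))
})

test_that("z is increasing in f (fixed mu, sigma) and W ordering follows z", {
  withr::with_seed(41, m <- matrix(rbinom(80, 1, 0.3), nrow = 10))
  prof <- profile_from_matrix(m)
  null <- tibble::tibble(group = colnames(prof$matrix), mu = 0.3,
                         sigma = 0.05)
  prefs <- compute_preferences(prof, null)
  expect_true(all(diff(prefs$z[order(prefs$f)]) >= 0))
  expect_equal(order(prefs$z), order(prefs$w))
})

test_that("duplicating every row leaves column frequencies unchanged", {
  withr::with_seed(43, m <- matrix(rbinom(30, 1, 0.4), nrow = 5))
  rownames(m) <- sprintf("c%d", 1:5)
  doubled <- rbind(m, m)
  rownames(doubled) <- sprintf("c%d", 1:10)
  f1 <- colMeans(profile_from_matrix(m)$matrix)
  f2 <- colMeans(profile_from_matrix(doubled)$matrix)
  expect_equal(unname(f1), unname(f2))
})

test_that("the pharmacological call boundary is inclusive at 0.4", {
  prefs <- tibble::tibble(w = c(0.40, 0.39, 1.0, 0))
  called <- call_pharmacological(prefs)
  expect_equal(called$call, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("consensus ratios and the inclusive hot-spot boundary", {
  m <- rbind(rep(1, 4), rep(c(1, 0), 2), c(1, 1, 0, 0), c(1, 0, 0, 0))
  m <- m[rep(1:4, length.out = 10), ]  # 10 actives
  rownames(m) <- sprintf("act%02d", 1:10)
  cons <- consensus_ratio(profile_from_matrix(m, "V"))
  expect_equal(nrow(cons), 4)
  expect_true(all(cons$ratio >= 0 & cons$ratio <= 1))
  expect_equal(cons$hot_spot, cons$ratio >= 0.5)
  # exact 0.5 is a hot spot
  m2 <- matrix(c(1, 1, 0, 0), ncol = 1,
               dimnames = list(sprintf("a%d", 1:4), "A:SER1:S"))
  expect_true(consensus_ratio(profile_from_matrix(m2))$hot_spot)
})

test_that("row-shuffle scheme conserves per-row counts in expectation", {
  withr::with_seed(51, m <- matrix(rbinom(60, 1, 0.3), nrow = 10))
  prof <- profile_from_matrix(m)
  null <- shuffle_null(prof, n_shuffles = 500, seed = 9, scheme = "rows")
  expect_equal(sum(null$mu) * nrow(m), sum(m), tolerance = 1e-12)
})
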