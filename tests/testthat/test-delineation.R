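test_that("alpha-cut labelling handles uniform grids", {
  ps <- alpha_cut_patches(matrix(0.8, 5, 5), 0.5)
  expect_identical(nrow(ps$patches), 1L)
  expect_identical(ps$patches$n_cells, 25L)
  ps0 <- alpha_cut_patches(matrix(0.4, 5, 5), 0.5)
  expect_identical(nrow(ps0$patches), 0L)
  expect_true(all(ps0$labels == 0L))
})

test_that("diagonal contact joins patches under queen connectivity", {
  m <- matrix(0, 6, 6)
  m[2:3, 2:3] <- 0.9
  m[4:5, 4:5] <- 0.9
  ps <- alpha_cut_patches(m, 0.5)
  expect_identical(nrow(ps$patches), 1L)
})

test_that("labelling agrees with a flood-fill oracle on random grids", {
  withr::with_seed(31, {
    for (i in 1:10) {
      m <- matrix(runif(15 * 15), 15, 15)
      ps <- alpha_cut_patches(m, 0.6)
      ref <- ref_flood_fill(m >= 0.6)
      expect_identical(max(ps$labels), max(ref))
      # identical partitions up to label permutation
      if (max(ref) > 0) {
        cross <- table(ps$labels[ps$labels > 0], ref[ref > 0])
        expect_true(all(rowSums(cross > 0) == 1))
        expect_true(all(colSums(cross > 0) == 1))
      }
    }
  })
})

test_that("pHab is the plain membership sum and scales to amount by cell area", {
  m <- matrix(c(0.6, 0.7, 0.8, 0.1), 2)
  expect_equal(patch_habitat(m, 1:3), 2.1)
  # crisp limit: n cells at membership 1 give pHab = n, amount = n * A
  ps <- alpha_cut_patches(matrix(1, 4, 3), 0.5, cell_size = 2)
  expect_equal(ps$patches$phab, 12)
  expect_equal(ps$patches$amount, 48)
})

test_that("per-patch pHab sums match the labels they cover", {
  withr::with_seed(17, {
    m <- matrix(runif(12 * 12), 12, 12)
    ps <- alpha_cut_patches(m, 0.5)
    for (p in ps$patches$patch) {
      expect_equal(ps$patches$phab[p], sum(m[ps$labels == p]))
      expect_lte(ps$patches$phab[p], ps$patches$n_cells[p])
    }
    expect_equal(sum(ps$patches$phab), total_phab(m, 0.5))
  })
})

test_that("centroids are snapped to member cells", {
  # C-shaped patch whose geometric centroid falls outside the patch
  m <- matrix(0, 7, 7)
  m[2:6, 2] <- 1; m[2, 2:6] <- 1; m[6, 2:6] <- 1
  ps <- alpha_cut_patches(m, 0.5)
  expect_identical(nrow(ps$patches), 1L)
  expect_identical(ps$labels[ps$patches$centroid_row, ps$patches$centroid_col], 1L)
})

test_that("raising the alpha-cut never increases labelled cells or pHab", {
  withr::with_seed(23, {
    m <- matrix(runif(20 * 20), 20, 20)
    alphas <- c(0.2, 0.4, 0.6, 0.8)
    cells <- numeric(); ph <- numeric()
    for (a in alphas) {
      ps <- alpha_cut_patches(m, a)
      cells <- c(cells, sum(ps$patches$n_cells))
      ph <- c(ph, sum(ps$patches$phab))
    }
    expect_true(all(diff(cells) <= 0))
    expect_true(all(diff(ph) <= 0))
  })
})

test_that("habitat suitability contracts memberships with the H weights", {
  h_w <- c(0.9, 0.1, 0, 0)
  mk <- function(v) realization(array(v, dim = c(1, 1, 4)), letters[1:4], 1)
  expect_equal(habitat_suitability(mk(c(1, 0, 0, 0)), h_w)[1, 1], 0.9)
  expect_equal(habitat_suitability(mk(c(0.8, 0.2, 0, 0)), h_w)[1, 1], 0.74)
  expect_equal(habitat_suitability(mk(c(0, 0, 0.5, 0.5)), h_w)[1, 1], 0)
  expect_error(habitat_suitability(mk(c(1, 0, 0, 0)), c(1, 0)), "classes")
})

test_that("core frequency is exact for zero-variance cells and calibrated for Beta(1,1)", {
  mu <- array(c(0.8, 0.3), dim = c(1, 2, 1))
  st <- class_stack(mu, array(0, dim = dim(mu)), "habitat", 1)
  cf <- core_frequency(st, n_iter = 10, alpha_cut = 0.5, seed = 1)
  expect_equal(cf[1, 1], 1)
  expect_equal(cf[1, 2], 0)

  # Beta(1,1) cell: P(value >= 0.5) = 0.5
  mu2 <- array(0.5, dim = c(1, 1, 1))
  st2 <- class_stack(mu2, array(1 / 12, dim = c(1, 1, 1)), "habitat", 1)
  cf2 <- core_frequency(st2, n_iter = 10000, alpha_cut = 0.5, seed = 2)
  expect_lt(abs(cf2[1, 1] - 0.5), 0.02)
})

test_that("habitat-amount Monte Carlo collapses on crisp landscapes", {
  st <- crisp_stack(block_rows = 3:6, block_cols = 3:7)  # 20 cells, A = 4
  mc <- habitat_amount_mc(st, n_iter = 20, seed = 1)
  expect_equal(unique(mc$values$value), 20 * 4)
  expect_equal(mc$summary$sd, 0)
})
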