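test_that("kernel calibration pins the tail exactly", {
  expect_equal(calibrate_decay(5, 0.01), 0.921034, tolerance = 1e-6)
  ke <- kernel_spec(10, 0.01)
  expect_equal(kernel_value(ke, 0), 1)
  expect_equal(kernel_value(ke, 10), 0.01, tolerance = 1e-9)
  kf <- kernel_spec(100, 0.05, "functional_cost")
  expect_equal(kernel_value(kf, 100), 0.05, tolerance = 1e-9)
  # strictly decreasing in distance
  d <- seq(0, 120, by = 5)
  expect_true(all(diff(kernel_value(kf, d)) < 0))
  expect_error(calibrate_decay(-1, 0.01), "maxD")
  expect_error(calibrate_decay(5, 1.5), "tail_d")
})

test_that("negative effect is zero without deleterious membership", {
  st <- random_stack(2, nr = 6, nc = 6)
  r <- sample_realization(st, seed = 1)
  ke <- kernel_spec(3, 0.01)
  expect_equal(negative_effect(r, character(0), ke), matrix(0, 6, 6))
  m <- r$membership; m[, , 4] <- 0
  m <- m / array(apply(m, c(1, 2), sum), dim = dim(m))
  r0 <- realization(m, r$class_labels, r$cell_size)
  expect_equal(negative_effect(r0, "urban", ke), matrix(0, 6, 6))
})

test_that("a lone deleterious neighbour at maxD contributes the kernel tail", {
  m <- array(0, dim = c(1, 6, 2)); m[, , 1] <- 1
  m[1, 6, 1] <- 0; m[1, 6, 2] <- 1   # urban cell 5 units right of cell 1
  r <- realization(m, c("habitat", "urban"), 1)
  ke <- kernel_spec(5, 0.01)
  nn <- negative_effect(r, "urban", ke)
  expect_equal(nn[1, 1], 0.01, tolerance = 1e-9)
})

test_that("negative effect and functional cost match exhaustive-pair oracles", {
  st <- random_stack(9, nr = 7, nc = 7)
  r <- sample_realization(st, seed = 4)
  ke <- kernel_spec(5, 0.01)  # maxD 5 map units = 5 cells at cell_size 1
  nn <- negative_effect(r, "urban", ke)
  ref <- ref_nneg(r$membership, 4, ke$decay_alpha, 5)
  expect_lt(max(abs(nn - ref)), 1e-10)

  rr <- c(1, 5, 8, 10)
  fc <- functional_cost(r, rr, "urban", ke)
  ref_fc <- ref_functional_cost(r$membership, rr, 4, ke$decay_alpha, 5)
  expect_lt(max(abs(fc - ref_fc)), 1e-10)
  expect_true(all(fc >= weighted_cost(r, rr) - 1e-12))
})

test_that("adding deleterious membership never decreases nNeg or functional cost", {
  st <- random_stack(12, nr = 7, nc = 7)
  r <- sample_realization(st, seed = 2)
  ke <- kernel_spec(4, 0.01)
  nn1 <- negative_effect(r, "urban", ke)
  fc1 <- functional_cost(r, c(1, 5, 8, 10), "urban", ke)
  m2 <- r$membership
  m2[4, 4, 4] <- min(1, m2[4, 4, 4] + 0.3)  # bump one neighbour's urban share
  r2 <- realization(m2, r$class_labels, r$cell_size)
  nn2 <- negative_effect(r2, "urban", ke)
  fc2 <- functional_cost(r2, c(1, 5, 8, 10), "urban", ke)
  expect_true(all(nn2 - nn1 >= -1e-12))
  expect_true(all(fc2 - fc1 >= -1e-12))
})

test_that("foraging suitability contracts memberships with the F weights", {
  f_w <- c(0.8, 0.5, 0.3, 0.2)
  mk <- function(v) realization(array(v, dim = c(1, 1, 4)), letters[1:4], 1)
  expect_equal(forage_suitability(mk(c(1, 0, 0, 0)), f_w)[1, 1], 0.8)
  expect_equal(forage_suitability(mk(c(0, 0, 0, 1)), f_w)[1, 1], 0.2)
  expect_equal(forage_suitability(mk(rep(0.25, 4)), f_w)[1, 1], 0.45)
})

test_that("positive effect matches a Dijkstra-plus-sum oracle", {
  withr::with_seed(44, {
    forage <- matrix(runif(81, 0.1, 0.9), 9, 9)
    habitat <- matrix(runif(81), 9, 9)
    cost <- matrix(1, 9, 9)
    kf <- kernel_spec(4, 0.05, "functional_cost")
    np <- positive_effect(forage, habitat, cost, kf, cell_size = 1)
    ref <- ref_npos(forage, habitat, cost, kf$decay_alpha, 4)
    expect_lt(max(abs(np - ref)), 1e-10)
    # and on a heterogeneous cost surface
    cost2 <- matrix(runif(81, 0.5, 3), 9, 9)
    np2 <- positive_effect(forage, habitat, cost2, kf, cell_size = 1)
    ref2 <- ref_npos(forage, habitat, cost2, kf$decay_alpha, 4)
    expect_lt(max(abs(np2 - ref2)), 1e-10)
  })
})

test_that("positive effect is a bounded mean and zero off habitat", {
  forage <- matrix(0.6, 9, 9)
  habitat <- matrix(0, 9, 9); habitat[5, 5] <- 1
  kf <- kernel_spec(3, 0.05, "functional_cost")
  np <- positive_effect(forage, habitat, matrix(1, 9, 9), kf)
  expect_lte(np[5, 5], 0.6)       # mean of kernel-damped forage <= forage
  expect_gt(np[5, 5], 0)
  expect_equal(sum(np != 0), 1L)  # non-habitat cells stay zero
})

test_that("functional habitat combines, clips and degenerates correctly", {
  h <- matrix(c(0.6, 0.3, 0.9), 1)
  fh <- functional_habitat(h, matrix(c(0.2, 0, 0.4), 1),
                           matrix(c(0.1, 0.5, 0), 1))
  expect_equal(as.vector(fh), c(0.7, 0, 1))
  expect_equal(as.vector(attr(fh, "unclipped")), c(0.7, -0.2, 1.3))
  # all-zero neighbourhood terms reproduce the habitat surface bit-for-bit
  st <- random_stack(6)
  hab <- habitat_suitability(sample_realization(st, seed = 3),
                             c(0.9, 0.1, 0, 0))
  expect_identical(functional_habitat(hab)[, ], hab)
})
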