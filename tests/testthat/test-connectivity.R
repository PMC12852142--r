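# a patch_graph with prescribed direct-move probabilities, bypassing the
# raster stage, for testing the graph algebra in isolation
toy_graph <- function(p, weights = rep(1, nrow(p))) {
  structure(list(
    nodes = tibble::tibble(patch = seq_len(nrow(p)), phab = weights,
                           weight = weights),
    cd = -log(p), p = p, paths = NULL, alpha_disp = 1),
    class = "patch_graph")
}

test_that("dispersal probabilities follow the calibrated exponential", {
  prof <- species_profile(dispersal_distance = 200, dispersal_tail = 0.05)
  a_disp <- -log(0.05) / 200
  # cd equal to the dispersal distance gives exactly the tail probability
  expect_equal(exp(-a_disp * 200), 0.05, tolerance = 1e-12)
  # three-patch fixture: probabilities are hand-evaluated exponentials
  st <- crisp_stack(nr = 12, nc = 18, block_rows = 2:4, block_cols = 2:4)
  st$membership[2:4, 8:10, 1] <- 1; st$membership[2:4, 8:10, 2] <- 0
  st$membership[9:11, 14:16, 1] <- 1; st$membership[9:11, 14:16, 2] <- 0
  prof2 <- two_class_profile()
  ps <- alpha_cut_patches(st$membership[, , 1], 0.5, st$cell_size)
  expect_identical(nrow(ps$patches), 3L)
  cost <- weighted_cost(boolean_realization(st), prof2$R)
  pg <- build_patch_graph(ps, cost, prof2, st$cell_size)
  a2 <- -log(prof2$dispersal_tail) / prof2$dispersal_distance
  expect_equal(pg$p, exp(-a2 * pg$cd), tolerance = 1e-12)
  expect_equal(diag(pg$p), rep(1, 3))
})

test_that("max-product probabilities agree with hand-worked cases", {
  expect_equal(max_product_probability(toy_graph(rbind(c(1, 0.3), c(0.3, 1)))),
               rbind(c(1, 0.3), c(0.3, 1)))
  # chain a-b-c beats the weak direct edge: max(0.2, 0.5 * 0.5) = 0.25
  p <- rbind(c(1, 0.5, 0.2), c(0.5, 1, 0.5), c(0.2, 0.5, 1))
  ps <- max_product_probability(toy_graph(p))
  expect_equal(ps[1, 3], 0.25)
  expect_equal(ps[1, 2], 0.5)
})

test_that("max-product equals exhaustive path enumeration on random graphs", {
  withr::with_seed(13, {
    for (i in 1:5) {
      n <- 6
      p <- matrix(0, n, n)
      up <- upper.tri(p)
      vals <- runif(sum(up))
      vals[runif(sum(up)) < 0.3] <- 0   # drop some edges entirely
      p[up] <- vals; p <- p + t(p); diag(p) <- 1
      got <- max_product_probability(toy_graph(p))
      ref <- ref_max_product(p)
      expect_equal(got, ref, tolerance = 1e-12)
      expect_true(all(got >= p - 1e-12))       # never below the direct edge
      expect_equal(got, t(got))                # symmetric
    }
  })
})

test_that("the reachability metric reduces algebraically on small graphs", {
  a_l <- 400
  # single patch: 100 * h / A_L
  g1 <- toy_graph(matrix(1, 1, 1), weights = 37)
  expect_equal(rfh(g1, a_l), 100 * 37 / a_l)
  # two equal patches with P*_12 = p: 100 * h * sqrt(2 + 2p) / A_L
  p <- 0.4; h <- 21
  g2 <- toy_graph(rbind(c(1, p), c(p, 1)), weights = c(h, h))
  expect_equal(rfh(g2, a_l), 100 * h * sqrt(2 + 2 * p) / a_l)
  # fully disconnected: sqrt of sum of squares, below the full-connection sum
  g3 <- toy_graph(diag(1, 3), weights = c(5, 12, 8))
  expect_equal(rfh(g3, a_l), 100 * sqrt(5^2 + 12^2 + 8^2) / a_l)
  expect_lt(rfh(g3, a_l), 100 * (5 + 12 + 8) / a_l)
})

test_that("the metric is monotone in probabilities and patch weights", {
  a_l <- 1000
  p1 <- rbind(c(1, 0.2, 0.1), c(0.2, 1, 0.3), c(0.1, 0.3, 1))
  w <- c(10, 20, 15)
  base <- rfh(toy_graph(p1, w), a_l)
  p2 <- p1; p2[1, 2] <- p2[2, 1] <- 0.6
  expect_gt(rfh(toy_graph(p2, w), a_l), base)
  w2 <- w; w2[3] <- 25
  expect_gt(rfh(toy_graph(p1, w2), a_l), base)
})

test_that("crisp landscapes collapse the Monte Carlo to the Boolean baseline", {
  st <- crisp_stack(nr = 12, nc = 16, block_rows = 3:5, block_cols = 3:5)
  st$membership[8:10, 11:13, 1] <- 1; st$membership[8:10, 11:13, 2] <- 0
  prof <- two_class_profile()
  mc <- rfh_monte_carlo(st, prof, n_iter = 5, seed = 9, mode = "rh",
                        target_class = "habitat")
  expect_equal(mc$summary$sd, 0)
  be <- boolean_ehi(st, prof, target_class = "habitat")
  expect_equal(unique(mc$values$value), be$value, tolerance = 1e-12)
  expect_true(be$value > 0 && be$value < 100)
})

test_that("same seed reproduces the distribution; patches from fHab differ from RH", {
  st <- make_four_class(scenario_spec("four_class", grid_rows = 30,
                                      grid_cols = 30, seed = 4))
  prof <- species_profile(maxD_forage = 30, dispersal_distance = 100)
  m1 <- rfh_monte_carlo(st, prof, n_iter = 4, seed = 5, mode = "rfh",
                        collect_density = FALSE)
  m2 <- rfh_monte_carlo(st, prof, n_iter = 4, seed = 5, mode = "rfh",
                        collect_density = FALSE)
  expect_identical(m1$values, m2$values)
  expect_true(all(m1$values$n_patches >= 1))
  expect_true(all(m1$values$value > 0 & m1$values$value < 100))
})

test_that("empty landscapes yield zero reachable habitat", {
  st <- crisp_stack(nr = 8, nc = 8, block_rows = 2:3, block_cols = 2:3)
  st$membership[, , 1] <- 0; st$membership[, , 2] <- 1
  prof <- two_class_profile()
  mc <- rfh_monte_carlo(st, prof, n_iter = 2, seed = 1, mode = "rh",
                        target_class = "habitat")
  expect_equal(mc$values$value, c(0, 0))
  expect_equal(mc$values$n_patches, c(0L, 0L))
})
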