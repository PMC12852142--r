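test_that("weighted cost is a convex combination of resistances", {
  rr <- c(1, 5, 8, 10)
  mk <- function(v) realization(array(v, dim = c(1, 1, 4)), letters[1:4], 1)
  expect_equal(weighted_cost(mk(c(1, 0, 0, 0)), rr)[1, 1], 1)
  expect_equal(weighted_cost(mk(c(0.5, 0.5, 0, 0)), rr)[1, 1], 3)
  st <- random_stack(8)
  wc <- weighted_cost(sample_realization(st, seed = 5), rr)
  expect_true(all(wc >= min(rr) - 1e-12 & wc <= max(rr) + 1e-12))
  expect_error(weighted_cost(sample_realization(st, seed = 5), c(1, 5, -8, 10)),
               "positive")
})

test_that("functional cost reduces to weighted cost without deleterious classes", {
  st <- random_stack(4, nr = 6, nc = 6)
  r <- sample_realization(st, seed = 1)
  ke <- kernel_spec(3, 0.01)
  expect_identical(functional_cost(r, c(1, 5, 8, 10), character(0), ke),
                   weighted_cost(r, c(1, 5, 8, 10)))
})

test_that("least-cost paths on flat surfaces follow straight geometry", {
  flat <- matrix(1, 8, 8)
  lcp <- least_cost_path(flat, c(3, 2), c(3, 7), cell_size = 2)
  expect_equal(lcp$cost, 5 * 2)                 # 5 steps * cell_size
  expect_true(all(lcp$path$row == 3))
  diag_lcp <- least_cost_path(flat, c(1, 1), c(5, 5), cell_size = 2)
  expect_equal(diag_lcp$cost, 4 * sqrt(2) * 2)
})

test_that("least-cost distances match an independent Dijkstra on random surfaces", {
  cost <- random_cost(77, 20, 20)
  src <- c(2, 3); dst <- c(18, 16)
  lcp <- least_cost_path(cost, src, dst, cell_size = 1.5)
  ref <- ref_dijkstra(cost, src, dst, cell_size = 1.5)
  expect_equal(lcp$cost, ref, tolerance = 1e-10)
  # symmetry on the undirected grid
  back <- least_cost_path(cost, dst, src, cell_size = 1.5)
  expect_equal(back$cost, lcp$cost, tolerance = 1e-10)
  # path endpoints and 8-adjacency of consecutive cells
  expect_equal(unlist(lcp$path[1, ]), src, ignore_attr = TRUE)
  expect_equal(unlist(lcp$path[nrow(lcp$path), ]), dst, ignore_attr = TRUE)
  steps <- cbind(diff(lcp$path$row), diff(lcp$path$col))
  expect_true(all(abs(steps) <= 1) && all(rowSums(abs(steps)) >= 1))
})

test_that("cost_distance agrees with the Dijkstra oracle from several sources", {
  cost <- random_cost(5, 10, 10)
  from <- c(1, 35, 78)
  d <- cost_distance(cost, from, seq_len(100), cell_size = 1)
  for (i in seq_along(from)) {
    sr <- ((from[i] - 1) %% 10) + 1; sc <- ((from[i] - 1) %/% 10) + 1
    ref <- ref_dijkstra_all(cost, sr, sc, 1)
    expect_equal(as.vector(d[i, ]), as.vector(ref), tolerance = 1e-10)
  }
})

test_that("non-positive or non-finite cost surfaces are rejected", {
  bad <- matrix(1, 4, 4); bad[2, 2] <- 0
  expect_error(least_cost_path(bad, c(1, 1), c(4, 4)), "positive")
  bad[2, 2] <- Inf
  expect_error(least_cost_path(bad, c(1, 1), c(4, 4)), "positive|finite")
})

test_that("path density counts traversals and degenerates on crisp landscapes", {
  p <- tibble::tibble(row = c(1, 2, 3), col = c(1, 2, 3))
  dens <- path_density(list(p, p, p), c(3, 3))
  expect_equal(diag(dens), c(1, 1, 1))
  expect_equal(sum(dens), 3)

  # zero variance: every Monte-Carlo draw reproduces the single Boolean LCP
  st <- crisp_stack(nr = 10, nc = 14, block_rows = 4:6, block_cols = 2:4)
  st$membership[4:6, 10:12, 1] <- 1
  st$membership[4:6, 10:12, 2] <- 0
  prof <- two_class_profile()
  mc <- rfh_monte_carlo(st, prof, n_iter = 4, seed = 1, mode = "rh",
                        target_class = "habitat")
  expect_true(all(mc$density %in% c(0, 1)))
  crisp <- boolean_realization(st)
  cost <- weighted_cost(crisp, prof$R)
  ps <- alpha_cut_patches(st$membership[, , 1], 0.5, st$cell_size)
  lcp <- least_cost_path(cost,
                         c(ps$patches$centroid_row[1], ps$patches$centroid_col[1]),
                         c(ps$patches$centroid_row[2], ps$patches$centroid_col[2]),
                         st$cell_size)
  ind <- matrix(0, 10, 14); ind[cbind(lcp$path$row, lcp$path$col)] <- 1
  expect_equal(mc$density, ind)
})

test_that("boolean realization is the arg-max one-hot classification", {
  st <- random_stack(21, nr = 5, nc = 5)
  b <- boolean_realization(st)
  flat <- matrix(st$membership, ncol = 4)
  expect_equal(matrix(b$membership, ncol = 4)[cbind(1:25, max.col(flat, "first"))],
               rep(1, 25))
  expect_true(all(rowSums(matrix(b$membership, ncol = 4)) == 1))
})
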