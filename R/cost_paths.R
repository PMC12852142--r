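#' Membership-weighted cost surface
#'
#' The movement cost of a cell is the membership-weighted sum of the class
#' resistance values — a convex combination when memberships sum to one, so
#' every cell cost lies between `min(R)` and `max(R)`.
#'
#' @param real a [realization()].
#' @param resistance numeric vector of per-class resistance values, all
#'   > 0.
#' @return A positive numeric cost matrix.
#' @examples
#' stack <- make_four_class(scenario_spec("four_class"))
#' cost <- weighted_cost(sample_realization(stack, seed = 1), c(1, 5, 8, 10))
#' range(cost)
#' @export
weighted_cost <- function(real, resistance) {
  if (any(!is.finite(resistance)) || any(resistance <= 0)) {
    abort("all resistance values must be positive and finite.")
  }
  contract_classes(real, resistance, "resistance")
}

#' Functional cost surface (edge-inflated movement cost)
#'
#' Adds to the membership-weighted cost the kernel-weighted resistance
#' contributions of deleterious memberships in the Euclidean neighbourhood:
#' movement near (e.g.) urban cover costs more than the same cover
#' composition far from it. The result is everywhere >= the plain
#' [weighted_cost()].
#'
#' @inheritParams weighted_cost
#' @param deleterious class names or indices exerting the effect.
#' @param kernel a [kernel_spec()] with `distance_mode = "euclidean"`
#'   (edge-effect calibration).
#' @param cell_size cell edge length in map units.
#' @return A positive numeric cost matrix.
#' @export
functional_cost <- function(real, resistance, deleterious, kernel,
                            cell_size = real$cell_size) {
  base <- weighted_cost(real, resistance)
  if (length(deleterious) == 0L) return(base)
  stopifnot(inherits(kernel, "kernel_spec"))
  if (kernel$distance_mode != "euclidean") {
    abort("edge-effect kernels use euclidean distance.")
  }
  ci <- vapply(deleterious, function(x) class_index(real, x), integer(1L))
  k <- dim(real$membership)[3L]
  rw <- numeric(k); rw[ci] <- resistance[ci]
  extra <- contract_classes(real, rw, "resistance")  # sum_i in del M_ki * R_i
  base + kernel_window_sum(extra, kernel, cell_size)
}

# 8-connected grid graph over a cost surface; vertex i = cell i
# (column-major). Per-step cost = mean of endpoint cell costs * step length
# (* sqrt(2) on diagonals), so on a unit surface cost distance equals
# Euclidean distance.
grid_graph <- function(cost, cell_size = 1) {
  stopifnot(is.matrix(cost))
  if (any(!is.finite(cost)) || any(cost <= 0)) {
    abort("cost surface must be strictly positive and finite.")
  }
  nr <- nrow(cost); nc <- ncol(cost)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (o in offs) {
    r1 <- max(1L, 1L - o[[1L]]):min(nr, nr - o[[1L]])
    c1 <- max(1L, 1L - o[[2L]]):min(nc, nc - o[[2L]])
    a <- idx[r1, c1, drop = FALSE]
    b <- idx[r1 + o[[1L]], c1 + o[[2L]], drop = FALSE]
    from <- c(from, as.vector(a)); to <- c(to, as.vector(b))
    wt <- c(wt, (cost[a] + cost[b]) / 2 * cell_size * o[[3L]])
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  g
}

#' Least-cost path between two cells
#'
#' Minimal accumulated cost over 8-connected moves, with per-step cost the
#' mean of the two endpoint cell costs times the step length (diagonals
#' scaled by sqrt(2)). On a uniform unit-cost surface the accumulated cost
#' equals the Euclidean path length. Equal-cost ties are broken
#' deterministically by the shortest-path backend given the fixed
#' edge-insertion order, so repeated runs return the same path.
#'
#' @param cost positive cost matrix.
#' @param src,dst cells as `c(row, col)`.
#' @param cell_size cell edge length in map units.
#' @return A list with `path` (tibble of `row`, `col` along the path,
#'   inclusive of endpoints) and `cost` (accumulated cost distance).
#' @examples
#' lcp <- least_cost_path(matrix(1, 5, 5), c(2, 1), c(2, 5))
#' lcp$cost  # 4: straight line on a flat unit surface
#' @export
least_cost_path <- function(cost, src, dst, cell_size = 1) {
  nr <- nrow(cost)
  s <- (src[2L] - 1L) * nr + src[1L]
  d <- (dst[2L] - 1L) * nr + dst[1L]
  if (s == d) abort("`src` and `dst` must differ.")
  g <- grid_graph(cost, cell_size)
  sp <- igraph::shortest_paths(g, from = s, to = d, output = "vpath")
  v <- as.integer(sp$vpath[[1L]])
  if (length(v) == 0L) abort("destination unreachable.")
  cd <- igraph::distances(g, v = s, to = d)[1L, 1L]
  list(path = tibble::tibble(row = ((v - 1L) %% nr) + 1L,
                             col = ((v - 1L) %/% nr) + 1L),
       cost = cd)
}

#' Accumulated cost distances between sets of cells
#'
#' @param cost positive cost matrix.
#' @param from,to integer vectors of cell indices (column-major).
#' @param cell_size cell edge length in map units.
#' @return A `length(from)` x `length(to)` matrix of cost distances.
#' @export
cost_distance <- function(cost, from, to = from, cell_size = 1) {
  g <- grid_graph(cost, cell_size)
  igraph::distances(g, v = from, to = to)
}

#' Path-density surface from an ensemble of least-cost paths
#'
#' For each cell, the fraction of paths in the ensemble that traverse it —
#' the Monte-Carlo analogue of a single deterministic least-cost path. With
#' zero classification uncertainty every draw produces the same path and
#' the density degenerates to that path's 0/1 indicator.
#'
#' @param paths a list of path tibbles (`row`, `col`), e.g. the `path`
#'   elements returned by [least_cost_path()] across iterations.
#' @param dim grid dimensions `c(rows, cols)`.
#' @return A numeric matrix of densities in \[0, 1\].
#' @export
path_density <- function(paths, dim) {
  stopifnot(length(paths) >= 1L)
  acc <- matrix(0, dim[1L], dim[2L])
  for (p in paths) {
    hit <- matrix(FALSE, dim[1L], dim[2L])
    hit[cbind(p$row, p$col)] <- TRUE
    acc <- acc + hit
  }
  acc / length(paths)
}

#' Crisp (Boolean) realization by arg-max classification
#'
#' Hard-classifies each cell to the class with the highest mean membership
#' (one-hot memberships), reproducing the Boolean-landscape baseline
#' workflows: cost per cell becomes the resistance of the winning class and
#' patches become crisp cell sets.
#'
#' @param stack a [class_stack()].
#' @return A [realization()] with one-hot memberships.
#' @export
boolean_realization <- function(stack) {
  stopifnot(inherits(stack, "class_stack"))
  d <- dim(stack$membership)
  flat <- matrix(stack$membership, ncol = d[3L])
  win <- max.col(flat, ties.method = "first")
  m <- matrix(0, nrow(flat), d[3L])
  m[cbind(seq_len(nrow(flat)), win)] <- 1
  realization(array(m, dim = d), stack$class_labels, stack$cell_size)
}
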