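#' Build the probabilistic patch graph
#'
#' Nodes are patches weighted by their fuzzy habitat amount `pHab * A`;
#' every patch pair is connected by the least-cost distance `cd_pq` between
#' the (snapped) patch centroids over the supplied cost surface, converted
#' to a direct-movement probability `p_pq = exp(-alpha_disp * cd_pq)` with
#' `alpha_disp = -log(dispersal_tail) / dispersal_distance` — the same
#' negative-exponential calibration used for the neighbourhood kernels, in
#' the incidence-function tradition.
#'
#' @param patches a [alpha_cut_patches()] `patch_set`.
#' @param cost positive cost matrix on the same grid.
#' @param profile a [species_profile()] (supplies `dispersal_distance` and
#'   `dispersal_tail`).
#' @param cell_size cell edge length in map units.
#' @param graph optional prebuilt grid graph over `cost` (performance).
#' @param collect_paths also record the least-cost-path cell sequences for
#'   every patch pair (for path-density accumulation).
#' @return A `patch_graph`: `nodes` tibble (`patch`, `phab`, `weight`),
#'   matrices `cd` (cost distances) and `p` (direct-move probabilities),
#'   and optionally `paths` (list of `row`/`col` tibbles).
#' @export
build_patch_graph <- function(patches, cost, profile,
                              cell_size = patches$cell_size, graph = NULL,
                              collect_paths = FALSE) {
  stopifnot(inherits(patches, "patch_set"), inherits(profile, "species_profile"))
  tbl <- patches$patches
  n <- nrow(tbl)
  a <- cell_size^2
  nodes <- tibble::tibble(patch = tbl$patch, phab = tbl$phab,
                          weight = tbl$phab * a)
  alpha_disp <- calibrate_decay(profile$dispersal_distance,
                                profile$dispersal_tail)
  cd <- matrix(0, n, n); p <- diag(1, n)
  paths <- list()
  if (n > 1L) {
    nr <- nrow(cost)
    vids <- (tbl$centroid_col - 1L) * nr + tbl$centroid_row
    if (is.null(graph)) graph <- grid_graph(cost, cell_size)
    cd <- igraph::distances(graph, v = vids, to = vids)
    dimnames(cd) <- NULL
    p <- exp(-alpha_disp * cd)
    if (collect_paths) {
      for (i in seq_len(n - 1L)) {
        vp <- igraph::shortest_paths(graph, from = vids[i],
                                     to = vids[(i + 1L):n],
                                     output = "vpath")$vpath
        for (v in vp) {
          v <- as.integer(v)
          paths[[length(paths) + 1L]] <-
            tibble::tibble(row = ((v - 1L) %% nr) + 1L,
                           col = ((v - 1L) %/% nr) + 1L)
        }
      }
    }
  }
  structure(list(nodes = nodes, cd = cd, p = p,
                 paths = if (collect_paths) paths else NULL,
                 alpha_disp = alpha_disp),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d patch(es); total weighted habitat %.4g\n",
              nrow(x$nodes), sum(x$nodes$weight)))
  invisible(x)
}

#' @method tidy patch_graph
#' @export
tidy.patch_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  if (n < 2L) {
    return(tibble::tibble(from = integer(), to = integer(),
                          cost_distance = numeric(), p = numeric()))
  }
  pairs <- which(upper.tri(x$cd), arr.ind = TRUE)
  tibble::tibble(from = x$nodes$patch[pairs[, 1L]],
                 to = x$nodes$patch[pairs[, 2L]],
                 cost_distance = x$cd[pairs], p = x$p[pairs])
}

#' Maximum-product movement probabilities between patches
#'
#' `P*_pq` is the maximum, over all patch-to-patch routes, of the product of
#' stepwise direct-movement probabilities — computed as a shortest path on
#' `-log(p)` edge weights. `P*_pp = 1`; patch pairs with no positive-
#' probability route get 0. `P*` is symmetric and never below the direct
#' probability `p_pq`.
#'
#' @param graph a [build_patch_graph()] `patch_graph`.
#' @return The `P*` matrix.
#' @examples
#' # chain a-b-c beats a weak direct edge: P*_ac = max(0.2, 0.5 * 0.5)
#' @export
max_product_probability <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  p <- graph$p
  n <- nrow(p)
  if (n == 1L) return(matrix(1, 1L, 1L))
  idx <- which(upper.tri(p) & p > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- -log(p[idx])
  }
  d <- igraph::distances(g)
  pstar <- exp(-d)            # Inf distance -> 0
  diag(pstar) <- 1
  dimnames(pstar) <- NULL
  pstar
}

#' Reachable (functional) habitat metric
#'
#' The connectivity-weighted habitat total, as a percentage of landscape
#' area:
#' `RFH = 100 * sqrt(sum_p sum_q w_p * w_q * P*_pq) / A_L`
#' with `w_p = pHab_p * A` and the double sum running over ordered pairs
#' including `p = q` (`P*_pp = 1`). With a single patch this reduces to
#' `100 * w / A_L`; disconnection can only shrink it, reachability only
#' grow it.
#'
#' @param graph a [build_patch_graph()] `patch_graph` (empty graphs give 0).
#' @param A_L landscape area in squared map units.
#' @param pstar optionally, a precomputed [max_product_probability()]
#'   matrix.
#' @return The metric value (percent).
#' @export
rfh <- function(graph, A_L, pstar = NULL) {
  stopifnot(inherits(graph, "patch_graph"), A_L > 0)
  w <- graph$nodes$weight
  if (length(w) == 0L) return(0)
  if (is.null(pstar)) pstar <- max_product_probability(graph)
  100 * sqrt(drop(t(w) %*% pstar %*% w)) / A_L
}

#' Monte-Carlo distribution of reachable (functional) habitat
#'
#' Propagates classification uncertainty into the connectivity metric. Per
#' iteration: draw a realization, build the iteration's cost surface and
#' habitat surface, alpha-cut it into patches, assemble the patch graph and
#' evaluate [rfh()].
#'
#' Two modes:
#' * `"rfh"` — full functional habitat: functional cost (edge-inflated),
#'   multivariate `habitat_c`, negative and positive neighbourhood effects,
#'   alpha-cut on the clipped `fHab` surface, patch weights from `fHab`.
#' * `"rh"` — reachable habitat baseline: a single class's membership
#'   surface, plain membership-weighted cost, no neighbourhood effects.
#'
#' @param stack a [class_stack()].
#' @param profile a [species_profile()] matching the stack's classes.
#' @param n_iter number of Monte-Carlo iterations.
#' @param seed integer root seed; per-iteration sub-seeds are derived
#'   deterministically.
#' @param mode `"rfh"` or `"rh"`.
#' @param target_class class whose membership defines habitat in `"rh"`
#'   mode (default `"woodland"` if present, else the first class).
#' @param collect_density accumulate the pooled least-cost-path density
#'   surface across iterations (default `TRUE`).
#' @return An `fh_mc` with per-iteration `value` (percent) and `n_patches`;
#'   the pooled `density` matrix when requested.
#' @examples
#' stack <- make_four_class(scenario_spec("four_class", grid_rows = 30,
#'                                        grid_cols = 30))
#' mc <- rfh_monte_carlo(stack, species_profile(), n_iter = 5, seed = 1,
#'                       mode = "rh")
#' glance(mc)
#' @export
rfh_monte_carlo <- function(stack, profile, n_iter = 1000L, seed = 1L,
                            mode = c("rfh", "rh"), target_class = NULL,
                            collect_density = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "class_stack"), inherits(profile, "species_profile"),
            n_iter >= 1L)
  if (length(profile$class_labels) != n_classes(stack)) {
    abort("profile and stack disagree on the number of classes.")
  }
  if (is.null(target_class)) {
    target_class <- if ("woodland" %in% stack$class_labels) "woodland"
                    else stack$class_labels[1L]
  }
  bs <- beta_surface(stack)
  seeds <- iteration_seeds(seed, n_iter)
  a_l <- landscape_area(stack)
  vals <- numeric(n_iter); npat <- integer(n_iter)
  all_paths <- list()
  for (i in seq_len(n_iter)) {
    real <- sample_realization(bs, seed = seeds[i])
    it <- rfh_iteration(real, profile, mode, target_class, collect_density)
    vals[i] <- if (is.null(it$graph)) 0 else rfh(it$graph, a_l)
    npat[i] <- it$n_patches
    if (collect_density && length(it$paths)) {
      all_paths <- c(all_paths, it$paths)
    }
  }
  dens <- if (collect_density && length(all_paths)) {
    path_density(all_paths, dim(stack$membership)[1:2])
  } else NULL
  new_fh_mc(
    tibble::tibble(iteration = seq_len(n_iter), value = vals,
                   n_patches = npat),
    metric = if (mode == "rfh") "reachable_functional_habitat"
             else "reachable_habitat",
    units = "percent",
    extra = list(density = dens, mode = mode))
}

# one Monte-Carlo iteration: habitat surface + cost surface -> patch graph
rfh_iteration <- function(real, profile, mode, target_class, collect_paths) {
  alpha <- profile$alpha_cut
  cs <- real$cell_size
  if (mode == "rh") {
    values <- real$membership[, , class_index(real, target_class)]
    cost <- weighted_cost(real, profile$R)
  } else {
    edge_k <- kernel_spec(profile$maxD_edge, profile$d_edge, "euclidean")
    forage_k <- kernel_spec(profile$maxD_forage, profile$d_forage,
                            "functional_cost")
    cost <- functional_cost(real, profile$R, profile$deleterious, edge_k, cs)
    hab <- habitat_suitability(real, profile$H)
    nneg <- negative_effect(real, profile$deleterious, edge_k, cs)
    forage <- forage_suitability(real, profile$F_)
    npos <- positive_effect(forage, hab, cost, forage_k, cs, alpha)
    values <- functional_habitat(hab, npos, nneg)
  }
  ps <- alpha_cut_patches(values, alpha, cs)
  if (nrow(ps$patches) == 0L) {
    return(list(graph = NULL, n_patches = 0L, paths = NULL))
  }
  pg <- build_patch_graph(ps, cost, profile, cs, collect_paths = collect_paths)
  list(graph = pg, n_patches = nrow(ps$patches), paths = pg$paths)
}

#' Boolean connectivity baseline (crisp patches, no neighbourhood effects)
#'
#' The comparison workflow on the hard-classified landscape: cells take the
#' class with the highest mean membership, patches are queen-connected cells
#' of the target class weighted by crisp area (`n_cells * A`), cost is the
#' winning class's resistance, and the same max-product patch-graph metric
#' is evaluated. There is no stochasticity: the result is a single value.
#'
#' @param stack a [class_stack()].
#' @param profile a [species_profile()].
#' @param target_class habitat class (default `"woodland"` if present).
#' @return A list with `value` (percent), the `patch_set`, the
#'   `patch_graph` and the crisp `cost` matrix.
#' @export
boolean_ehi <- function(stack, profile, target_class = NULL) {
  stopifnot(inherits(stack, "class_stack"), inherits(profile, "species_profile"))
  if (is.null(target_class)) {
    target_class <- if ("woodland" %in% stack$class_labels) "woodland"
                    else stack$class_labels[1L]
  }
  crisp <- boolean_realization(stack)
  values <- crisp$membership[, , class_index(crisp, target_class)]
  cost <- weighted_cost(crisp, profile$R)
  ps <- alpha_cut_patches(values, profile$alpha_cut, stack$cell_size)
  if (nrow(ps$patches) == 0L) {
    return(list(value = 0, patches = ps, graph = NULL, cost = cost))
  }
  pg <- build_patch_graph(ps, cost, profile, stack$cell_size)
  list(value = rfh(pg, landscape_area(stack)), patches = ps, graph = pg,
       cost = cost)
}
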