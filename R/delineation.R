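#' Delineate patches by an alpha-cut with queen connectivity
#'
#' Cells whose value meets the threshold (`value >= alpha_cut`) are grouped
#' into maximal 8-connected (queen neighbourhood) components. Each patch
#' records its cell count, the sum of member-cell values (`phab`), the
#' habitat amount `phab * cell_size^2`, and a centroid (mean of member-cell
#' centers, snapped to the nearest member cell when it falls outside the
#' patch, so it can serve as a least-cost-path endpoint).
#'
#' @param values numeric matrix of per-cell values in \[0, 1\] (a single
#'   class's membership, or a functional-habitat surface).
#' @param alpha_cut threshold in (0, 1); cells with `value >= alpha_cut`
#'   are included. Default 0.5.
#' @param cell_size cell edge length in map units (default 1).
#' @return A `patch_set`: list with the integer `labels` matrix (0 =
#'   background) and a `patches` tibble (`patch`, `n_cells`, `phab`,
#'   `amount`, `centroid_row`, `centroid_col`).
#' @examples
#' m <- matrix(0, 5, 5); m[2:3, 2:3] <- 0.9
#' alpha_cut_patches(m, 0.5)
#' @export
alpha_cut_patches <- function(values, alpha_cut = 0.5, cell_size = 1) {
  stopifnot(is.matrix(values))
  nr <- nrow(values); nc <- ncol(values)
  keep <- which(values >= alpha_cut)
  labels <- matrix(0L, nr, nc)
  if (length(keep) == 0L) {
    return(new_patch_set(labels, empty_patch_tbl(), alpha_cut, cell_size))
  }
  sel <- logical(nr * nc); sel[keep] <- TRUE
  vid <- integer(nr * nc); vid[keep] <- seq_along(keep)  # cell -> graph vertex
  # queen adjacency: four unique undirected offsets
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  edges <- list()
  rows <- ((keep - 1L) %% nr) + 1L
  cols <- ((keep - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- rows + o[1L]; c2 <- cols + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- sel[nb]
    edges[[length(edges) + 1L]] <- cbind(vid[keep[ok][ok2]], vid[nb[ok2]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- as.integer(igraph::components(g)$membership)
  labels[keep] <- comp
  patches <- tibble::tibble(
    patch = seq_len(max(comp)),
    n_cells = tabulate(comp)) |>
    dplyr::mutate(
      phab = as.numeric(tapply(values[keep], comp, sum)),
      amount = .data$phab * cell_size^2)
  cen <- patch_centroids(labels, patches$patch)
  patches$centroid_row <- cen$row
  patches$centroid_col <- cen$col
  new_patch_set(labels, patches, alpha_cut, cell_size)
}

new_patch_set <- function(labels, patches, alpha_cut, cell_size) {
  structure(list(labels = labels, patches = patches,
                 alpha_cut = alpha_cut, cell_size = cell_size),
            class = "patch_set")
}

empty_patch_tbl <- function() {
  tibble::tibble(patch = integer(), n_cells = integer(), phab = numeric(),
                 amount = numeric(), centroid_row = integer(),
                 centroid_col = integer())
}

# mean of member-cell centers, snapped to the nearest member cell
patch_centroids <- function(labels, ids) {
  nr <- nrow(labels)
  out_r <- integer(length(ids)); out_c <- integer(length(ids))
  for (i in seq_along(ids)) {
    cells <- which(labels == ids[i])
    r <- ((cells - 1L) %% nr) + 1L
    cc <- ((cells - 1L) %/% nr) + 1L
    mr <- mean(r); mc <- mean(cc)
    j <- which.min((r - mr)^2 + (cc - mc)^2)
    out_r[i] <- r[j]; out_c[i] <- cc[j]
  }
  list(row = out_r, col = out_c)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patch(es) at alpha-cut %g on a %d x %d grid\n",
              nrow(x$patches), x$alpha_cut, nrow(x$labels), ncol(x$labels)))
  print(x$patches, n = 5)
  invisible(x)
}

#' @method tidy patch_set
#' @export
tidy.patch_set <- function(x, ...) x$patches

#' Fuzzy habitat content of a set of cells
#'
#' `patch_habitat()` sums the membership values of the given cells (the
#' type-1 fuzzy habitat content `pHab`); multiplying by the cell area gives
#' the habitat amount in squared map units. `total_phab()` sums membership
#' over *all* cells meeting the alpha-cut, the quantity tracked per
#' Monte-Carlo iteration (components may split or merge across draws, so
#' the landscape-wide sum is the stable summary).
#'
#' @param values numeric membership matrix.
#' @param cells integer vector of cell indices (column-major), e.g.
#'   `which(patch_set$labels == id)`.
#' @param alpha_cut inclusion threshold for `total_phab()`.
#' @return A single number (membership sum).
#' @examples
#' m <- matrix(c(0.6, 0.7, 0.8, 0.1), 2)
#' patch_habitat(m, 1:3)  # 2.1
#' @export
patch_habitat <- function(values, cells) {
  stopifnot(is.matrix(values), all(cells >= 1L), all(cells <= length(values)))
  sum(values[cells])
}

#' @rdname patch_habitat
#' @export
total_phab <- function(values, alpha_cut = 0.5) {
  sum(values[values >= alpha_cut])
}

#' Multivariate habitat suitability surface
#'
#' `habitat_suitability()` computes the per-cell habitat value as the
#' membership-weighted sum of class habitat-suitability weights `H`
#' (a convex combination when memberships sum to one, hence in \[0, 1\]).
#' `forage_suitability()` is the same contraction with foraging weights `F`.
#'
#' @param real a [realization()] (or `class_stack`, in which case the mean
#'   membership is used).
#' @param weights numeric vector of per-class weights in \[0, 1\], one per
#'   class of `real`.
#' @return A numeric matrix (rows x cols).
#' @examples
#' stack <- make_four_class(scenario_spec("four_class"))
#' h <- habitat_suitability(sample_realization(stack, seed = 1),
#'                          c(0.9, 0.1, 0, 0))
#' range(h)
#' @export
habitat_suitability <- function(real, weights) {
  contract_classes(real, weights, "habitat suitability")
}

#' @rdname habitat_suitability
#' @export
forage_suitability <- function(real, weights) {
  contract_classes(real, weights, "foraging suitability")
}

contract_classes <- function(real, weights, what) {
  m <- real$membership
  k <- dim(m)[3L]
  if (length(weights) != k) {
    abort(sprintf("%s weights have length %d but the landscape has %d classes.",
                  what, length(weights), k))
  }
  d <- dim(m)
  matrix(matrix(m, ncol = k) %*% weights, d[1L], d[2L])
}

#' Core-frequency surface from Monte-Carlo realizations
#'
#' For each cell, the proportion of Monte-Carlo realizations in which the
#' cell's value meets the alpha-cut — a continuous core-to-edge gradient: 1
#' where the threshold is met in every draw (patch interior), 0 where it
#' never is (exterior), intermediate through the transition zone.
#'
#' @param stack a [class_stack()].
#' @param extract function mapping a [realization()] to a numeric matrix
#'   (default: the first class's membership).
#' @param n_iter number of Monte-Carlo draws.
#' @param alpha_cut threshold (default 0.5).
#' @param seed integer seed driving all draws.
#' @return A numeric matrix of frequencies in \[0, 1\].
#' @export
core_frequency <- function(stack, extract = function(r) r$membership[, , 1L],
                           n_iter = 1000L, alpha_cut = 0.5, seed = 1L) {
  stopifnot(n_iter >= 1L)
  bs <- beta_surface(stack)
  seeds <- iteration_seeds(seed, n_iter)
  d <- dim(stack$membership)
  acc <- NULL
  for (i in seq_len(n_iter)) {
    v <- extract(sample_realization(bs, seed = seeds[i]))
    if (!is.matrix(v)) v <- matrix(v, d[1L], d[2L])
    hit <- (v >= alpha_cut) + 0
    acc <- if (is.null(acc)) hit else acc + hit
  }
  acc / n_iter
}

# deterministic per-iteration sub-seeds from one root seed, so iteration i
# is reproducible in isolation
iteration_seeds <- function(seed, n_iter) {
  with_local_seed(seed, sample.int(.Machine$integer.max, n_iter))
}

#' Monte-Carlo distribution of habitat amount
#'
#' Repeatedly draws a landscape realization, applies the alpha-cut to one
#' class's membership surface, sums the retained memberships (landscape-wide
#' `pHab`) and multiplies by the cell area. The spread of the resulting
#' distribution reflects the classification uncertainty: low-contrast
#' (ecotone-rich) landscapes give wide distributions, hard-edged ones
#' narrow.
#'
#' @param stack a [class_stack()].
#' @param class class name or index whose membership defines habitat
#'   (default the first class).
#' @param n_iter number of Monte-Carlo iterations.
#' @param alpha_cut inclusion threshold (default 0.5).
#' @param seed integer root seed.
#' @return An `fh_mc` object; `tidy()` returns the per-iteration tibble,
#'   `glance()` the summary row (mean, min, max, sd, quartiles).
#' @examples
#' stack <- make_single_patch(scenario_spec("single_patch_high_contrast"))
#' mc <- habitat_amount_mc(stack, n_iter = 50, seed = 1)
#' glance(mc)
#' @export
habitat_amount_mc <- function(stack, class = 1L, n_iter = 1000L,
                              alpha_cut = 0.5, seed = 1L) {
  stopifnot(n_iter >= 1L)
  ci <- class_index(stack, class)
  bs <- beta_surface(stack)
  a <- cell_area(stack)
  seeds <- iteration_seeds(seed, n_iter)
  vals <- vapply(seq_len(n_iter), function(i) {
    r <- sample_realization(bs, seed = seeds[i])
    total_phab(r$membership[, , ci], alpha_cut) * a
  }, numeric(1L))
  new_fh_mc(tibble::tibble(iteration = seq_len(n_iter), value = vals),
            metric = "habitat_amount", units = "squared map units")
}

class_index <- function(x, class) {
  if (is.character(class)) {
    ci <- match(class, x$class_labels)
    if (is.na(ci)) abort(sprintf("unknown class '%s'.", class))
    ci
  } else {
    stopifnot(class >= 1L, class <= length(x$class_labels))
    as.integer(class)
  }
}
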