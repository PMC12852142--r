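# shift-and-add windowed kernel sum: for each cell, the sum over all
# neighbour cells within Euclidean distance maxD (focal cell excluded) of
# kernel(distance) * source value. Distances are center-to-center in map
# units; offsets beyond maxD are truncated (kernel there is <= tail_d).
kernel_window_sum <- function(source, kernel, cell_size) {
  stopifnot(is.matrix(source), inherits(kernel, "kernel_spec"))
  nr <- nrow(source); nc <- ncol(source)
  rad <- floor(kernel$maxD / cell_size + 1e-9)
  out <- matrix(0, nr, nc)
  if (rad < 1L) return(out)
  for (dr in -rad:rad) {
    for (dc in -rad:rad) {
      if (dr == 0L && dc == 0L) next
      d <- cell_size * sqrt(dr^2 + dc^2)
      if (d > kernel$maxD + 1e-9) next
      w <- exp(-kernel$decay_alpha * d)
      # source cell k = (r + dr, c + dc) contributes to focal cell (r, c)
      r_lo <- max(1L, 1L - dr); r_hi <- min(nr, nr - dr)
      c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
      if (r_lo > r_hi || c_lo > c_hi) next
      r_f <- r_lo:r_hi; c_f <- c_lo:c_hi
      out[r_f, c_f] <- out[r_f, c_f] + w * source[r_f + dr, c_f + dc]
    }
  }
  out
}

#' Negative neighbourhood effect surface
#'
#' For every cell, sums the kernel-weighted memberships to deleterious
#' land-cover classes over the Euclidean neighbourhood out to the maximum
#' edge-effect distance: nearby high-membership deleterious cover (e.g.
#' urban) depresses habitat quality, with influence decaying as
#' `exp(-alpha * D)` and reaching `tail_d` (default 0.01) at `maxD`. The
#' focal cell itself is excluded from its neighbourhood.
#'
#' @param real a [realization()].
#' @param deleterious class names or indices exerting the negative effect;
#'   an empty set yields an all-zero surface.
#' @param kernel a [kernel_spec()] with `distance_mode = "euclidean"`.
#' @param cell_size cell edge length in map units (default: taken from
#'   `real`).
#' @return A numeric matrix (>= 0) of `nNeg` values.
#' @examples
#' stack <- make_four_class(scenario_spec("four_class"))
#' r <- sample_realization(stack, seed = 1)
#' ks <- kernel_spec(maxD = 10, tail_d = 0.01)
#' nneg <- negative_effect(r, "urban", ks)
#' @export
negative_effect <- function(real, deleterious, kernel,
                            cell_size = real$cell_size) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (kernel$distance_mode != "euclidean") {
    abort("edge-effect kernels use euclidean distance.")
  }
  d <- dim(real$membership)
  if (length(deleterious) == 0L) return(matrix(0, d[1L], d[2L]))
  ci <- vapply(deleterious, function(x) class_index(real, x), integer(1L))
  src <- apply(real$membership[, , ci, drop = FALSE], c(1L, 2L), sum)
  kernel_window_sum(src, kernel, cell_size)
}

#' Positive neighbourhood effect (resource complementarity) surface
#'
#' For each habitat cell (a cell whose habitat suitability meets the
#' alpha-cut), averages the kernel-weighted foraging suitability of all
#' cells reachable within the maximum foraging distance, where distance is
#' the accumulated functional cost between cells (so intervening hostile
#' cover shrinks the accessible foraging neighbourhood). The focal cell is
#' excluded; the sum is normalized by the neighbour count `|C|`; cells with
#' no reachable neighbour, and all non-habitat cells, get 0.
#'
#' @param forage numeric matrix of per-cell foraging suitability
#'   ([forage_suitability()]).
#' @param habitat numeric matrix of habitat suitability
#'   ([habitat_suitability()]).
#' @param cost a positive cost matrix (the functional cost surface,
#'   [functional_cost()]) over which distances accumulate.
#' @param kernel a [kernel_spec()] with `distance_mode = "functional_cost"`
#'   (typically `maxD` = foraging distance, `tail_d` = 0.05).
#' @param cell_size cell edge length in map units.
#' @param alpha_cut habitat threshold (default 0.5).
#' @return A numeric matrix (>= 0) of `nPos` values.
#' @export
positive_effect <- function(forage, habitat, cost, kernel, cell_size = 1,
                            alpha_cut = 0.5) {
  stopifnot(is.matrix(forage), is.matrix(habitat),
            identical(dim(forage), dim(habitat)),
            identical(dim(forage), dim(cost)),
            inherits(kernel, "kernel_spec"))
  if (kernel$distance_mode != "functional_cost") {
    abort("foraging kernels use functional-cost distance.")
  }
  out <- matrix(0, nrow(forage), ncol(forage))
  hab <- which(habitat >= alpha_cut)
  if (length(hab) == 0L) return(out)
  g <- grid_graph(cost, cell_size)
  dmat <- igraph::distances(g, v = hab)
  mask <- dmat <= kernel$maxD + 1e-9
  mask[cbind(seq_along(hab), hab)] <- FALSE  # exclude the focal cell
  w <- matrix(0, nrow(dmat), ncol(dmat))
  w[mask] <- exp(-kernel$decay_alpha * dmat[mask])
  n_nb <- rowSums(mask)
  vals <- as.numeric(w %*% as.vector(forage))
  out[hab] <- ifelse(n_nb > 0, vals / n_nb, 0)
  out
}

#' Functional habitat surface
#'
#' Combines the multivariate habitat suitability with the positive and
#' negative neighbourhood effects: `fHab = habitat + nPos - nNeg`, clipped
#' to \[0, 1\] so the result keeps membership semantics and remains
#' alpha-cuttable. The raw, unclipped surface is retained as attribute
#' `"unclipped"` for diagnostics.
#'
#' @param habitat habitat-suitability matrix ([habitat_suitability()]).
#' @param nPos positive-effect matrix ([positive_effect()]), or 0.
#' @param nNeg negative-effect matrix ([negative_effect()]), or 0.
#' @return A numeric matrix in \[0, 1\] with attribute `"unclipped"`.
#' @examples
#' h <- matrix(c(0.6, 0.3), 1)
#' functional_habitat(h, matrix(c(0.2, 0), 1), matrix(c(0.1, 0.5), 1))
#' @export
functional_habitat <- function(habitat, nPos = 0, nNeg = 0) {
  stopifnot(is.matrix(habitat))
  raw <- habitat + nPos - nNeg
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "unclipped") <- raw
  out
}
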