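#' Beta parameters from a mean and variance (method of moments)
#'
#' Converts per-cell (mean, variance) membership summaries into Beta shape
#' parameters via `nu = mu * (1 - mu) / sigma2 - 1`, `a = mu * nu`,
#' `b = (1 - mu) * nu`. Degenerate cells — zero variance or a mean of
#' exactly 0 or 1 — are flagged as point masses and sampled as constants.
#' A variance at or above the Beta-feasible bound `mu * (1 - mu)` is capped
#' at 0.95 of that bound and flagged (a data-quality warning is emitted).
#'
#' @param mu numeric vector/array of means in \[0, 1\].
#' @param sigma2 numeric vector/array of variances, >= 0, same shape.
#' @return A list with components `shape1`, `shape2` (NA where point-mass),
#'   `point_mass` and `capped` (logical, same shape as `mu`).
#' @examples
#' beta_from_moments(0.5, 1 / 12)  # the uniform distribution: a = b = 1
#' beta_from_moments(0.6, 0.0225)  # a = 5.8, b = 3.8667
#' @export
beta_from_moments <- function(mu, sigma2) {
  if (anyNA(mu) || any(mu < 0) || any(mu > 1)) {
    abort("`mu` must lie in [0, 1].")
  }
  if (anyNA(sigma2) || any(!is.finite(sigma2)) || any(sigma2 < 0)) {
    abort("`sigma2` must be finite and >= 0.")
  }
  if (!identical(length(mu), length(sigma2))) {
    abort("`mu` and `sigma2` must have the same length.")
  }
  point_mass <- sigma2 == 0 | mu == 0 | mu == 1
  bound <- mu * (1 - mu)
  capped <- !point_mass & sigma2 >= bound
  if (any(capped)) {
    warn(sprintf(
      "%d cell(s) had variance >= mu*(1-mu); capped at 0.95 of the Beta bound.",
      sum(capped)))
    sigma2[capped] <- 0.95 * bound[capped]
  }
  nu <- ifelse(point_mass, NA_real_, bound / sigma2 - 1)
  out <- list(shape1 = mu * nu, shape2 = (1 - mu) * nu,
              point_mass = point_mass, capped = capped)
  if (is.array(mu)) {
    out <- lapply(out, function(v) array(v, dim = dim(mu)))
  }
  out
}

#' Fit per-cell Beta distributions to a class stack
#'
#' Moment-matches a Beta distribution to every (cell, class) pair of a
#' [class_stack()], giving the type-2 fuzzy representation from which
#' Monte-Carlo realizations are drawn.
#'
#' @param stack a [class_stack()].
#' @return A `beta_surface`: shape arrays, point-mass/capped flags, the
#'   stack's mean membership, class labels and cell size.
#' @examples
#' bs <- beta_surface(make_single_patch(scenario_spec("single_patch_low_contrast")))
#' @export
beta_surface <- function(stack) {
  stopifnot(inherits(stack, "class_stack"))
  fit <- beta_from_moments(stack$membership, stack$variance)
  structure(
    list(shape1 = fit$shape1, shape2 = fit$shape2,
         point_mass = fit$point_mass, capped = fit$capped,
         mean = stack$membership, class_labels = stack$class_labels,
         cell_size = stack$cell_size),
    class = "beta_surface")
}

#' @export
print.beta_surface <- function(x, ...) {
  d <- dim(x$mean)
  cat(sprintf("<beta_surface> %d x %d grid, %d classes (%d point-mass, %d capped cells)\n",
              d[1L], d[2L], d[3L], sum(x$point_mass), sum(x$capped)))
  invisible(x)
}

#' Draw one Monte-Carlo realization of the landscape
#'
#' Samples one membership value per cell per class from the fitted Beta
#' distributions (point-mass cells return their mean exactly), then — by
#' default — renormalizes the class memberships within each cell to sum to
#' one, so that downstream membership-weighted sums remain convex
#' combinations. Sampling is per-cell independent.
#'
#' @param x a `beta_surface` or a [class_stack()] (fitted on the fly).
#' @param seed optional integer; when given, the draw is a deterministic
#'   function of the seed and the caller's RNG state is left untouched.
#' @param renormalize renormalize per-cell memberships to sum to one
#'   (default `TRUE`); set `FALSE` for sensitivity checks on the raw draws.
#' @return A [realization()].
#' @examples
#' stack <- make_single_patch(scenario_spec("single_patch_low_contrast"))
#' r1 <- sample_realization(stack, seed = 42)
#' r2 <- sample_realization(stack, seed = 42)
#' identical(r1$membership, r2$membership)
#' @export
sample_realization <- function(x, seed = NULL, renormalize = TRUE) {
  if (inherits(x, "class_stack")) x <- beta_surface(x)
  stopifnot(inherits(x, "beta_surface"))
  draw_one <- function() {
    m <- x$mean
    idx <- which(!x$point_mass)
    if (length(idx)) {
      m[idx] <- rbeta(length(idx), x$shape1[idx], x$shape2[idx])
    }
    m
  }
  m <- if (is.null(seed)) draw_one() else with_local_seed(seed, draw_one())
  # closure only applies when the classes partition the cell (K >= 2)
  if (renormalize && dim(m)[3L] > 1L) {
    s <- rowSums(matrix(m, ncol = dim(m)[3L]))
    s[s == 0] <- 1  # all-zero cells (possible only unnormalized inputs) kept at 0
    m <- m / array(s, dim = dim(m))
  }
  realization(m, x$class_labels, x$cell_size)
}
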