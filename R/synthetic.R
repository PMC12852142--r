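#' Scenario specification for synthetic fuzzy landscapes
#'
#' The generator emulates three simulated study landscapes: a single compact
#' habitat patch with a low-contrast (wide, ecotone-like) membership
#' transition, the same patch with a high-contrast (hard-edged) transition,
#' and a four-class woodland/grassland/wetland/urban mosaic. In every
#' scenario the uncertainty surface is largest at intermediate membership:
#' the variance model is `s * mu * (1 - mu)`, which peaks at `mu = 0.5` and
#' keeps each (mean, variance) pair valid Beta moments for `0 < s < 1`.
#'
#' @param scenario one of `"single_patch_low_contrast"`,
#'   `"single_patch_high_contrast"`, `"four_class"`.
#' @param grid_rows,grid_cols grid dimensions (positive integers).
#' @param cell_size cell edge length in map units.
#' @param transition_width width, in cells, of the membership transition zone
#'   (the band where membership passes from 0.8 down to 0.2). Wide for the
#'   low-contrast scenario, narrow for the high-contrast one; `0` gives a
#'   crisp step.
#' @param variance_scale `s` in the variance model `s * mu * (1 - mu)`,
#'   a fraction in (0, 1).
#' @param seed integer seed; the generated stack is a deterministic function
#'   of the full specification including the seed.
#' @return A `scenario_spec` list.
#' @examples
#' scenario_spec("four_class", seed = 7)
#' @export
scenario_spec <- function(scenario = c("single_patch_low_contrast",
                                       "single_patch_high_contrast",
                                       "four_class"),
                          grid_rows = 50L, grid_cols = 50L, cell_size = 2,
                          transition_width = NULL, variance_scale = 0.2,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(transition_width)) {
    transition_width <- switch(scenario,
      single_patch_low_contrast = 6,
      single_patch_high_contrast = 1,
      four_class = 3)
  }
  if (grid_rows < 1 || grid_cols < 1) abort("grid dimensions must be positive.")
  if (transition_width < 0) abort("`transition_width` must be >= 0.")
  if (variance_scale <= 0 || variance_scale >= 1) {
    abort("`variance_scale` must lie strictly between 0 and 1.")
  }
  structure(
    list(scenario = scenario, grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols), cell_size = cell_size,
         transition_width = transition_width,
         variance_scale = variance_scale, seed = as.integer(seed)),
    class = "scenario_spec")
}

# run `expr` under a seeded RNG without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# logistic ramp: ~0.8 -> 0.2 over `width` cells of signed distance; width 0
# degenerates to a crisp step
ramp <- function(signed_dist, width) {
  if (width <= 0) return(as.numeric(signed_dist >= 0))
  stats::plogis(signed_dist / (width / (2 * log(4))))
}

# smooth seeded perturbation of a blob radius as a low-order Fourier series
# in polar angle; amplitude is a fixed fraction of the radius
wobble <- function(theta, n_harmonics = 3L) {
  a <- stats::runif(n_harmonics, -1, 1)
  phi <- stats::runif(n_harmonics, 0, 2 * pi)
  out <- 0
  for (j in seq_len(n_harmonics)) out <- out + a[j] * sin(j * theta + phi[j])
  out / n_harmonics
}

#' Generate a single-patch membership + variance stack
#'
#' Builds a two-class (habitat, matrix) stack with a central compact patch:
#' membership tends to 1 in the patch interior and 0 outside, with a
#' sigmoidal transition whose width is set by `transition_width`. The matrix
#' class is the exact complement, so per-cell memberships sum to one by
#' construction. Variance is `s * mu * (1 - mu)` for each class.
#'
#' @param spec a [scenario_spec()] with one of the two single-patch
#'   scenarios.
#' @return A [class_stack()] with classes `habitat`, `matrix`.
#' @examples
#' stack <- make_single_patch(scenario_spec("single_patch_high_contrast"))
#' range(stack$membership)
#' @export
make_single_patch <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!spec$scenario %in% c("single_patch_low_contrast",
                            "single_patch_high_contrast")) {
    abort("`spec$scenario` must be one of the single-patch variants.")
  }
  nr <- spec$grid_rows; nc <- spec$grid_cols
  r0 <- min(nr, nc) / 5
  if (min(nr, nc) / 2 <= 1.15 * r0 + spec$transition_width / 2 + 1) {
    abort(sprintf(
      "grid %d x %d is too small to contain the patch plus a transition of width %g cells.",
      nr, nc, spec$transition_width))
  }
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((row - cr)^2 + (col - cc)^2)
  theta <- atan2(row - cr, col - cc)
  mu <- with_local_seed(spec$seed, {
    r_eff <- r0 * (1 + 0.12 * wobble(theta))
    ramp(r_eff - d, spec$transition_width)
  })
  membership <- array(c(mu, 1 - mu), dim = c(nr, nc, 2L))
  variance <- spec$variance_scale * membership * (1 - membership)
  class_stack(membership, variance, c("habitat", "matrix"), spec$cell_size)
}

#' Generate a four-class woodland/grassland/wetland/urban stack
#'
#' Builds the four-class mosaic used throughout the worked examples: two
#' disjoint high-woodland regions on either side of a central high-wetland
#' band, an urban strip along the bottom margin, and a grassland matrix
#' elsewhere. Memberships are composed hierarchically so they sum exactly to
#' one per cell; variance is `s * mu * (1 - mu)`.
#'
#' The geometry guarantees that a straight raster line between the two
#' woodland-region centroids crosses cells with wetland membership above
#' 0.5, so least-cost paths between the woodland patches must detour around
#' (or pay for crossing) the wetland.
#'
#' @param spec a [scenario_spec()] with `scenario = "four_class"`.
#' @return A [class_stack()] with classes `woodland`, `grassland`,
#'   `wetland`, `urban`.
#' @examples
#' stack <- make_four_class(scenario_spec("four_class", seed = 7))
#' stack$class_labels
#' @export
make_four_class <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario != "four_class") {
    abort("`spec$scenario` must be 'four_class'.")
  }
  nr <- spec$grid_rows; nc <- spec$grid_cols
  r0 <- min(nr, nc) * 0.14
  w <- spec$transition_width
  if (nc < 8 * r0 / 1.4 || min(nr, nc) < 4 * (r0 + w)) {
    abort(sprintf(
      "grid %d x %d is too small for two woodland regions plus transitions of width %g cells.",
      nr, nc, w))
  }
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  centers <- list(c((nr + 1) / 2, 0.27 * nc), c((nr + 1) / 2, 0.73 * nc))
  with_local_seed(spec$seed, {
    wood_raw <- matrix(0, nr, nc)
    for (ctr in centers) {
      d <- sqrt((row - ctr[1])^2 + (col - ctr[2])^2)
      theta <- atan2(row - ctr[1], col - ctr[2])
      r_eff <- r0 * (1 + 0.1 * wobble(theta))
      wood_raw <- pmax(wood_raw, ramp(r_eff - d, w))
    }
    half_band <- 0.08 * nc
    wet_raw <- ramp(half_band - abs(col - (nc + 1) / 2), w)
    margin <- max(2, 0.1 * nr)
    urb_raw <- ramp(margin - (nr - row), w)
    wood <- wood_raw
    rem <- 1 - wood
    wet <- rem * wet_raw
    rem <- rem * (1 - wet_raw)
    urb <- rem * urb_raw
    grass <- rem * (1 - urb_raw)
    membership <- array(c(wood, grass, wet, urb), dim = c(nr, nc, 4L))
    variance <- spec$variance_scale * membership * (1 - membership)
    class_stack(membership, variance,
                c("woodland", "grassland", "wetland", "urban"),
                spec$cell_size)
  })
}

#' Generate a synthetic landscape from a scenario specification
#'
#' Dispatches to [make_single_patch()] or [make_four_class()] according to
#' `spec$scenario`.
#'
#' @param spec a [scenario_spec()].
#' @return A [class_stack()].
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario == "four_class") make_four_class(spec)
  else make_single_patch(spec)
}
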