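#' Fuzzy land-cover class stack
#'
#' A `class_stack` holds congruent per-class type-1 membership surfaces and
#' their companion uncertainty (variance) surfaces on a regular grid, i.e. the
#' output a probabilistic classifier provides for a landscape. Membership
#' values lie in \[0, 1\]; the variance surface carries the type-2 (second
#' order) uncertainty around each membership value.
#'
#' @param membership numeric array `rows x cols x K` of mean class
#'   memberships, each value in \[0, 1\].
#' @param variance numeric array `rows x cols x K` of membership variances,
#'   finite and non-negative.
#' @param class_labels character vector of `K` land-cover class names.
#' @param cell_size edge length of a grid cell in map units; cell area is
#'   `cell_size^2` and landscape area is `rows * cols * cell_size^2`.
#'
#' @return An object of class `class_stack`.
#' @examples
#' spec <- scenario_spec("single_patch_low_contrast", seed = 1)
#' stack <- make_single_patch(spec)
#' stack
#' @export
class_stack <- function(membership, variance, class_labels, cell_size) {
  if (!is.array(membership) || length(dim(membership)) != 3L) {
    abort("`membership` must be a rows x cols x K array.")
  }
  if (!identical(dim(membership), dim(variance))) {
    abort("`membership` and `variance` grids must be congruent.")
  }
  k <- dim(membership)[3L]
  if (length(class_labels) != k) {
    abort(sprintf("`class_labels` has length %d but the stack has %d classes.",
                  length(class_labels), k))
  }
  if (anyNA(membership) || any(membership < 0) || any(membership > 1)) {
    bad <- which(is.na(membership) | membership < 0 | membership > 1,
                 arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "membership out of [0, 1] at cell (row %d, col %d), class '%s'.",
      bad[1L], bad[2L], class_labels[bad[3L]]))
  }
  if (anyNA(variance) || any(!is.finite(variance)) || any(variance < 0)) {
    bad <- which(is.na(variance) | !is.finite(variance) | variance < 0,
                 arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "variance must be finite and >= 0; offending cell (row %d, col %d), class '%s'.",
      bad[1L], bad[2L], class_labels[bad[3L]]))
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    abort("`cell_size` must be a single positive number.")
  }
  structure(
    list(membership = membership, variance = variance,
         class_labels = as.character(class_labels),
         cell_size = as.numeric(cell_size)),
    class = "class_stack")
}

#' @export
print.class_stack <- function(x, ...) {
  d <- dim(x$membership)
  cat(sprintf("<class_stack> %d x %d grid, %d classes, cell size %g\n",
              d[1L], d[2L], d[3L], x$cell_size))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat(sprintf("  cell area %g, landscape area %g (squared map units)\n",
              cell_area(x), landscape_area(x)))
  invisible(x)
}

#' Grid geometry helpers
#'
#' @param x a `class_stack` or `realization`.
#' @return `cell_area()`: the area of one cell; `landscape_area()`: the total
#'   study-extent area, both in squared map units.
#' @export
cell_area <- function(x) x$cell_size^2

#' @rdname cell_area
#' @export
landscape_area <- function(x) prod(dim(x$membership)[1:2]) * x$cell_size^2

#' Number of land-cover classes in a stack or realization
#' @param x a `class_stack` or `realization`.
#' @export
n_classes <- function(x) dim(x$membership)[3L]

#' One Monte-Carlo realization of a fuzzy landscape
#'
#' A `realization` is a single crisp-valued draw of the membership surfaces:
#' one membership value per cell per class, optionally renormalized so the
#' per-cell class memberships sum to one.
#'
#' @param membership numeric array `rows x cols x K` in \[0, 1\].
#' @param class_labels character vector of class names.
#' @param cell_size cell edge length in map units.
#' @return An object of class `realization`.
#' @export
realization <- function(membership, class_labels, cell_size) {
  structure(
    list(membership = membership, class_labels = as.character(class_labels),
         cell_size = as.numeric(cell_size)),
    class = "realization")
}

#' @export
print.realization <- function(x, ...) {
  d <- dim(x$membership)
  cat(sprintf("<realization> %d x %d grid, %d classes, cell size %g\n",
              d[1L], d[2L], d[3L], x$cell_size))
  invisible(x)
}

#' @method as_tibble class_stack
#' @export
as_tibble.class_stack <- function(x, ...) {
  d <- dim(x$membership)
  tibble::tibble(
    row = rep(rep(seq_len(d[1L]), d[2L]), d[3L]),
    col = rep(rep(seq_len(d[2L]), each = d[1L]), d[3L]),
    class = rep(x$class_labels, each = d[1L] * d[2L]),
    membership = as.vector(x$membership),
    variance = as.vector(x$variance))
}

#' @method as_tibble realization
#' @export
as_tibble.realization <- function(x, ...) {
  d <- dim(x$membership)
  tibble::tibble(
    row = rep(rep(seq_len(d[1L]), d[2L]), d[3L]),
    col = rep(rep(seq_len(d[2L]), each = d[1L]), d[3L]),
    class = rep(x$class_labels, each = d[1L] * d[2L]),
    membership = as.vector(x$membership))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
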