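#' Calibrate the negative-exponential kernel decay constant
#'
#' Solves `exp(-alpha * maxD) = tail_d` for `alpha`, i.e.
#' `alpha = -log(tail_d) / maxD`: the kernel equals 1 at distance zero and
#' exactly `tail_d` at the maximum effect distance. The edge-effect kernel
#' uses `tail_d = 0.01` at the maximum edge-effect distance; the foraging
#' kernel uses `tail_d = 0.05` at the maximum foraging distance.
#'
#' @param maxD maximum effect distance, in map units (> 0).
#' @param tail_d kernel value at `maxD`, a probability in (0, 1).
#' @return The decay constant, per map unit.
#' @examples
#' a <- calibrate_decay(5, 0.01)   # 0.921034 per unit
#' exp(-a * 5)                     # back to 0.01
#' @export
calibrate_decay <- function(maxD, tail_d) {
  if (!is.numeric(maxD) || maxD <= 0) abort("`maxD` must be > 0.")
  if (!is.numeric(tail_d) || tail_d <= 0 || tail_d >= 1) {
    abort("`tail_d` must lie strictly between 0 and 1.")
  }
  -log(tail_d) / maxD
}

#' Distance-decay kernel specification
#'
#' Bundles the calibrated decay constant with the distance mode used to
#' measure `D_ck`: straight-line (`"euclidean"`, the edge-effect case) or
#' accumulated functional cost (`"functional_cost"`, the foraging case).
#'
#' @param maxD maximum effect distance in map units.
#' @param tail_d kernel value at `maxD`.
#' @param distance_mode `"euclidean"` or `"functional_cost"`.
#' @return A `kernel_spec` list with the derived `decay_alpha`.
#' @examples
#' ks <- kernel_spec(100, 0.05, "functional_cost")
#' kernel_value(ks, c(0, 50, 100))
#' @export
kernel_spec <- function(maxD, tail_d,
                        distance_mode = c("euclidean", "functional_cost")) {
  distance_mode <- match.arg(distance_mode)
  structure(list(decay_alpha = calibrate_decay(maxD, tail_d), maxD = maxD,
                 tail_d = tail_d, distance_mode = distance_mode),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @param kernel a `kernel_spec`.
#' @param D distance(s) in map units.
#' @export
kernel_value <- function(kernel, D) {
  stopifnot(inherits(kernel, "kernel_spec"))
  exp(-kernel$decay_alpha * D)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> exp(-%g D), %s distance; P(%g) = %g\n",
              x$decay_alpha, x$distance_mode, x$maxD, x$tail_d))
  invisible(x)
}
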