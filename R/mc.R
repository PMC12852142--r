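#' Monte-Carlo result container
#'
#' Light wrapper around a per-iteration tibble of metric values with a
#' precomputed summary. Created by [habitat_amount_mc()] and
#' [rfh_monte_carlo()].
#'
#' @name fh_mc
NULL

new_fh_mc <- function(values, metric, units = "", extra = list()) {
  stopifnot(is.data.frame(values), all(c("iteration", "value") %in% names(values)))
  structure(c(list(values = values, metric = metric, units = units,
                   summary = mc_summary(values$value)), extra),
            class = "fh_mc")
}

#' Summarize a Monte-Carlo sample
#'
#' @param x numeric vector of per-iteration metric values.
#' @param n_bins number of equal-width histogram bins over the observed
#'   range (default 30).
#' @return A list with `n_iter`, `mean`, `min`, `max`, `sd`, `quantiles`
#'   (5/25/50/75/95%), and histogram `breaks`/`counts` (counts sum to
#'   `n_iter`).
#' @export
mc_summary <- function(x, n_bins = 30L) {
  stopifnot(length(x) >= 1L, n_bins >= 1L)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  list(n_iter = length(x), mean = mean(x), min = min(x), max = max(x),
       sd = if (length(x) > 1L) sd(x) else 0,
       quantiles = quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = TRUE),
       breaks = breaks, counts = counts)
}

#' @export
print.fh_mc <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<fh_mc> %s over %d iterations%s\n", x$metric, s$n_iter,
              if (nzchar(x$units)) paste0(" (", x$units, ")") else ""))
  cat(sprintf("  mean = %.4g  min = %.4g  max = %.4g  sd = %.4g\n",
              s$mean, s$min, s$max, s$sd))
  invisible(x)
}

#' @method tidy fh_mc
#' @export
tidy.fh_mc <- function(x, ...) x$values

#' @method glance fh_mc
#' @export
glance.fh_mc <- function(x, ...) {
  s <- x$summary
  tibble::tibble(metric = x$metric, n_iter = s$n_iter, mean = s$mean,
                 min = s$min, max = s$max, sd = s$sd,
                 q25 = unname(s$quantiles["25%"]),
                 median = unname(s$quantiles["50%"]),
                 q75 = unname(s$quantiles["75%"]))
}

#' @method autoplot fh_mc
#' @export
autoplot.fh_mc <- function(object, bins = 30L, ...) {
  ggplot2::ggplot(object$values, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey20", linewidth = 0.2) +
    ggplot2::labs(x = paste0(object$metric,
                             if (nzchar(object$units)) paste0(" (", object$units, ")")),
                  y = "realizations") +
    ggplot2::theme_minimal()
}
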