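#' Configuration for a reproducible Monte-Carlo run
#'
#' @param input path to a class-stack TIFF ([write_class_stack()] layout),
#'   or a [class_stack()] object directly.
#' @param profile a [species_profile()] or path to a YAML profile.
#' @param mode `"amount"` (habitat-amount distribution + core frequency),
#'   `"density"` (least-cost-path density, RH mode), `"rfh"` (reachable
#'   functional habitat distribution), or `"boolean_ehi"` (deterministic
#'   crisp baseline).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed integer root seed.
#' @param alpha_cut overrides the profile's alpha-cut when given.
#' @param target_class habitat class for amount/density/boolean modes.
#' @param out_dir output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(input, profile = species_profile(),
                       mode = c("amount", "density", "rfh", "boolean_ehi"),
                       n_iter = 10000L, seed = 1L, alpha_cut = NULL,
                       target_class = NULL, out_dir = "fuzzyhab_out") {
  mode <- match.arg(mode)
  if (n_iter < 1L) abort("`n_iter` must be >= 1.")
  if (is.character(input) && !file.exists(input)) {
    abort(sprintf("input raster '%s' does not exist.", input))
  }
  if (is.character(profile)) profile <- read_species_profile(profile)
  if (!is.null(alpha_cut)) profile$alpha_cut <- alpha_cut
  structure(list(input = input, profile = profile, mode = mode,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 target_class = target_class, out_dir = out_dir),
            class = "run_config")
}

#' Execute a configured Monte-Carlo run
#'
#' Runs the configured pipeline, writes its artifacts (surfaces as TIFF,
#' per-iteration distributions as CSV, a summary JSON, and a log recording
#' the seed and every parameter value) under `out_dir`, and returns the
#' Monte-Carlo summary. Identical configuration and seed produce identical
#' outputs. `mode = "boolean_ehi"` has no stochastic component, so
#' `n_iter` is forced to 1 with a warning if set higher.
#'
#' @param config a [run_config()].
#' @return An `fh_mc` (or, for `boolean_ehi`, a degenerate one-iteration
#'   `fh_mc`), invisibly alongside the files on disk.
#' @export
fh_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stack <- if (inherits(config$input, "class_stack")) config$input
           else read_class_stack(config$input)
  profile <- config$profile
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  n_iter <- config$n_iter
  if (config$mode == "boolean_ehi" && n_iter != 1L) {
    warn("boolean_ehi mode is deterministic; forcing n_iter = 1.")
    n_iter <- 1L
  }
  target <- config$target_class
  if (is.null(target)) {
    target <- if ("woodland" %in% stack$class_labels) "woodland"
              else stack$class_labels[1L]
  }
  res <- switch(config$mode,
    amount = {
      mc <- habitat_amount_mc(stack, class = target, n_iter = n_iter,
                              alpha_cut = profile$alpha_cut,
                              seed = config$seed)
      freq <- core_frequency(
        stack,
        extract = function(r) r$membership[, , class_index(r, target)],
        n_iter = min(n_iter, 1000L), alpha_cut = profile$alpha_cut,
        seed = config$seed)
      write_surface(freq, out("core_frequency.tif"))
      mc
    },
    density = ,
    rfh = {
      mc <- rfh_monte_carlo(stack, profile, n_iter = n_iter,
                            seed = config$seed,
                            mode = if (config$mode == "rfh") "rfh" else "rh",
                            target_class = target, collect_density = TRUE)
      if (!is.null(mc$density)) {
        write_surface(mc$density, out("path_density.tif"))
      }
      mc
    },
    boolean_ehi = {
      be <- boolean_ehi(stack, profile, target_class = target)
      write_surface(be$cost, out("boolean_cost.tif"))
      if (nrow(be$patches$patches)) {
        write_patch_set(be$patches, out("boolean_patches.csv"))
      }
      new_fh_mc(tibble::tibble(iteration = 1L, value = be$value),
                metric = "boolean_ehi", units = "percent")
    })
  write.csv(res$values, out("distribution.csv"), row.names = FALSE)
  s <- res$summary
  jsonlite::write_json(
    list(metric = res$metric, units = res$units, n_iter = s$n_iter,
         mean = s$mean, min = s$min, max = s$max, sd = s$sd,
         quantiles = as.list(s$quantiles),
         histogram = list(breaks = s$breaks, counts = s$counts)),
    out("summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(run_log_lines(config, n_iter, target), out("run_log.txt"))
  invisible(res)
}

# every (possibly defaulted) parameter value is logged for auditability
run_log_lines <- function(config, n_iter, target) {
  p <- config$profile
  c(sprintf("fuzzyhab %s", as.character(utils::packageVersion("fuzzyhab"))),
    sprintf("mode: %s", config$mode),
    sprintf("seed: %d", config$seed),
    sprintf("n_iter: %d", n_iter),
    sprintf("target_class: %s", target),
    sprintf("alpha_cut: %g", p$alpha_cut),
    sprintf("H: %s", paste(p$H, collapse = ", ")),
    sprintf("F: %s", paste(p$F_, collapse = ", ")),
    sprintf("R: %s", paste(p$R, collapse = ", ")),
    sprintf("deleterious: %s", paste(p$deleterious, collapse = ", ")),
    sprintf("maxD_edge: %g (tail %g)", p$maxD_edge, p$d_edge),
    sprintf("maxD_forage: %g (tail %g)", p$maxD_forage, p$d_forage),
    sprintf("dispersal: %g (tail %g)", p$dispersal_distance,
            p$dispersal_tail))
}
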