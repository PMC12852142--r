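#' Species profile: resource weights, kernels and movement parameters
#'
#' Bundles the species-specific parameters driving habitat delineation:
#' per-class habitat suitability `H` and foraging suitability `F` (both in
#' \[0, 1\]), per-class movement resistance `R` (> 0), the maximum
#' edge-effect and foraging distances with their kernel tail probabilities,
#' the dispersal distance/tail calibrating between-patch movement
#' probabilities, the alpha-cut, and the set of deleterious classes.
#'
#' The defaults parameterize the four-class woodland/grassland/wetland/urban
#' demonstration landscape: a woodland-breeding species that forages partly
#' in grassland, avoids urban cover (the single deleterious class, edge
#' effect out to 10 map units = 5 cells at the default 2-unit cell size),
#' and forages up to 100 map units.
#'
#' @param H habitat-suitability weights per class, each in \[0, 1\].
#' @param F_ foraging-suitability weights per class, each in \[0, 1\].
#' @param R resistance per class, all > 0.
#' @param class_labels class names the weights refer to.
#' @param deleterious classes exerting negative edge effects (subset of
#'   `class_labels`, possibly empty).
#' @param maxD_edge maximum edge-effect distance, map units.
#' @param maxD_forage maximum foraging distance, map units.
#' @param d_edge kernel tail at `maxD_edge` (default 0.01).
#' @param d_forage kernel tail at `maxD_forage` (default 0.05).
#' @param dispersal_distance characteristic dispersal distance, map units.
#' @param dispersal_tail movement probability at `dispersal_distance`
#'   (default 0.05).
#' @param alpha_cut habitat inclusion threshold in (0, 1), default 0.5
#'   (above 0.5 a cell cannot hold a higher membership to any other class).
#' @return A `species_profile` list.
#' @examples
#' species_profile()
#' @export
species_profile <- function(H = c(0.9, 0.1, 0, 0),
                            F_ = c(0.8, 0.5, 0.3, 0.2),
                            R = c(1, 5, 8, 10),
                            class_labels = c("woodland", "grassland",
                                             "wetland", "urban"),
                            deleterious = "urban",
                            maxD_edge = 10, maxD_forage = 100,
                            d_edge = 0.01, d_forage = 0.05,
                            dispersal_distance = 200,
                            dispersal_tail = 0.05,
                            alpha_cut = 0.5) {
  k <- length(class_labels)
  if (length(H) != k || length(F_) != k || length(R) != k) {
    abort("`H`, `F_` and `R` must each have one value per class.")
  }
  if (any(H < 0 | H > 1) || any(F_ < 0 | F_ > 1)) {
    abort("`H` and `F_` weights must lie in [0, 1].")
  }
  if (any(R <= 0)) abort("all resistance values must be > 0.")
  for (p in list(d_edge = d_edge, d_forage = d_forage,
                 dispersal_tail = dispersal_tail, alpha_cut = alpha_cut)) {
    if (p <= 0 || p >= 1) {
      abort("tail probabilities and `alpha_cut` must lie strictly in (0, 1).")
    }
  }
  if (maxD_edge <= 0 || maxD_forage <= 0 || dispersal_distance <= 0) {
    abort("all distances must be > 0.")
  }
  if (length(deleterious) && !all(deleterious %in% class_labels)) {
    abort("`deleterious` must name classes present in `class_labels`.")
  }
  structure(
    list(H = setNames(H, class_labels), F_ = setNames(F_, class_labels),
         R = setNames(R, class_labels), class_labels = class_labels,
         deleterious = deleterious, maxD_edge = maxD_edge,
         maxD_forage = maxD_forage, d_edge = d_edge, d_forage = d_forage,
         dispersal_distance = dispersal_distance,
         dispersal_tail = dispersal_tail, alpha_cut = alpha_cut),
    class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile>\n")
  print(tibble::tibble(class = x$class_labels, H = unname(x$H),
                       F_ = unname(x$F_), R = unname(x$R)))
  cat(sprintf("  edge: maxD %g (tail %g)   forage: maxD %g (tail %g)\n",
              x$maxD_edge, x$d_edge, x$maxD_forage, x$d_forage))
  cat(sprintf("  dispersal: %g (tail %g)   alpha-cut %g   deleterious: %s\n",
              x$dispersal_distance, x$dispersal_tail, x$alpha_cut,
              if (length(x$deleterious)) paste(x$deleterious, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Read a species profile from a YAML configuration file
#'
#' The file holds the fields of [species_profile()] (class_labels, H, F, R,
#' distances, tails, alpha_cut, deleterious); the YAML key `F` is accepted
#' for the foraging weights.
#'
#' @param path path to a YAML file.
#' @return A `species_profile`.
#' @export
read_species_profile <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML profiles requires the 'yaml' package.")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$F) && is.null(cfg$F_)) { cfg$F_ <- cfg$F; cfg$F <- NULL }
  do.call(species_profile, cfg)
}
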