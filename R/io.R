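#' Read and write fuzzy class stacks as multi-band TIFF
#'
#' A stack with `K` classes is written as a 2K-band 32-bit float TIFF —
#' bands `1..K` the mean memberships, bands `K+1..2K` the variances — with
#' a JSON sidecar (`<path>.json`) carrying the class labels, cell size and
#' band layout. Reading validates the band count against the sidecar and
#' checks value ranges, reporting the offending band and cell on failure.
#' Round-tripping preserves values to 32-bit float precision.
#'
#' @param stack a [class_stack()].
#' @param path TIFF file path (the sidecar is written next to it).
#' @return `write_class_stack()`: the path, invisibly;
#'   `read_class_stack()`: a [class_stack()].
#' @examples
#' stack <- make_single_patch(scenario_spec("single_patch_low_contrast"))
#' f <- tempfile(fileext = ".tif")
#' write_class_stack(stack, f)
#' stack2 <- read_class_stack(f)
#' max(abs(stack2$membership - stack$membership))
#' @export
write_class_stack <- function(stack, path) {
  stopifnot(inherits(stack, "class_stack"))
  k <- n_classes(stack)
  bands <- c(lapply(seq_len(k), function(i) stack$membership[, , i]),
             lapply(seq_len(k), function(i) stack$variance[, , i]))
  tiff::writeTIFF(bands, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(type = "class_stack", class_labels = stack$class_labels,
               cell_size = stack$cell_size, n_classes = k,
               band_order = c(paste0("membership:", stack$class_labels),
                              paste0("variance:", stack$class_labels)))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_class_stack
#' @export
read_class_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("raster file '%s' not found.", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("sidecar '%s' (class labels, cell size) not found.", sp))
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  bands <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(bands)) bands <- list(bands)
  k <- meta$n_classes
  if (length(bands) != 2L * k) {
    abort(sprintf(
      "expected %d bands (%d membership + %d variance) but file has %d.",
      2L * k, k, k, length(bands)))
  }
  dims <- dim(bands[[1L]])
  membership <- array(unlist(bands[seq_len(k)]), dim = c(dims, k))
  variance <- array(unlist(bands[k + seq_len(k)]), dim = c(dims, k))
  tol <- 1e-6  # float32 round-off on stored values
  bad <- which(membership < -tol | membership > 1 + tol, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "membership band %d ('%s') has value %.6g out of [0, 1] at cell (row %d, col %d).",
      bad[1L, 3L], meta$class_labels[bad[1L, 3L]],
      membership[bad[1L, , drop = FALSE]], bad[1L, 1L], bad[1L, 2L]))
  }
  membership <- pmin(pmax(membership, 0), 1)
  class_stack(membership, pmax(variance, 0), meta$class_labels,
              meta$cell_size)
}

#' Read and write single-band surfaces as 32-bit float TIFF
#'
#' Arbitrary-range surfaces (cost, density, core frequency, functional
#' habitat) are stored scaled into \[0, 1\] with the scale factor and
#' offset recorded in the JSON sidecar, and restored on read.
#'
#' @param surface numeric matrix.
#' @param path TIFF file path.
#' @return `write_surface()`: the path, invisibly; `read_surface()`: a
#'   numeric matrix.
#' @export
write_surface <- function(surface, path) {
  stopifnot(is.matrix(surface), all(is.finite(surface)))
  lo <- min(surface); hi <- max(surface)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((surface - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(type = "surface", offset = lo, scale = scale),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  m * meta$scale + meta$offset
}

#' Export a patch set to CSV (and its labels to TIFF)
#'
#' Writes the per-patch table (`patch`, `n_cells`, `phab`, `amount`,
#' `centroid_row`, `centroid_col`) as CSV; optionally the integer label
#' grid as a surface TIFF alongside.
#'
#' @param patches a `patch_set`.
#' @param csv_path output CSV path.
#' @param labels_path optional TIFF path for the label grid.
#' @return `csv_path`, invisibly.
#' @export
write_patch_set <- function(patches, csv_path, labels_path = NULL) {
  stopifnot(inherits(patches, "patch_set"))
  write.csv(patches$patches, csv_path, row.names = FALSE)
  if (!is.null(labels_path)) {
    write_surface(matrix(as.numeric(patches$labels), nrow(patches$labels)),
                  labels_path)
  }
  invisible(csv_path)
}
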