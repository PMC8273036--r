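#' Intensity channel
#'
#' A single 2D fluorescence channel: a non-negative real intensity matrix
#' indexed (row, col), its physical pixel size and a provenance trail
#' recording every processing step applied so far.
#'
#' @param values numeric matrix of intensities (finite, any real values;
#'   raw micrographs are non-negative but processed channels may not be).
#' @param pixel_size physical pixel size in nm/pixel (> 0).
#' @param name stain name, e.g. `"MAP2"`, `"LAMP1"`, `"mTOR"`, `"P-pS6"`.
#' @param provenance character vector of processing-step descriptions.
#' @return An object of class `"channel"`.
#' @export
channel <- function(values, pixel_size, name = "", provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("channel values must be a numeric matrix")
  if (any(!is.finite(values)))
    stopf("channel '%s' contains non-finite values", name)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stopf("pixel_size must be a single positive number (nm/pixel)")
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         name = as.character(name), provenance = as.character(provenance)),
    class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel '%s'> %d x %d px, %.1f nm/px, range [%.3g, %.3g]\n",
              x$name, nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

append_provenance <- function(ch, step) {
  ch$provenance <- c(ch$provenance, step)
  ch
}

has_provenance <- function(ch, pattern) {
  any(grepl(pattern, ch$provenance, fixed = TRUE))
}

#' Binary mask
#'
#' A boolean region with the provenance of the channel/threshold that
#' produced it. No anonymous masks: downstream operations log or warn when
#' provenance is missing.
#'
#' @param values logical matrix.
#' @param provenance character vector describing how the mask was obtained.
#' @return An object of class `"lq_mask"`.
#' @export
lq_mask <- function(values, provenance = character()) {
  if (!is.matrix(values) || !is.logical(values))
    stopf("mask values must be a logical matrix")
  structure(list(values = values, provenance = as.character(provenance)),
            class = "lq_mask")
}

#' @export
print.lq_mask <- function(x, ...) {
  cat(sprintf("<mask> %d x %d px, %d foreground px (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Labeled segmented objects
#'
#' Integer-labeled connected objects (0 = background) with a per-object
#' table of id, area, centroid and equivalent diameter. Labels are
#' consecutive from 1.
#'
#' @param labels integer matrix of object labels (0 background).
#' @param pixel_size nm/pixel, used for the equivalent-diameter column.
#' @param provenance character vector.
#' @return An object of class `"labeled_objects"` with elements `labels`
#'   (matrix) and `objects` (data.frame: `id`, `area`, `centroid_row`,
#'   `centroid_col`, `equivalent_diameter_nm`).
#' @export
labeled_objects <- function(labels, pixel_size, provenance = character()) {
  if (!is.matrix(labels)) stopf("labels must be an integer matrix")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  # enforce consecutive ids from 1
  if (length(ids) && !identical(ids, seq_along(ids))) {
    relab <- integer(max(ids))
    relab[ids] <- seq_along(ids)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
    ids <- seq_along(ids)
  }
  if (length(ids)) {
    area <- tabulate(labels[labels > 0L], nbins = length(ids))
    rr <- row(labels); cc <- col(labels)
    pos <- labels > 0L
    cr <- vapply(split(rr[pos], labels[pos]), mean, numeric(1))
    ccol <- vapply(split(cc[pos], labels[pos]), mean, numeric(1))
    objects <- data.frame(
      id = ids, area = area, centroid_row = unname(cr),
      centroid_col = unname(ccol),
      equivalent_diameter_nm = 2 * sqrt(area / pi) * pixel_size)
  } else {
    objects <- data.frame(id = integer(), area = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          equivalent_diameter_nm = numeric())
  }
  structure(list(labels = labels, objects = objects,
                 pixel_size = as.numeric(pixel_size),
                 provenance = as.character(provenance)),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d objects on %d x %d px\n",
              nrow(x$objects), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

n_objects <- function(lo) nrow(lo$objects)

#' Multi-channel image
#'
#' Named 2D intensity channels sharing shape and pixel size; the unit of
#' analysis ("one field").
#'
#' @param channels named list of numeric matrices, all the same shape.
#' @param pixel_size nm/pixel.
#' @param image_id identifier for the field.
#' @return An object of class `"mc_image"`.
#' @export
mc_image <- function(channels, pixel_size, image_id = "") {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stopf("channels must be a non-empty named list")
  shp <- dim(channels[[1]])
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), shp))
      stopf("channel '%s' shape differs from '%s'", nm, names(channels)[1])
  }
  structure(list(channels = channels, pixel_size = as.numeric(pixel_size),
                 image_id = as.character(image_id)),
            class = "mc_image")
}

#' Extract one channel of a multi-channel image as a [channel()] object
#' @param img an `mc_image`.
#' @param name channel name.
#' @param provenance provenance to attach.
#' @return A `"channel"` object.
#' @export
get_channel <- function(img, name, provenance = character()) {
  if (!name %in% names(img$channels))
    stopf("image '%s' has no channel '%s'", img$image_id, name)
  channel(img$channels[[name]], img$pixel_size, name = name,
          provenance = provenance)
}
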