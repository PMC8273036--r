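#' Segment LAMP1-positive late-endosome objects
#'
#' Isodata threshold, 8-connected component labeling, optional splitting of
#' touching puncta by a distance-transform watershed, then removal of
#' objects whose area is not strictly above `min_area` pixels (the default
#' 25 px corresponds to an equivalent diameter of about 350 nm at
#' 65 nm/pixel).
#'
#' The LAMP1 channel should be background-subtracted first; a warning is
#' issued when the provenance carries no `rolling_ball` step.
#'
#' @param lamp1 a [channel()] with the LAMP1 signal.
#' @param min_area objects with area `<= min_area` are discarded
#'   (strictly-above rule; default 25).
#' @param split_touching split touching puncta with a watershed on the
#'   distance transform (default `FALSE`).
#' @return A [labeled_objects()]; empty segmentation gives zero objects.
#' @export
segment_les <- function(lamp1, min_area = 25, split_touching = FALSE) {
  stopifnot(inherits(lamp1, "channel"))
  if (!is.numeric(min_area) || length(min_area) != 1L || min_area < 0)
    stopf("min_area must be a single number >= 0")
  if (!has_provenance(lamp1, "rolling_ball"))
    warnf("LAMP1 channel '%s' has no background-subtraction step in its provenance",
          lamp1$name)
  if (length(unique(as.vector(lamp1$values))) < 2L)
    return(labeled_objects(matrix(0L, nrow(lamp1$values), ncol(lamp1$values)),
                           lamp1$pixel_size,
                           provenance = c(lamp1$provenance, "segment_les:blank")))
  m <- auto_threshold(lamp1, "isodata")
  lab <- label8(m$values)
  if (split_touching && max(lab) > 0L) {
    dm <- EBImage::distmap(m$values * 1)
    lab <- as.matrix(EBImage::watershed(dm, tolerance = 1))
    lab[!m$values] <- 0L
    storage.mode(lab) <- "integer"
  }
  if (max(lab) > 0L) {
    area <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(area <= min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  labeled_objects(lab, lamp1$pixel_size,
                  provenance = c(m$provenance,
                                 sprintf("segment_les(min_area=%g, split=%s)",
                                         min_area, split_touching)))
}

#' IN and ring-shaped OUT masks around segmented objects
#'
#' The IN mask is the union of object footprints intersected with the
#' dendrite mask. The OUT mask is the ring of pixels whose exact Euclidean
#' distance `d` to the nearest object pixel satisfies
#' `gap < d <= gap + width` (default: a 4-pixel-wide ring starting 6 pixels
#' outside the objects), intersected with the dendrite mask and excluding
#' all object pixels. Rings of neighbouring objects merge in the union
#' mask; in per-object mode each ring pixel is assigned to its nearest
#' object (ties to the lower id).
#'
#' @param les a [labeled_objects()] from [segment_les()].
#' @param dendrite_mask an [lq_mask()] restricting both masks to dendrites.
#' @param gap ring offset from the object boundary in pixels (default 6).
#' @param width ring width in pixels (default 4).
#' @param per_object also build per-object ring masks (default `FALSE`).
#' @return An object of class `"in_out_masks"`: `in_mask`, `out_mask`
#'   ([lq_mask()]), `gap`, `width`, and `per_object_rings` (named list of
#'   logical matrices, or `NULL`).
#' @export
build_in_out <- function(les, dendrite_mask, gap = 6, width = 4,
                         per_object = FALSE) {
  stopifnot(inherits(les, "labeled_objects"), inherits(dendrite_mask, "lq_mask"))
  if (gap < 0) stopf("gap must be >= 0")
  if (width <= 0) stopf("width must be > 0")
  if (!identical(dim(les$labels), dim(dendrite_mask$values)))
    stopf("labels and dendrite mask shapes differ")
  obj <- les$labels > 0L
  in_mask <- obj & dendrite_mask$values
  if (!any(obj)) {
    ring <- matrix(FALSE, nrow(obj), ncol(obj))
  } else {
    # distance of every non-object pixel to the nearest object pixel
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(!obj), nrow(obj))))
    ring <- d > gap & d <= gap + width
  }
  out_mask <- ring & dendrite_mask$values & !obj
  per_rings <- NULL
  if (per_object && n_objects(les) > 0) {
    ids <- les$objects$id
    dists <- vapply(ids, function(i) {
      as.vector(EBImage::distmap(matrix(as.numeric(les$labels != i),
                                        nrow(obj))))
    }, numeric(length(obj)))
    nearest <- ids[max.col(-dists, ties.method = "first")]
    per_rings <- lapply(ids, function(i) {
      m <- out_mask & matrix(nearest == i, nrow(obj))
      m
    })
    names(per_rings) <- as.character(ids)
  }
  structure(list(
    in_mask = lq_mask(in_mask,
                      provenance = c(les$provenance, dendrite_mask$provenance,
                                     "in_mask")),
    out_mask = lq_mask(out_mask,
                       provenance = c(les$provenance, dendrite_mask$provenance,
                                      sprintf("ring(gap=%g, width=%g)", gap,
                                              width))),
    gap = gap, width = width, per_object_rings = per_rings,
    labels = les$labels), class = "in_out_masks")
}

#' Remove soma footprints from a mask
#'
#' Restricts a (typically MAP2-derived) mask to dendrites by clearing every
#' pixel belonging to a labeled soma.
#'
#' @param mask an [lq_mask()].
#' @param soma_labels a [labeled_objects()] of somata.
#' @return The mask with soma pixels set to `FALSE`.
#' @export
remove_somas <- function(mask, soma_labels) {
  stopifnot(inherits(mask, "lq_mask"), inherits(soma_labels, "labeled_objects"))
  if (!identical(dim(mask$values), dim(soma_labels$labels)))
    stopf("mask and soma label shapes differ")
  lq_mask(mask$values & soma_labels$labels == 0L,
          provenance = c(mask$provenance, "remove_somas"))
}
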