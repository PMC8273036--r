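#' IN/OUT recruitment ratio
#'
#' Measures the mean fluorescence of a (background-subtracted) channel
#' inside segmented objects (IN) and in their surrounding ring regions
#' (OUT), and reports the ratio IN/OUT — the object-based readout of
#' marker recruitment to the segmented structures. One IN mean and one OUT
#' mean are computed per image by pooling pixels over all objects; when
#' the masks carry per-object rings, a per-object table is added.
#'
#' The ratio is invariant to multiplying the channel by a positive scalar
#' but not to adding a constant, which is why background subtraction must
#' precede it; a warning is issued if the channel provenance carries no
#' `rolling_ball` step.
#'
#' @param mtor a [channel()] (typically mTOR, background-subtracted).
#' @param masks an `"in_out_masks"` from [build_in_out()].
#' @param image_id,condition identifiers copied into the result.
#' @return An object of class `"recruitment_result"`: a list with
#'   `image_id`, `condition`, `mean_in`, `mean_out`, `ratio`,
#'   `n_in_pixels`, `n_out_pixels`, `n_objects`, `valid`, `reason`, and
#'   `per_object` (data.frame or `NULL`). Invalid results (no objects, no
#'   ring, zero background) carry `valid = FALSE` and a reason instead of
#'   being dropped.
#' @export
in_out_ratio <- function(mtor, masks, image_id = "", condition = "") {
  stopifnot(inherits(mtor, "channel"), inherits(masks, "in_out_masks"))
  if (!identical(dim(mtor$values), dim(masks$in_mask$values)))
    stopf("channel and mask shapes differ")
  if (!has_provenance(mtor, "rolling_ball"))
    warnf("channel '%s' has no background-subtraction step in its provenance",
          mtor$name)
  n_in <- sum(masks$in_mask$values)
  n_out <- sum(masks$out_mask$values)
  n_obj <- length(unique(masks$labels[masks$labels > 0L &
                                        masks$in_mask$values]))
  res <- list(image_id = image_id, condition = condition,
              mean_in = NA_real_, mean_out = NA_real_, ratio = NA_real_,
              n_in_pixels = n_in, n_out_pixels = n_out, n_objects = n_obj,
              valid = FALSE, reason = "", per_object = NULL)
  if (n_in == 0L) { res$reason <- "no-objects"; return(structure(res, class = "recruitment_result")) }
  if (n_out == 0L) { res$reason <- "no-ring"; return(structure(res, class = "recruitment_result")) }
  res$mean_in <- mean(mtor$values[masks$in_mask$values])
  res$mean_out <- mean(mtor$values[masks$out_mask$values])
  if (res$mean_out <= 0) {
    res$reason <- "zero-background"
    return(structure(res, class = "recruitment_result"))
  }
  res$ratio <- res$mean_in / res$mean_out
  res$valid <- TRUE
  if (!is.null(masks$per_object_rings)) {
    ids <- as.integer(names(masks$per_object_rings))
    po <- lapply(ids, function(i) {
      fin <- masks$labels == i & masks$in_mask$values
      ring <- masks$per_object_rings[[as.character(i)]]
      mi <- if (any(fin)) mean(mtor$values[fin]) else NA_real_
      mo <- if (any(ring)) mean(mtor$values[ring]) else NA_real_
      data.frame(id = i, mean_in = mi, mean_out = mo,
                 ratio = if (!is.na(mo) && mo > 0) mi / mo else NA_real_)
    })
    res$per_object <- do.call(rbind, po)
  }
  structure(res, class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<recruitment> %s [%s]: IN/OUT = %.4f (IN %.2f over %d px, OUT %.2f over %d px, %d objects)\n",
                x$image_id, x$condition, x$ratio, x$mean_in, x$n_in_pixels,
                x$mean_out, x$n_out_pixels, x$n_objects))
  else
    cat(sprintf("<recruitment> %s [%s]: invalid (%s)\n", x$image_id,
                x$condition, x$reason))
  invisible(x)
}

#' Convert recruitment results to a one-row-per-image data frame
#' @param results a list of `"recruitment_result"` objects (or one).
#' @return A data.frame with the scalar fields of each result.
#' @export
recruitment_table <- function(results) {
  if (inherits(results, "recruitment_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(image_id = r$image_id, condition = r$condition,
               mean_in = r$mean_in, mean_out = r$mean_out, ratio = r$ratio,
               n_in_pixels = r$n_in_pixels, n_out_pixels = r$n_out_pixels,
               n_objects = r$n_objects, valid = r$valid, reason = r$reason)))
}

#' Intensity clustering index over a region
#'
#' A per-region contrast statistic quantifying how clustered (peaked) a
#' signal is over a surface: the default variant is
#' `(max - min) / mean` over the region's pixels, a dimensionless contrast
#' measure that is 0 for a uniform region and grows with focal
#' enrichment. The `"literal"` variant computes `(max / min) / mean`
#' instead (and requires `min > 0`); note its value carries units of
#' 1/intensity.
#'
#' @param ch a [channel()].
#' @param region an [lq_mask()]; must be non-empty.
#' @param variant `"contrast"` (default) or `"literal"`.
#' @return A list with `index`, `variant`, `max`, `min`, `mean`, `n_pixels`.
#' @export
clustering_index <- function(ch, region, variant = c("contrast", "literal")) {
  stopifnot(inherits(ch, "channel"), inherits(region, "lq_mask"))
  variant <- match.arg(variant)
  v <- ch$values[region$values]
  if (!length(v)) stopf("clustering_index: empty region")
  mx <- max(v); mn <- min(v); mu <- mean(v)
  if (mu == 0) stopf("clustering_index: region mean is zero")
  idx <- if (variant == "contrast") (mx - mn) / mu else {
    if (mn <= 0) stopf("clustering_index literal variant: region min is zero")
    (mx / mn) / mu
  }
  list(index = idx, variant = variant, max = mx, min = mn, mean = mu,
       n_pixels = length(v))
}
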