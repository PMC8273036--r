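#' Compartmentalized P-pS6 field activity
#'
#' Mean (background-subtracted) P-pS6 intensity over the whole
#' MAP2-positive neuronal surface of a field, and split into the somatic
#' and dendritic compartments. The soma mask is intersected with the MAP2
#' mask, the dendrite compartment is the MAP2 mask minus the somata, so
#' the two compartments partition the whole mask exactly:
#' `area_soma + area_dendrite = area_whole` and the whole-field mean is
#' the area-weighted mean of the compartment means.
#'
#' @param pps6 a [channel()] (background-subtracted; a warning is issued
#'   when the provenance carries no `rolling_ball` step).
#' @param map2_mask an [lq_mask()] of the neuronal surface.
#' @param soma_mask an [lq_mask()] of somatic regions.
#' @param image_id,condition identifiers copied into the result.
#' @return An object of class `"field_activity"`: `image_id`, `condition`,
#'   `mean_whole`, `mean_soma`, `mean_dendrite`, `area_whole`,
#'   `area_soma`, `area_dendrite`, `valid`, `reason`. Empty compartments
#'   give `NA` means; an empty MAP2 mask gives an invalid result with
#'   reason `"no-neurons"`.
#' @export
field_activity <- function(pps6, map2_mask, soma_mask,
                           image_id = "", condition = "") {
  stopifnot(inherits(pps6, "channel"), inherits(map2_mask, "lq_mask"),
            inherits(soma_mask, "lq_mask"))
  if (!identical(dim(pps6$values), dim(map2_mask$values)) ||
      !identical(dim(pps6$values), dim(soma_mask$values)))
    stopf("channel and mask shapes differ")
  if (!has_provenance(pps6, "rolling_ball"))
    warnf("channel '%s' has no background-subtraction step in its provenance",
          pps6$name)
  whole <- map2_mask$values
  soma <- soma_mask$values & whole
  dend <- whole & !soma
  res <- list(image_id = image_id, condition = condition,
              mean_whole = NA_real_, mean_soma = NA_real_,
              mean_dendrite = NA_real_,
              area_whole = sum(whole), area_soma = sum(soma),
              area_dendrite = sum(dend), valid = TRUE, reason = "")
  if (res$area_whole == 0L) {
    res$valid <- FALSE; res$reason <- "no-neurons"
    return(structure(res, class = "field_activity"))
  }
  res$mean_whole <- mean(pps6$values[whole])
  if (res$area_soma > 0L) res$mean_soma <- mean(pps6$values[soma])
  if (res$area_dendrite > 0L) res$mean_dendrite <- mean(pps6$values[dend])
  structure(res, class = "field_activity")
}

#' Convert field-activity results to a data frame
#' @param results a list of `"field_activity"` objects (or one).
#' @return A data.frame, one row per field.
#' @export
activity_table <- function(results) {
  if (inherits(results, "field_activity")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(image_id = r$image_id, condition = r$condition,
               mean_whole = r$mean_whole, mean_soma = r$mean_soma,
               mean_dendrite = r$mean_dendrite, area_whole = r$area_whole,
               area_soma = r$area_soma, area_dendrite = r$area_dendrite,
               valid = r$valid, reason = r$reason)))
}

#' Segment individual somata from the P-pS6 channel
#'
#' Thresholds the (background-subtracted) P-pS6 image (isodata), restricts
#' the result to the MAP2 mask, fills holes, splits touching somata by a
#' watershed on the distance transform, and discards components smaller
#' than `min_soma_area` pixels — yielding one label per soma for
#' inter-neuron variability analyses.
#'
#' @param pps6 a [channel()] (background-subtracted).
#' @param map2_mask an [lq_mask()] of the neuronal surface.
#' @param min_soma_area components below this area are discarded
#'   (default 200 px, which separates somata from dendritic hot spots at
#'   typical large-field pixel sizes).
#' @return A [labeled_objects()] of somata (possibly empty).
#' @export
segment_somas <- function(pps6, map2_mask, min_soma_area = 200) {
  stopifnot(inherits(pps6, "channel"), inherits(map2_mask, "lq_mask"))
  if (length(unique(as.vector(pps6$values))) < 2L)
    return(labeled_objects(matrix(0L, nrow(pps6$values), ncol(pps6$values)),
                           pps6$pixel_size,
                           provenance = "segment_somas:blank"))
  m <- auto_threshold(pps6, "isodata")
  v <- m$values & map2_mask$values
  v <- fill_holes(v)
  lab <- label8(v)
  if (max(lab) > 0L) {
    dm <- EBImage::distmap(v * 1)
    ws <- as.matrix(EBImage::watershed(dm, tolerance = 2))
    ws[!v] <- 0L
    storage.mode(ws) <- "integer"
    if (max(ws) >= max(lab)) lab <- ws
    area <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(area < min_soma_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  labeled_objects(lab, pps6$pixel_size,
                  provenance = c(m$provenance,
                                 sprintf("segment_somas(min_area=%g)",
                                         min_soma_area)))
}

#' Per-soma mean P-pS6 intensities
#'
#' @param pps6 a [channel()].
#' @param somas a [labeled_objects()] of somata.
#' @param image_id,condition identifiers copied into each record.
#' @return A data.frame with one row per soma: `image_id`, `condition`,
#'   `soma_id`, `mean_intensity`, `area`, `centroid_row`, `centroid_col`.
#' @export
per_soma_intensities <- function(pps6, somas, image_id = "", condition = "") {
  stopifnot(inherits(pps6, "channel"), inherits(somas, "labeled_objects"))
  if (!identical(dim(pps6$values), dim(somas$labels)))
    stopf("channel and label shapes differ")
  if (n_objects(somas) == 0L)
    return(data.frame(image_id = character(), condition = character(),
                      soma_id = integer(), mean_intensity = numeric(),
                      area = integer(), centroid_row = numeric(),
                      centroid_col = numeric()))
  pos <- somas$labels > 0L
  means <- vapply(split(pps6$values[pos], somas$labels[pos]), mean, numeric(1))
  data.frame(image_id = image_id, condition = condition,
             soma_id = somas$objects$id,
             mean_intensity = unname(means[as.character(somas$objects$id)]),
             area = somas$objects$area,
             centroid_row = somas$objects$centroid_row,
             centroid_col = somas$objects$centroid_col)
}

#' Percentile-shift analysis of per-soma intensity distributions
#'
#' Computes the `q`-th percentile of the control distribution (linear
#' interpolation between order statistics, R's default type-7 quantile)
#' and the fraction of treated values strictly above it — a
#' heterogeneity-robust description of a population shift: if treated
#' equals control the expected fraction is `(100 - q)/100`.
#'
#' @param control numeric vector of control measurements (non-empty).
#' @param treated numeric vector of treated measurements (non-empty).
#' @param q percentile in (0, 100); default 75.
#' @return A list with `threshold`, `fraction_above`, `q`, `n_control`,
#'   `n_treated`.
#' @export
percentile_shift <- function(control, treated, q = 75) {
  if (!length(control)) stopf("percentile_shift: empty control sample")
  if (!length(treated)) stopf("percentile_shift: empty treated sample")
  if (q <= 0 || q >= 100) stopf("q must be strictly between 0 and 100")
  thr <- unname(quantile(control, q / 100, type = 7, names = FALSE))
  list(threshold = thr, fraction_above = mean(treated > thr), q = q,
       n_control = length(control), n_treated = length(treated))
}
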