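ball_element <- function(diameter) {
  r <- diameter / 2
  ri <- floor(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  keep <- off$dr^2 + off$dc^2 <= r^2
  off <- off[keep, , drop = FALSE]
  list(dr = as.integer(off$dr), dc = as.integer(off$dc),
       h = sqrt(pmax(r^2 - off$dr^2 - off$dc^2, 0)))
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a fluorescence channel by rolling a ball of
#' the given diameter under the intensity landscape and subtracts it. The
#' background is the grayscale opening of the image with a ball-shaped
#' (spherical-cap height profile) structuring element, so structures
#' narrower than the ball are retained as foreground while broad intensity
#' plateaus and gradients are removed. The output is everywhere `>= 0` and
#' `<= ` the input.
#'
#' The parameter is the ball *diameter* in pixels (ball radius =
#' `ball_diameter / 2`), matching how the quantification protocol states
#' its values (50 px for P-pS6 images, 75 px for mTOR images).
#'
#' @param ch a [channel()].
#' @param ball_diameter ball diameter in pixels (`>= 1`).
#' @return The background-subtracted channel, with provenance appended.
#' @export
rolling_ball_subtract <- function(ch, ball_diameter) {
  stopifnot(inherits(ch, "channel"))
  if (!is.numeric(ball_diameter) || length(ball_diameter) != 1L ||
      ball_diameter < 1)
    stopf("ball_diameter must be a single number >= 1")
  se <- ball_element(ball_diameter)
  er <- cpp_gray_erode(ch$values, se$dr, se$dc, se$h)
  bg <- cpp_gray_dilate(er, se$dr, se$dc, se$h)
  out <- pmax(ch$values - bg, 0)
  dim(out) <- dim(ch$values)
  ch$values <- out
  append_provenance(ch, sprintf("rolling_ball(diameter=%g)", ball_diameter))
}

#' Automatic global thresholding
#'
#' `method = "mean"` uses the arithmetic mean of all pixel values as the
#' threshold (the FIJI "Mean" auto threshold); `method = "isodata"` iterates
#' the intermeans rule t <- (mean below t + mean above t) / 2 to a fixed
#' point (the ImageJ "Default"/isodata family). The mask is `values > t`.
#'
#' A constant image yields an empty mask under `"mean"` (no pixel exceeds
#' its own mean) and an error under `"isodata"`, which needs at least two
#' distinct values.
#'
#' @param ch a [channel()].
#' @param method `"isodata"` (default) or `"mean"`.
#' @return An [lq_mask()] whose provenance records the channel, method and
#'   the threshold actually computed.
#' @export
auto_threshold <- function(ch, method = c("isodata", "mean")) {
  stopifnot(inherits(ch, "channel"))
  method <- match.arg(method)
  v <- ch$values
  if (method == "mean") {
    t <- mean(v)
  } else {
    if (length(unique(as.vector(v))) < 2L)
      stopf("isodata threshold undefined: channel '%s' is constant", ch$name)
    t <- mean(v)
    for (i in 1:200) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (!length(hi) || !length(lo)) break
      t_new <- (mean(lo) + mean(hi)) / 2
      if (abs(t_new - t) < 1e-9 * max(1, abs(t))) { t <- t_new; break }
      t <- t_new
    }
  }
  lq_mask(v > t,
          provenance = c(ch$provenance,
                         sprintf("auto_threshold(channel=%s, method=%s, t=%.6g)",
                                 ch$name, method, t)))
}

label8 <- function(mask_values) cpp_label8(mask_values)

fill_holes <- function(mask_values) {
  f <- EBImage::fillHull(mask_values * 1L)
  f > 0
}

drop_small_components <- function(mask_values, min_px, strict = TRUE) {
  lab <- label8(mask_values)
  if (max(lab) == 0L) return(mask_values)
  area <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- if (strict) which(area >= min_px) else which(area > min_px)
  mask_values & (lab %in% keep & lab > 0L)
}

#' Cell-surface mask from a transfection or fill signal
#'
#' Thresholds a channel carrying a whole-cell signal (e.g. a transfected
#' fluorescent-protein fill), fills interior holes and removes speckle
#' components smaller than `min_component` pixels, yielding a mask of the
#' cellular surface.
#'
#' @param ch a [channel()].
#' @param method threshold method, as in [auto_threshold()].
#' @param min_component components with fewer than this many pixels are
#'   removed (default 50).
#' @return An [lq_mask()] with full provenance.
#' @export
mask_from_signal <- function(ch, method = c("isodata", "mean"),
                             min_component = 50) {
  method <- match.arg(method)
  m <- auto_threshold(ch, method)
  v <- fill_holes(m$values)
  v <- drop_small_components(v, min_component, strict = TRUE)
  lq_mask(v, provenance = c(m$provenance,
                            "fill_holes",
                            sprintf("drop_components(<%d px)", min_component)))
}
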