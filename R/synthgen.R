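#' Geometry parameters for the synthetic neuron field
#'
#' Defaults describe a dendritic field as imaged at high magnification:
#' 65 nm/pixel (so a 25-pixel object area corresponds to an equivalent
#' diameter of about 350 nm), a couple of neurons per 256 x 256 crop, 3
#' unbranched piecewise-linear dendrites each, and LAMP1-positive late
#' endosomes (LEs) rendered as disks of 3-6 px radius (equivalent
#' diameters roughly 0.4-0.8 um) scattered along dendrites and in somata.
#' Large-field somatic simulations (many neurons at ~325 nm/pixel, as from
#' a 20x sCMOS setup) are obtained by overriding `pixel_size`, `n_neurons`
#' and the size ranges.
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size nm per pixel (> 0).
#' @param n_neurons number of neurons in the field.
#' @param soma_radius_range (low, high) soma radius in pixels.
#' @param dendrites_per_neuron dendrites radiating from each soma.
#' @param dendrite_length_range (low, high) dendrite length in pixels.
#' @param dendrite_width_range (low, high) dendrite width in pixels.
#' @param n_les_per_100um_dendrite expected LE count per 100 um of
#'   dendrite length.
#' @param le_radius_range (low, high) LE radius in pixels.
#' @param n_les_per_soma expected LE count per soma.
#' @param le_annular if `TRUE`, LEs are rendered as annuli (donut-like
#'   limiting-membrane staining) rather than filled disks.
#' @param allow_le_overlap if `TRUE`, LE placement skips the
#'   non-overlap rejection step (stress-tests ring-exclusion logic).
#' @param seed RNG seed for geometry generation.
#' @return A validated list of class `"geometry_params"`.
#' @export
geometry_params <- function(image_shape = c(256L, 256L),
                            pixel_size = 65,
                            n_neurons = 2,
                            soma_radius_range = c(14, 20),
                            dendrites_per_neuron = 3,
                            dendrite_length_range = c(80, 150),
                            dendrite_width_range = c(5, 8),
                            n_les_per_100um_dendrite = 30,
                            le_radius_range = c(3, 6),
                            n_les_per_soma = 2,
                            le_annular = FALSE,
                            allow_le_overlap = FALSE,
                            seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            n_neurons = as.integer(n_neurons),
            soma_radius_range = soma_radius_range,
            dendrites_per_neuron = as.integer(dendrites_per_neuron),
            dendrite_length_range = dendrite_length_range,
            dendrite_width_range = dendrite_width_range,
            n_les_per_100um_dendrite = n_les_per_100um_dendrite,
            le_radius_range = le_radius_range,
            n_les_per_soma = n_les_per_soma,
            le_annular = isTRUE(le_annular),
            allow_le_overlap = isTRUE(allow_le_overlap),
            seed = as.integer(seed))
  for (nm in c("soma_radius_range", "dendrite_length_range",
               "dendrite_width_range", "le_radius_range")) {
    r <- p[[nm]]
    if (length(r) != 2L || r[1] > r[2] || any(r < 0))
      stopf("%s must be (low, high) with 0 <= low <= high", nm)
  }
  if (p$pixel_size <= 0) stopf("pixel_size must be > 0")
  if (p$n_neurons < 0 || p$dendrites_per_neuron < 0 ||
      p$n_les_per_100um_dendrite < 0 || p$n_les_per_soma < 0)
    stopf("counts and densities must be >= 0")
  if (p$n_neurons > 0 && p$soma_radius_range[2] > min(p$image_shape) / 2)
    stopf("soma radius %.1f px does not fit in a %d x %d image",
          p$soma_radius_range[2], p$image_shape[1], p$image_shape[2])
  class(p) <- "geometry_params"
  p
}

#' Photophysics parameters for rendering a synthetic field
#'
#' Intensities are in arbitrary photon-count-like units (rendered in
#' floating point; quantized to 16 bits only on file write). With
#' `poisson_noise = TRUE` each pixel is a Poisson draw with the noise-free
#' intensity as its mean, plus Gaussian read noise. `mtor_enrichment` is
#' the ground-truth IN/OUT analogue: the factor by which cytoplasmic mTOR
#' intensity is multiplied inside each LE (1 = no recruitment). The P-pS6
#' channel is bright in somata and decays exponentially along dendrite
#' arclength with decay length `pps6_dendrite_decay_length`; optional
#' discrete hot spots are Gaussian bumps in arclength whose amplitude is
#' `hotspot_amplitude` times the local dendritic baseline.
#'
#' @param background_level additive background intensity.
#' @param shading_amplitude amplitude of a smooth shading plane, as a
#'   fraction of `background_level`.
#' @param map2_intensity,lamp1_intensity,mtor_cytoplasm_intensity,pps6_soma_intensity
#'   stain intensities above background.
#' @param mtor_enrichment per-object IN/OUT ground-truth ratio (>= 0;
#'   1 = no recruitment). Used for every LE unless the ground truth
#'   carries a per-object map.
#' @param pps6_dendrite_decay_length exponential decay length (pixels) of
#'   dendritic P-pS6.
#' @param hotspot_positions list of `c(dendrite_id, arclength_fraction)`
#'   pairs placing P-pS6 hot spots.
#' @param hotspot_amplitude hot-spot amplitude as a multiple of the local
#'   dendritic baseline.
#' @param hotspot_width Gaussian sigma (pixels) of the hot spot along
#'   arclength.
#' @param psf_sigma isotropic Gaussian PSF sigma in pixels (0 = no blur).
#' @param poisson_noise apply Poisson shot noise?
#' @param gaussian_read_noise_sd additive Gaussian read-noise sd.
#' @param seed RNG seed for the noise draws.
#' @return A validated list of class `"photophysics_params"`.
#' @export
photophysics_params <- function(background_level = 100,
                                shading_amplitude = 0.1,
                                map2_intensity = 500,
                                lamp1_intensity = 900,
                                mtor_cytoplasm_intensity = 300,
                                pps6_soma_intensity = 600,
                                mtor_enrichment = 1,
                                pps6_dendrite_decay_length = 60,
                                hotspot_positions = list(),
                                hotspot_amplitude = 0,
                                hotspot_width = 4,
                                psf_sigma = 1,
                                poisson_noise = TRUE,
                                gaussian_read_noise_sd = 5,
                                seed = 1L) {
  p <- list(background_level = background_level,
            shading_amplitude = shading_amplitude,
            map2_intensity = map2_intensity,
            lamp1_intensity = lamp1_intensity,
            mtor_cytoplasm_intensity = mtor_cytoplasm_intensity,
            pps6_soma_intensity = pps6_soma_intensity,
            mtor_enrichment = mtor_enrichment,
            pps6_dendrite_decay_length = pps6_dendrite_decay_length,
            hotspot_positions = hotspot_positions,
            hotspot_amplitude = hotspot_amplitude,
            hotspot_width = hotspot_width,
            psf_sigma = psf_sigma,
            poisson_noise = isTRUE(poisson_noise),
            gaussian_read_noise_sd = gaussian_read_noise_sd,
            seed = as.integer(seed))
  if (p$mtor_enrichment < 0) stopf("mtor_enrichment must be >= 0")
  if (p$background_level < 0 || p$gaussian_read_noise_sd < 0)
    stopf("background_level and gaussian_read_noise_sd must be >= 0")
  if (p$pps6_dendrite_decay_length <= 0)
    stopf("pps6_dendrite_decay_length must be > 0")
  class(p) <- "photophysics_params"
  p
}

stamp_disk <- function(nr, nc, r0, c0, radius) {
  ri <- ceiling(radius)
  rows <- max(1, floor(r0 - ri)):min(nr, ceiling(r0 + ri))
  cols <- max(1, floor(c0 - ri)):min(nc, ceiling(c0 + ri))
  if (!length(rows) || !length(cols)) return(NULL)
  g <- expand.grid(r = rows, c = cols)
  d2 <- (g$r - r0)^2 + (g$c - c0)^2
  keep <- d2 <= radius^2
  out <- cbind(g$r[keep], g$c[keep])
  attr(out, "d2") <- d2[keep]
  out
}

#' Generate the geometry and ground truth of a synthetic neuron field
#'
#' Places `n_neurons` disk somata, grows unbranched piecewise-linear
#' dendrites with bounded turning angle radiating from each soma, and
#' scatters non-overlapping LE disks along dendrites and inside somata
#' (overlap can be allowed for stress tests). All placement is
#' deterministic for a fixed `params$seed`.
#'
#' @param params a [geometry_params()] object.
#' @return An object of class `"ground_truth"` with elements `map2_mask`
#'   ([lq_mask()]), `soma_labels` and `le_labels` ([labeled_objects()]),
#'   `dendrite_centerlines` (list of `id`, `soma_id`, `vertices` (n x 2
#'   row/col matrix), `width`, `length`), `per_le_enrichment` (`NULL`
#'   until assigned), `hotspot_truth` (empty data.frame until rendering),
#'   plus internal per-pixel arclength and dendrite-id maps used by the
#'   renderer.
#' @export
make_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  with_seed(params$seed, make_geometry_impl(params))
}

make_geometry_impl <- function(p) {
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  map2 <- matrix(FALSE, nr, nc)
  soma_lab <- matrix(0L, nr, nc)
  le_lab <- matrix(0L, nr, nc)
  arclen <- matrix(NA_real_, nr, nc)
  arclen_d2 <- matrix(Inf, nr, nc)  # distance to the assigning stamp center
  dend_id <- matrix(NA_integer_, nr, nc)
  centerlines <- list()
  le_centers <- NULL   # accepted LE centers (r, c, radius)

  # --- somata ---------------------------------------------------------
  soma_r <- numeric(0); soma_pos <- NULL
  if (p$n_neurons > 0) {
    margin <- p$soma_radius_range[2] + 2
    for (i in seq_len(p$n_neurons)) {
      r_i <- runif(1, p$soma_radius_range[1], p$soma_radius_range[2])
      placed <- FALSE
      for (try in 1:2000) {
        pos <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        sep_ok <- TRUE
        if (length(soma_r)) {
          d <- sqrt((soma_pos[, 1] - pos[1])^2 + (soma_pos[, 2] - pos[2])^2)
          sep_ok <- all(d > soma_r + r_i + 4)
        }
        if (sep_ok) { placed <- TRUE; break }
      }
      if (!placed)
        stopf("could not place %d non-overlapping somata in a %d x %d image",
              p$n_neurons, nr, nc)
      soma_r <- c(soma_r, r_i)
      soma_pos <- rbind(soma_pos, pos)
      px <- stamp_disk(nr, nc, pos[1], pos[2], r_i)
      map2[px] <- TRUE
      soma_lab[px] <- i
      arclen[px] <- 0
    }
  }

  # --- dendrites ------------------------------------------------------
  did <- 0L
  seg_len <- 10
  for (i in seq_len(p$n_neurons)) {
    k <- p$dendrites_per_neuron
    if (k == 0) next
    base <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi / k)
    for (j in seq_len(k)) {
      did <- did + 1L
      ang <- base[j] + runif(1, -pi / (3 * k), pi / (3 * k))
      L <- runif(1, p$dendrite_length_range[1], p$dendrite_length_range[2])
      w <- runif(1, p$dendrite_width_range[1], p$dendrite_width_range[2])
      pt <- soma_pos[i, ] + soma_r[i] * c(cos(ang), sin(ang))
      verts <- matrix(pt, 1, 2)
      s <- 0
      inside <- function(p) p[1] >= 3 && p[1] <= nr - 2 && p[2] >= 3 &&
        p[2] <= nc - 2
      while (s < L) {
        step <- min(seg_len, L - s)
        nxt <- pt + step * c(cos(ang), sin(ang))
        if (!inside(nxt)) {
          # steer back toward the field center, one bounded turn per try
          to_ctr <- atan2(nc / 2 - pt[2], nr / 2 - pt[1])
          turn <- sign(sin(to_ctr - ang)) * pi / 9
          if (turn == 0) turn <- pi / 9
          ok <- FALSE
          for (k in 1:9) {
            ang <- ang + turn
            nxt <- pt + step * c(cos(ang), sin(ang))
            if (inside(nxt)) { ok <- TRUE; break }
          }
          if (!ok) break  # cornered: truncate
        }
        verts <- rbind(verts, nxt)
        pt <- nxt
        s <- s + step
        ang <- ang + runif(1, -pi / 9, pi / 9)  # bounded turning (<= 20 deg)
      }
      if (nrow(verts) < 2) { did <- did - 1L; next }
      # rasterize as overlapping disks along the centerline
      cum <- 0
      for (v in seq_len(nrow(verts) - 1)) {
        a <- verts[v, ]; b <- verts[v + 1, ]
        seg <- sqrt(sum((b - a)^2))
        ts <- seq(0, seg, by = 0.5)
        for (t in ts) {
          q <- a + (b - a) * (t / seg)
          px <- stamp_disk(nr, nc, q[1], q[2], w / 2)
          if (is.null(px) || nrow(px) == 0L) next
          map2[px] <- TRUE
          s_here <- cum + t
          # arclength of the nearest stamp center, so the along-path
          # coordinate is unbiased across the tube cross-section
          d2 <- attr(px, "d2")
          upd <- arclen_d2[px] > d2
          arclen[px][upd] <- s_here
          arclen_d2[px][upd] <- d2[upd]
          dend_id[px][upd] <- did
        }
        cum <- cum + seg
      }
      centerlines[[did]] <- list(id = did, soma_id = i, vertices = verts,
                                 width = w, length = cum)
    }
  }

  # --- late endosomes -------------------------------------------------
  next_le <- 0L
  add_le <- function(r0, c0, radius) {
    if (!p$allow_le_overlap && !is.null(le_centers)) {
      d <- sqrt((le_centers[, 1] - r0)^2 + (le_centers[, 2] - c0)^2)
      if (any(d <= le_centers[, 3] + radius + 1)) return(FALSE)
    }
    rr <- round(r0); cc <- round(c0)
    if (rr < 1 || rr > nr || cc < 1 || cc > nc || !map2[rr, cc]) return(FALSE)
    px <- stamp_disk(nr, nc, r0, c0, radius)
    if (is.null(px) || nrow(px) == 0L || !all(map2[px])) return(FALSE)
    next_le <<- next_le + 1L
    if (p$le_annular) {
      inner <- stamp_disk(nr, nc, r0, c0, radius * 0.5)
      keep <- !(paste(px[, 1], px[, 2]) %in% paste(inner[, 1], inner[, 2]))
      px <- px[keep, , drop = FALSE]
    }
    le_lab[px] <<- next_le
    le_centers <<- rbind(le_centers, c(r0, c0, radius))
    TRUE
  }
  # along dendrites
  for (d in centerlines) {
    len_um <- d$length * p$pixel_size / 1000
    n_le <- rpois(1, p$n_les_per_100um_dendrite * len_um / 100)
    tries <- 0
    while (n_le > 0 && tries < 50 * n_le + 200) {
      tries <- tries + 1
      s0 <- runif(1, 0, d$length)
      pos <- point_at_arclength(d$vertices, s0)
      jit <- runif(2, -d$width / 4, d$width / 4)
      rad <- runif(1, p$le_radius_range[1], p$le_radius_range[2])
      if (add_le(pos[1] + jit[1], pos[2] + jit[2], rad)) n_le <- n_le - 1
    }
  }
  # in somata
  for (i in seq_len(p$n_neurons)) {
    n_le <- rpois(1, p$n_les_per_soma)
    tries <- 0
    while (n_le > 0 && tries < 50 * n_le + 200) {
      tries <- tries + 1
      rad <- runif(1, p$le_radius_range[1], p$le_radius_range[2])
      rho <- runif(1, 0, max(soma_r[i] - rad - 1, 0))
      th <- runif(1, 0, 2 * pi)
      if (add_le(soma_pos[i, 1] + rho * cos(th),
                 soma_pos[i, 2] + rho * sin(th), rad)) n_le <- n_le - 1
    }
  }

  structure(list(
    map2_mask = lq_mask(map2, provenance = "synthgen:ground_truth"),
    soma_labels = labeled_objects(soma_lab, p$pixel_size,
                                  provenance = "synthgen:ground_truth"),
    le_labels = labeled_objects(le_lab, p$pixel_size,
                                provenance = "synthgen:ground_truth"),
    dendrite_centerlines = centerlines,
    per_le_enrichment = NULL,
    hotspot_truth = data.frame(dendrite_id = integer(),
                               arclength_px = numeric()),
    arclength_map = arclen,
    dendrite_id_map = dend_id,
    params = p), class = "ground_truth")
}

# point on a polyline at a given arclength from its start
point_at_arclength <- function(verts, s) {
  for (v in seq_len(nrow(verts) - 1)) {
    a <- verts[v, ]; b <- verts[v + 1, ]
    seg <- sqrt(sum((b - a)^2))
    if (s <= seg || v == nrow(verts) - 1) {
      t <- if (seg > 0) min(s, seg) / seg else 0
      return(a + (b - a) * t)
    }
    s <- s - seg
  }
  verts[nrow(verts), ]
}

#' Assign per-object LE enrichment factors to a ground truth
#'
#' @param truth a `"ground_truth"` from [make_geometry()].
#' @param enrichment a scalar recycled over all LEs, or a vector with one
#'   value per LE object.
#' @return The truth with `per_le_enrichment` set (named by object id).
#' @export
assign_enrichment <- function(truth, enrichment) {
  stopifnot(inherits(truth, "ground_truth"))
  ids <- truth$le_labels$objects$id
  if (length(enrichment) == 1L) enrichment <- rep(enrichment, length(ids))
  if (length(enrichment) != length(ids))
    stopf("enrichment must be scalar or one value per LE (%d)", length(ids))
  if (any(enrichment < 0)) stopf("enrichment must be >= 0")
  truth$per_le_enrichment <- stats::setNames(as.numeric(enrichment),
                                             as.character(ids))
  truth
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  g <- dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

#' Render a synthetic multi-channel field from geometry and photophysics
#'
#' Channel construction (before PSF blur and noise):
#' * `MAP2` = background + shading plane + `map2_intensity` on the
#'   MAP2 mask;
#' * `LAMP1` = background + `lamp1_intensity` on LE objects;
#' * `mTOR` = background + `mtor_cytoplasm_intensity` on the MAP2 mask,
#'   multiplied by the per-object enrichment inside each LE;
#' * `P-pS6` = background + `pps6_soma_intensity` in somata, decaying
#'   exponentially along dendrite arclength, plus Gaussian hot-spot bumps.
#'
#' The noise-free render is fully deterministic; Poisson and read noise
#' (if enabled) depend only on `phys$seed`.
#'
#' @param truth a `"ground_truth"`; if `per_le_enrichment` is unset,
#'   `phys$mtor_enrichment` is applied to every LE.
#' @param phys a [photophysics_params()] object.
#' @return An [mc_image()] with channels `MAP2`, `LAMP1`, `mTOR`, `PpS6`.
#' @export
render <- function(truth, phys) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(phys, "photophysics_params"))
  if (is.null(truth$per_le_enrichment))
    truth <- assign_enrichment(truth, phys$mtor_enrichment)
  nr <- nrow(truth$map2_mask$values); nc <- ncol(truth$map2_mask$values)
  bg <- phys$background_level
  shade <- bg * phys$shading_amplitude *
    (outer(seq(-1, 1, length.out = nr), seq(-1, 1, length.out = nc), "+") / 2)
  map2m <- truth$map2_mask$values
  le <- truth$le_labels$labels
  soma <- truth$soma_labels$labels

  ch_map2 <- bg + shade + phys$map2_intensity * map2m
  ch_lamp1 <- bg + phys$lamp1_intensity * (le > 0L)
  enr <- matrix(1, nr, nc)
  if (length(truth$per_le_enrichment)) {
    pos <- le > 0L
    enr[pos] <- truth$per_le_enrichment[as.character(le[pos])]
  }
  ch_mtor <- bg + phys$mtor_cytoplasm_intensity * map2m * enr

  ch_pps6 <- matrix(bg, nr, nc)
  ch_pps6[soma > 0L] <- bg + phys$pps6_soma_intensity
  dpx <- !is.na(truth$arclength_map) & soma == 0L & map2m
  ch_pps6[dpx] <- bg + phys$pps6_soma_intensity *
    exp(-truth$arclength_map[dpx] / phys$pps6_dendrite_decay_length)

  hs_truth <- data.frame(dendrite_id = integer(), arclength_px = numeric())
  if (length(phys$hotspot_positions) && phys$hotspot_amplitude > 0) {
    for (hp in phys$hotspot_positions) {
      d_id <- as.integer(hp[1]); frac <- hp[2]
      if (d_id < 1 || d_id > length(truth$dendrite_centerlines)) next
      d <- truth$dendrite_centerlines[[d_id]]
      s0 <- frac * d$length
      base <- phys$pps6_soma_intensity *
        exp(-s0 / phys$pps6_dendrite_decay_length)
      on_d <- which(!is.na(truth$dendrite_id_map) &
                      truth$dendrite_id_map == d_id)
      ds <- truth$arclength_map[on_d] - s0
      ch_pps6[on_d] <- ch_pps6[on_d] + phys$hotspot_amplitude * base *
        exp(-ds^2 / (2 * phys$hotspot_width^2))
      hs_truth <- rbind(hs_truth,
                        data.frame(dendrite_id = d_id, arclength_px = s0))
    }
  }

  chans <- list(MAP2 = ch_map2, LAMP1 = ch_lamp1, mTOR = ch_mtor,
                PpS6 = ch_pps6)
  if (phys$psf_sigma > 0)
    chans <- lapply(chans, gaussian_blur, sigma = phys$psf_sigma)
  if (phys$poisson_noise || phys$gaussian_read_noise_sd > 0) {
    chans <- with_seed(phys$seed, lapply(chans, function(x) {
      v <- as.vector(x)
      if (phys$poisson_noise) v <- rpois(length(v), pmax(v, 0))
      if (phys$gaussian_read_noise_sd > 0)
        v <- v + rnorm(length(v), 0, phys$gaussian_read_noise_sd)
      matrix(pmax(v, 0), nrow(x), ncol(x))
    }))
  }
  img <- mc_image(chans, truth$params$pixel_size)
  attr(img, "hotspot_truth") <- hs_truth
  img
}

#' Generate and render one synthetic field in a single call
#'
#' @param geom a [geometry_params()] object.
#' @param phys a [photophysics_params()] object.
#' @param image_id identifier attached to the rendered image.
#' @return A list with `image` (an [mc_image()]) and `truth` (the
#'   `"ground_truth"` with `per_le_enrichment` and `hotspot_truth`
#'   populated).
#' @export
simulate_field <- function(geom, phys, image_id = "synth") {
  truth <- make_geometry(geom)
  truth <- assign_enrichment(truth, phys$mtor_enrichment)
  img <- render(truth, phys)
  img$image_id <- image_id
  truth$hotspot_truth <- attr(img, "hotspot_truth")
  attr(img, "hotspot_truth") <- NULL
  list(image = img, truth = truth)
}
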