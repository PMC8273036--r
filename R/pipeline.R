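#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipelines; the defaults are the
#' published protocol values: rolling-ball diameter 50 px for P-pS6 and
#' 75 px for mTOR images, LE minimum area 25 px (strictly above), ring
#' gap 6 px and width 4 px, mean auto threshold for MAP2 and isodata
#' elsewhere.
#'
#' @param pixel_size nm/pixel of the input images.
#' @param rolling_ball_diameter_pps6 rolling-ball diameter for P-pS6.
#' @param rolling_ball_diameter_mtor rolling-ball diameter for mTOR (and
#'   LAMP1 prior to segmentation).
#' @param le_min_area LE size filter (area strictly above this survives).
#' @param ring_gap,ring_width OUT-ring geometry in pixels.
#' @param map2_threshold threshold method for the MAP2 mask.
#' @param threshold_method default threshold method elsewhere.
#' @param min_soma_area minimum soma area in pixels.
#' @param seed RNG seed from which all pipeline randomness flows.
#' @param output_dir default output directory.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(pixel_size = 65,
                       rolling_ball_diameter_pps6 = 50,
                       rolling_ball_diameter_mtor = 75,
                       le_min_area = 25,
                       ring_gap = 6,
                       ring_width = 4,
                       map2_threshold = "mean",
                       threshold_method = "isodata",
                       min_soma_area = 200,
                       seed = 1L,
                       output_dir = ".") {
  structure(list(pixel_size = pixel_size,
                 rolling_ball_diameter_pps6 = rolling_ball_diameter_pps6,
                 rolling_ball_diameter_mtor = rolling_ball_diameter_mtor,
                 le_min_area = le_min_area, ring_gap = ring_gap,
                 ring_width = ring_width, map2_threshold = map2_threshold,
                 threshold_method = threshold_method,
                 min_soma_area = min_soma_area, seed = as.integer(seed),
                 output_dir = output_dir), class = "run_config")
}

# FNV-1a hash of the analysis parameters (output location excluded), for
# the reproducibility header
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$output_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Deterministic, pinned-format CSV with a reproducibility comment header.
write_result_csv <- function(df, path, cfg, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# lequant %s", as.character(packageVersion("lequant"))),
    sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# seed: %d", seed)), con)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.10g", df[[j]])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_result_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Simulate a set of fixture fields grouped by condition
#'
#' Writes `n_images` synthetic fields per condition (each condition is a
#' named ground-truth enrichment factor), with TIFF channels, truth
#' sidecars and a manifest CSV. Per-image seeds are drawn from
#' `config$seed`, so the whole fixture set is deterministic.
#'
#' @param out_dir output directory.
#' @param n_images images per condition.
#' @param conditions named numeric vector: condition name -> ground-truth
#'   mTOR enrichment.
#' @param geom a [geometry_params()] template (its seed is overridden
#'   per image).
#' @param phys a [photophysics_params()] template (enrichment and seed
#'   overridden per image).
#' @param config a [run_config()]; supplies the master seed.
#' @return Invisibly, the manifest data.frame (also written to
#'   `manifest.csv`).
#' @export
simulate_fixtures <- function(out_dir, n_images, conditions,
                              geom = geometry_params(),
                              phys = photophysics_params(),
                              config = run_config()) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stopf("conditions must be a named numeric vector")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_total <- n_images * length(conditions)
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, 2L * n_total))
  rows <- list()
  k <- 0L
  for (cond in names(conditions)) {
    for (i in seq_len(n_images)) {
      k <- k + 1L
      g <- geom; g$seed <- seeds[2L * k - 1L]
      p <- phys; p$seed <- seeds[2L * k]
      p$mtor_enrichment <- unname(conditions[[cond]])
      id <- sprintf("%s_%03d", cond, i)
      sim <- simulate_field(g, p, image_id = id)
      write_fixture(sim$image, sim$truth, out_dir, stem = id)
      rows[[k]] <- data.frame(image_id = id, condition = cond,
                              stem = id,
                              enrichment = p$mtor_enrichment,
                              geometry_seed = g$seed, noise_seed = p$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  write_result_csv(manifest, file.path(out_dir, "manifest.csv"), config,
                   config$seed)
  invisible(manifest)
}

load_manifest <- function(manifest) {
  if (is.data.frame(manifest)) return(manifest)
  read_result_csv(manifest)
}

#' Recruitment pipeline: IN/OUT ratio for every image of a manifest
#'
#' For each manifest row: read the fixture, rolling-ball-subtract the mTOR
#' and LAMP1 channels (diameter `config$rolling_ball_diameter_mtor`),
#' build the dendrite mask from MAP2 (mean auto threshold, somata removed
#' using the truth labels when available), segment LEs, build the IN/OUT
#' ring masks, and measure the ratio. Unreadable or incomplete images are
#' skipped with a logged reason and the run continues.
#'
#' @param fixture_dir directory holding the fixtures.
#' @param manifest manifest data.frame or path to `manifest.csv`.
#' @param config a [run_config()].
#' @param out_dir where to write `recruitment_results.csv`,
#'   `recruitment_summary.csv` and the comparison report (default:
#'   `config$output_dir`; `NULL` suppresses file output).
#' @return A list with `results` (per-image data.frame), `summary`
#'   (per-condition mean, SEM, n) and `comparison` (a
#'   `"group_comparison"` across conditions, or `NULL` if fewer than two
#'   conditions have enough valid images).
#' @export
analyze_recruitment <- function(fixture_dir, manifest, config = run_config(),
                                out_dir = config$output_dir) {
  manifest <- load_manifest(manifest)
  results <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      fx <- read_fixture(fixture_dir, row$stem)
      needed <- c("MAP2", "LAMP1", "mTOR")
      if (!all(needed %in% names(fx$image$channels)))
        stopf("missing channel(s): %s",
              paste(setdiff(needed, names(fx$image$channels)), collapse = ", "))
      mtor <- rolling_ball_subtract(get_channel(fx$image, "mTOR"),
                                    config$rolling_ball_diameter_mtor)
      lamp1 <- rolling_ball_subtract(get_channel(fx$image, "LAMP1"),
                                     config$rolling_ball_diameter_mtor)
      map2 <- get_channel(fx$image, "MAP2")
      dmask <- auto_threshold(map2, config$map2_threshold)
      if (!is.null(fx$truth)) dmask <- remove_somas(dmask, fx$truth$soma_labels)
      les <- segment_les(lamp1, min_area = config$le_min_area)
      masks <- build_in_out(les, dmask, gap = config$ring_gap,
                            width = config$ring_width)
      in_out_ratio(mtor, masks, image_id = row$image_id,
                   condition = row$condition)
    }, error = function(e) {
      message(sprintf("skipping image '%s': %s", row$image_id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  tab <- if (length(results)) recruitment_table(results) else
    data.frame(image_id = character(), condition = character(),
               mean_in = numeric(), mean_out = numeric(), ratio = numeric(),
               n_in_pixels = integer(), n_out_pixels = integer(),
               n_objects = integer(), valid = logical(), reason = character())
  valid <- tab[tab$valid, , drop = FALSE]
  summ <- if (nrow(valid)) {
    sp <- split(valid$ratio, valid$condition)
    data.frame(condition = names(sp),
               mean_ratio = vapply(sp, mean, numeric(1)),
               sem = vapply(sp, function(v)
                 if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                 numeric(1)),
               n = lengths(sp), row.names = NULL)
  } else data.frame(condition = character(), mean_ratio = numeric(),
                    sem = numeric(), n = integer())
  comparison <- NULL
  sp <- split(valid$ratio, valid$condition)
  sp <- sp[lengths(sp) >= 3L]
  if (length(sp) == 2L) comparison <- compare_two(sp[[1]], sp[[2]],
                                                  names = names(sp))
  if (length(sp) >= 3L) comparison <- compare_many(sp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(tab, file.path(out_dir, "recruitment_results.csv"),
                     config, config$seed)
    write_result_csv(summ, file.path(out_dir, "recruitment_summary.csv"),
                     config, config$seed)
    if (!is.null(comparison))
      writeLines(utils::capture.output(print(comparison)),
                 file.path(out_dir, "recruitment_comparison.txt"))
  }
  list(results = tab, summary = summ, comparison = comparison)
}

#' Activity pipeline: compartmentalized P-pS6 readout for a manifest
#'
#' For each manifest row: read the fixture, rolling-ball-subtract the
#' P-pS6 channel (diameter `config$rolling_ball_diameter_pps6`), build the
#' MAP2 mask, segment somata from the P-pS6 image, and compute the field
#' activity table and per-soma intensities. When `control_condition` is
#' present, a percentile-shift summary (75th percentile of the control
#' per-soma distribution) is computed against every other condition, and
#' group comparisons are run on per-field whole-neuron means.
#'
#' @param fixture_dir directory holding the fixtures.
#' @param manifest manifest data.frame or path to `manifest.csv`.
#' @param config a [run_config()].
#' @param control_condition name of the control condition (default: first
#'   condition in the manifest).
#' @param q percentile for the shift analysis (default 75).
#' @param out_dir as in [analyze_recruitment()].
#' @return A list with `fields` (per-field activity data.frame), `somas`
#'   (per-soma data.frame), `percentile_shift` (data.frame, one row per
#'   non-control condition) and `comparison`.
#' @export
analyze_activity <- function(fixture_dir, manifest, config = run_config(),
                             control_condition = NULL, q = 75,
                             out_dir = config$output_dir) {
  manifest <- load_manifest(manifest)
  if (is.null(control_condition)) control_condition <- manifest$condition[1]
  fields <- list(); somas <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    ok <- tryCatch({
      fx <- read_fixture(fixture_dir, row$stem)
      needed <- c("MAP2", "PpS6")
      if (!all(needed %in% names(fx$image$channels)))
        stopf("missing channel(s): %s",
              paste(setdiff(needed, names(fx$image$channels)), collapse = ", "))
      pps6 <- rolling_ball_subtract(get_channel(fx$image, "PpS6"),
                                    config$rolling_ball_diameter_pps6)
      map2 <- auto_threshold(get_channel(fx$image, "MAP2"),
                             config$map2_threshold)
      sl <- segment_somas(pps6, map2, min_soma_area = config$min_soma_area)
      soma_mask <- lq_mask(sl$labels > 0L, provenance = sl$provenance)
      fields[[length(fields) + 1L]] <-
        field_activity(pps6, map2, soma_mask, image_id = row$image_id,
                       condition = row$condition)
      somas[[length(somas) + 1L]] <-
        per_soma_intensities(pps6, sl, image_id = row$image_id,
                             condition = row$condition)
      TRUE
    }, error = function(e) {
      message(sprintf("skipping image '%s': %s", row$image_id,
                      conditionMessage(e)))
      FALSE
    })
  }
  field_tab <- if (length(fields)) activity_table(fields) else
    data.frame(image_id = character(), condition = character(),
               mean_whole = numeric(), mean_soma = numeric(),
               mean_dendrite = numeric(), area_whole = integer(),
               area_soma = integer(), area_dendrite = integer(),
               valid = logical(), reason = character())
  soma_tab <- do.call(rbind, somas)
  shift <- NULL
  if (!is.null(soma_tab) && nrow(soma_tab) &&
      control_condition %in% soma_tab$condition) {
    ctrl <- soma_tab$mean_intensity[soma_tab$condition == control_condition]
    others <- setdiff(unique(soma_tab$condition), control_condition)
    shift <- do.call(rbind, lapply(others, function(cond) {
      tr <- soma_tab$mean_intensity[soma_tab$condition == cond]
      ps <- percentile_shift(ctrl, tr, q = q)
      data.frame(control = control_condition, treated = cond, q = q,
                 threshold = ps$threshold,
                 fraction_above = ps$fraction_above,
                 n_control = ps$n_control, n_treated = ps$n_treated)
    }))
  }
  comparison <- NULL
  valid <- field_tab[field_tab$valid, , drop = FALSE]
  sp <- split(valid$mean_whole, valid$condition)
  sp <- sp[lengths(sp) >= 3L]
  if (length(sp) == 2L) comparison <- compare_two(sp[[1]], sp[[2]],
                                                  names = names(sp))
  if (length(sp) >= 3L) comparison <- compare_many(sp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(field_tab, file.path(out_dir, "activity_fields.csv"),
                     config, config$seed)
    if (!is.null(soma_tab) && nrow(soma_tab))
      write_result_csv(soma_tab, file.path(out_dir, "activity_somas.csv"),
                       config, config$seed)
    if (!is.null(shift))
      write_result_csv(shift, file.path(out_dir, "activity_percentile_shift.csv"),
                       config, config$seed)
    if (!is.null(comparison))
      writeLines(utils::capture.output(print(comparison)),
                 file.path(out_dir, "activity_comparison.txt"))
  }
  list(fields = field_tab, somas = soma_tab, percentile_shift = shift,
       comparison = comparison)
}

#' Write a PNG quality-control overlay of masks over a channel
#'
#' Renders the channel in gray with the IN mask in green and the OUT ring
#' in magenta, for visual auditing of the segmentation.
#'
#' @param ch a [channel()].
#' @param masks an `"in_out_masks"`.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
write_qc_overlay <- function(ch, masks, path) {
  v <- ch$values
  rng <- range(v)
  g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  rgb <- array(0, c(nrow(v), ncol(v), 3))
  rgb[, , 1] <- rgb[, , 2] <- rgb[, , 3] <- g
  im <- masks$in_mask$values; om <- masks$out_mask$values
  rgb[, , 1][im] <- 0; rgb[, , 2][im] <- 1; rgb[, , 3][im] <- 0
  rgb[, , 1][om] <- 1; rgb[, , 2][om] <- 0; rgb[, , 3][om] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}
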