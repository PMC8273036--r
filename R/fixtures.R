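TRUTH_SCHEMA_VERSION <- 1L

quantize16 <- function(x, what = "channel") {
  if (any(x > 65535)) {
    warnf("%s contains values above 65535; clipping at the 16-bit maximum",
          what)
    x <- pmin(x, 65535)
  }
  pmax(round(x), 0) / 65535
}

write_tiff16 <- function(pages, path) {
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e)
                   stopf("failed to write TIFF '%s': %s", path,
                         conditionMessage(e)))
  invisible(ok)
}

read_tiff16 <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stopf("failed to read TIFF '%s': %s", path,
                            conditionMessage(e)))
  lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "double"
    m
  })
}

#' Write a rendered field and its ground truth to disk
#'
#' Channels are quantized to unsigned 16 bits (values above 65535 are
#' clipped with a warning) and written either as one multi-page TIFF or as
#' one TIFF per channel. The ground truth goes to a JSON sidecar
#' (schema-versioned) holding scalars, per-object tables, centerlines and
#' the enrichment map, plus a multi-page 16-bit label TIFF for the MAP2
#' mask, soma labels and LE labels. [read_fixture()] round-trips the set.
#'
#' @param image an [mc_image()].
#' @param truth the matching `"ground_truth"` (may be `NULL` for truthless
#'   fixtures).
#' @param directory output directory (created if missing).
#' @param stem file-name stem; defaults to the image id.
#' @param multipage write one multi-page TIFF (default) instead of one
#'   file per channel.
#' @return Invisibly, a named list of the files written.
#' @export
write_fixture <- function(image, truth, directory,
                          stem = image$image_id, multipage = TRUE) {
  stopifnot(inherits(image, "mc_image"))
  if (!nzchar(stem)) stem <- "field"
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory '%s'", directory)
  files <- list()
  if (multipage) {
    path <- file.path(directory, paste0(stem, "_channels.tif"))
    write_tiff16(lapply(image$channels, quantize16), path)
    files$channels <- path
  } else {
    files$channels <- character()
    for (nm in names(image$channels)) {
      path <- file.path(directory, paste0(stem, "_", nm, ".tif"))
      write_tiff16(list(quantize16(image$channels[[nm]], nm)), path)
      files$channels <- c(files$channels, path)
    }
  }
  meta <- list(schema_version = TRUTH_SCHEMA_VERSION,
               image_id = image$image_id,
               pixel_size = image$pixel_size,
               channel_names = names(image$channels),
               multipage = multipage)
  if (!is.null(truth)) {
    lab_path <- file.path(directory, paste0(stem, "_truth_labels.tif"))
    write_tiff16(list(quantize16(truth$map2_mask$values * 1),
                      quantize16(truth$soma_labels$labels),
                      quantize16(truth$le_labels$labels)), lab_path)
    files$labels <- lab_path
    meta$truth <- list(
      per_le_enrichment = as.list(truth$per_le_enrichment),
      hotspot_truth = truth$hotspot_truth,
      soma_objects = truth$soma_labels$objects,
      le_objects = truth$le_labels$objects,
      dendrite_centerlines = lapply(truth$dendrite_centerlines, function(d)
        list(id = d$id, soma_id = d$soma_id, width = d$width,
             length = d$length,
             vertices = unname(apply(d$vertices, 1, c, simplify = FALSE)))))
  }
  json_path <- file.path(directory, paste0(stem, "_truth.json"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$sidecar <- json_path
  invisible(files)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @param stem file-name stem used at write time.
#' @return A list with `image` (an [mc_image()]; intensities on the
#'   original scale) and `truth` (a `"ground_truth"` rebuilt from the
#'   sidecar and label TIFF, or `NULL` if the fixture has no truth).
#' @export
read_fixture <- function(directory, stem) {
  json_path <- file.path(directory, paste0(stem, "_truth.json"))
  if (!file.exists(json_path)) stopf("no sidecar found at '%s'", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), TRUTH_SCHEMA_VERSION))
    stopf("unsupported truth schema version %s in '%s'",
          meta$schema_version, json_path)
  if (isTRUE(meta$multipage)) {
    pages <- read_tiff16(file.path(directory, paste0(stem, "_channels.tif")))
    names(pages) <- meta$channel_names
  } else {
    pages <- lapply(meta$channel_names, function(nm)
      read_tiff16(file.path(directory, paste0(stem, "_", nm, ".tif")))[[1]])
    names(pages) <- meta$channel_names
  }
  img <- mc_image(pages, meta$pixel_size, image_id = meta$image_id)
  truth <- NULL
  if (!is.null(meta$truth)) {
    lab <- read_tiff16(file.path(directory, paste0(stem, "_truth_labels.tif")))
    soma <- lab[[2]]; storage.mode(soma) <- "integer"
    les <- lab[[3]]; storage.mode(les) <- "integer"
    enr <- unlist(meta$truth$per_le_enrichment)
    if (is.null(enr)) enr <- stats::setNames(numeric(0), character(0))
    as_vertex_matrix <- function(v) {
      if (is.matrix(v)) v else do.call(rbind, v)
    }
    cl_raw <- meta$truth$dendrite_centerlines
    cl <- if (is.data.frame(cl_raw)) {
      lapply(seq_len(nrow(cl_raw)), function(i)
        list(id = cl_raw$id[i], soma_id = cl_raw$soma_id[i],
             width = cl_raw$width[i], length = cl_raw$length[i],
             vertices = as_vertex_matrix(cl_raw$vertices[[i]])))
    } else {
      lapply(cl_raw, function(d)
        list(id = d$id, soma_id = d$soma_id, width = d$width,
             length = d$length, vertices = as_vertex_matrix(d$vertices)))
    }
    hs <- as.data.frame(meta$truth$hotspot_truth)
    if (!nrow(hs) || !ncol(hs))
      hs <- data.frame(dendrite_id = integer(), arclength_px = numeric())
    truth <- structure(list(
      map2_mask = lq_mask(lab[[1]] > 0, provenance = "fixture:truth"),
      soma_labels = labeled_objects(soma, meta$pixel_size,
                                    provenance = "fixture:truth"),
      le_labels = labeled_objects(les, meta$pixel_size,
                                  provenance = "fixture:truth"),
      dendrite_centerlines = cl,
      per_le_enrichment = enr,
      hotspot_truth = hs,
      arclength_map = NULL, dendrite_id_map = NULL,
      params = NULL), class = "ground_truth")
  }
  list(image = img, truth = truth)
}
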