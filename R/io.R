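# Readers and writers binding the pipeline stages: paired PNG/TIFF scenes,
# indexed-label instance maps, growth-series CSVs, YAML run configuration
# and JSON manifests. Masks are 8-bit PNG with {0, 255}; label maps 8-bit
# indexed PNG (at most 255 instances per scene, far above any leaf count);
# the infrared channel a single-channel 16-bit TIFF. Coordinates are
# 0-based, row-major, origin top-left in all on-disk metadata.

#' Write a synthetic scene to disk
#'
#' Writes `<id>_rgb.png` (8-bit), `<id>_ir.tif` (single-channel 16-bit),
#' `<id>_mask.png` (0/255) and `<id>_labels.png` (8-bit indexed labels,
#' at most 255 instances).
#'
#' @param scene A `rifseg_scene` from [generate_scene()].
#' @param dir Output directory (created if missing).
#' @param id Basename stem.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_scene <- function(scene, dir, id = "scene001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rgb = file.path(dir, paste0(id, "_rgb.png")),
             ir = file.path(dir, paste0(id, "_ir.tif")),
             mask = file.path(dir, paste0(id, "_mask.png")),
             labels = file.path(dir, paste0(id, "_labels.png")))
  png::writePNG(scene$rgb / 255, paths["rgb"])
  tiff::writeTIFF(scene$ir, paths["ir"], bits.per.sample = 16)
  png::writePNG(scene$mask * 1.0, paths["mask"])
  if (max(scene$labelmap) > 255) {
    stop_rifseg("label maps support at most 255 instances per scene",
                "rifseg_invalid_input")
  }
  png::writePNG(scene$labelmap / 255, paths["labels"])
  invisible(paths)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir Directory.
#' @param id Basename stem.
#' @return List with `rgb` (`[0, 255]`), `ir` (`[0, 1]`), `mask` (0/1) and
#'   `labelmap` (integer) — the labels file is optional.
#' @export
read_scene <- function(dir, id) {
  rgb <- png::readPNG(file.path(dir, paste0(id, "_rgb.png"))) * 255
  ir <- tiff::readTIFF(file.path(dir, paste0(id, "_ir.tif")))
  if (length(dim(ir)) == 3L) ir <- ir[, , 1]
  mask_path <- file.path(dir, paste0(id, "_mask.png"))
  mask <- if (file.exists(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  } else NULL
  lab_path <- file.path(dir, paste0(id, "_labels.png"))
  labelmap <- if (file.exists(lab_path)) {
    l <- png::readPNG(lab_path)
    if (length(dim(l)) == 3L) l <- l[, , 1]
    matrix(as.integer(round(l * 255)), nrow(l), ncol(l))
  } else NULL
  list(rgb = rgb, ir = ir, mask = mask, labelmap = labelmap)
}

#' Write / read a predicted binary mask
#'
#' @param mask 0/1 matrix.
#' @param path PNG path.
#' @return `write_mask` the path, `read_mask` the 0/1 integer matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write / read growth series CSV
#'
#' Columns `genotype_id`, `thermal_time_Cd`, `canopy_cover`; UTF-8 with a
#' header row. A comment line records the config hash and seed when given.
#'
#' @param series Data frame with the three columns.
#' @param path CSV path.
#' @param seed,hash Optional provenance recorded in a leading comment line.
#' @return The path / the data frame.
#' @export
write_growth_csv <- function(series, path, seed = NULL, hash = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed) || !is.null(hash)) {
    writeLines(sprintf("# rifseg growth series; seed=%s; config=%s",
                       seed %||% "NA", hash %||% "NA"), con)
  }
  write.csv(series[, c("genotype_id", "thermal_time_Cd", "canopy_cover")],
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' All tunables of the pipeline in one YAML-serializable list: network
#' backbone and input size, probability threshold, loss hyperparameters,
#' thermal-time accumulation, instance-filter area, and seeds.
#'
#' @param ... Overrides of the defaults (partial matching is not used; give
#'   full names).
#' @return Named list of class `rifseg_config`.
#' @export
rifseg_config <- function(...) {
  cfg <- list(backbone_depth = 18L, input_size = c(96L, 96L),
              fusion = "multi", threshold = 0.5,
              phi = 10, lambda_sup = NULL,     # NULL: pixel count at train time
              ssim_window = c(11L, 11L), ssim_stride = NULL,
              lr = 1e-3, steps = 200L,
              base_temp = 10, upper_cutoff = NULL,
              min_leaf_area = 50L, seed = 1L,
              version = as.character(utils::packageVersion("rifseg")))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop_rifseg(paste("unknown config fields:", paste(bad, collapse = ", ")),
                "rifseg_invalid_config")
  }
  structure(modifyList(cfg, over, keep.null = TRUE), class = "rifseg_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A [rifseg_config()].
#' @param path YAML path.
#' @return The path / the configuration.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(rifseg_config, yaml::read_yaml(path))
}

#' Write a stage manifest
#'
#' JSON sidecar recording the configuration, its hash, the seed and the
#' files a stage produced; re-running a deterministic stage with the same
#' config reproduces the outputs bit-exactly.
#'
#' @param path Manifest path.
#' @param cfg Configuration list.
#' @param files Character vector of produced files.
#' @param extra Optional named list merged into the manifest.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, cfg, files, extra = list()) {
  m <- c(list(config = unclass(cfg), config_hash = config_hash(unclass(cfg)),
              seed = cfg$seed %||% NA, files = as.character(files),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
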