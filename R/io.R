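#' Read and write brightfield round images as TIFF
#'
#' Brightfield RGB rounds are stored as ordinary 8- or 16-bit RGB TIFF;
#' intensities are mapped to `[0, white_point]` on read.
#'
#' @param path file path.
#' @param microns_per_pixel calibration of the stored image.
#' @param round_id round label.
#' @param white_point blank-glass intensity scale.
#' @return `read_round_tiff()`: a `calibrated_image`.
#' @export
read_round_tiff <- function(path, microns_per_pixel, round_id = NA,
                            white_point = 255) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) != 3L || dim(px)[3] < 3L)
    stop("expected an RGB TIFF", call. = FALSE)
  calibrated_image(px[, , 1:3] * white_point, microns_per_pixel,
                   round_id = round_id, white_point = white_point)
}

#' @rdname read_round_tiff
#' @param img a brightfield `calibrated_image`.
#' @export
write_round_tiff <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"),
            img$modality == "brightfield_rgb")
  tiff::writeTIFF(img$pixels / img$white_point, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write/read a density map as 32-bit float TIFF plus JSON sidecar
#'
#' Densities are stored divided by `od_scale` (float TIFF is clamped to
#' `[0, 1]`); the sidecar (`<path>.json`) records the scale, stain name
#' and calibration so the map is self-describing.
#'
#' @param dm a [density_map()].
#' @param path output `.tif` path.
#' @param od_scale full-scale OD of the stored file.
#' @export
write_density_tiff <- function(dm, path, od_scale = 4) {
  stopifnot(inherits(dm, "density_map"))
  tiff::writeTIFF(pmin(dm$pixels / od_scale, 1), path, bits.per.sample = 32L)
  jsonlite::write_json(list(stain = dm$stain, od_scale = od_scale,
                            microns_per_pixel = dm$microns_per_pixel,
                            round_id = dm$round_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density_tiff
#' @export
read_density_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path)
  density_map(px * meta$od_scale, meta$microns_per_pixel, meta$stain,
              meta$round_id %||% NA)
}

#' Write/read a channel stack as multi-page float TIFF plus JSON sidecar
#'
#' One 32-bit float page per channel; the sidecar carries channel names,
#' calibration, provenance and the OD scale.
#'
#' @param stack a `channel_stack`.
#' @param path output `.tif` path.
#' @param od_scale full-scale OD of the stored pages.
#' @export
write_stack_tiff <- function(stack, path, od_scale = 4) {
  stopifnot(inherits(stack, "channel_stack"))
  pages <- lapply(stack$channels, function(m) pmin(m / od_scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channel_names = stack$channel_names, od_scale = od_scale,
         microns_per_pixel = stack$microns_per_pixel,
         provenance = stack$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) p * meta$od_scale)
  names(channels) <- meta$channel_names
  structure(list(channels = channels, channel_names = meta$channel_names,
                 microns_per_pixel = meta$microns_per_pixel,
                 valid = base::matrix(TRUE, nrow(channels[[1]]), ncol(channels[[1]])),
                 provenance = as.data.frame(meta$provenance)),
            class = "channel_stack")
}

#' Export the classified object table as CSV
#'
#' One row per object: id, centroid (um), area (um^2), per-marker boolean
#' calls, fractions and mean densities, and phenotype label. Rows are
#' ordered by id, so repeated runs produce byte-identical files.
#'
#' @param cells an `object_set`.
#' @param path output CSV path.
#' @export
write_object_table <- function(cells, path) {
  tab <- if (inherits(cells, "object_set")) cells$table else cells
  tab <- tab[order(tab$id), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export a proximity profile as CSV (counts and both normalizations)
#'
#' @param profile a `proximity_profile`.
#' @param path output CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "proximity_profile"))
  long <- do.call(rbind, lapply(colnames(profile$counts), function(ph) {
    data.frame(pathology_kind = profile$pathology_kind,
               bin = rownames(profile$counts), phenotype = ph,
               count = profile$counts[, ph],
               pct_within_bin = profile$row_pct[, ph],
               pct_within_phenotype = profile$col_pct[, ph])
  }))
  rownames(long) <- NULL
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a pipeline configuration as YAML
#'
#' Stain vectors are stored as name + 3 floats per stain; all geometric
#' parameters are microns.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  obj <- list(
    panel = as.list(cfg$panel),
    stains = lapply(cfg$stains$vectors, function(v)
      list(name = v$name, od_rgb = as.numeric(v$od_rgb))),
    thresholds = cfg$thresholds,
    min_cell_area = cfg$min_cell_area,
    pathology_min_size = cfg$pathology_min_size,
    pathology_size_metric = cfg$pathology_size_metric,
    radius = cfg$radius, bin_width = cfg$bin_width,
    overlap_fraction = cfg$overlap_fraction,
    registration_mode = cfg$registration_mode,
    max_rotation = cfg$max_rotation,
    reference_round = cfg$reference_round,
    cell_channel = cfg$cell_channel,
    plaque_channel = cfg$plaque_channel,
    tangle_channel = cfg$tangle_channel,
    touch_tolerance = cfg$touch_tolerance,
    seed = cfg$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_yaml
#' @export
read_pipeline_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  stains <- do.call(stain_matrix, lapply(obj$stains, function(s)
    stain_vector(s$name, as.numeric(s$od_rgb))))
  args <- obj[setdiff(names(obj), "stains")]
  args$panel <- unlist(args$panel)
  args$stains <- stains
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(pipeline_config, args)
}

#' Write a generated scene to a directory
#'
#' Per-round brightfield TIFFs, the ground-truth cell table as CSV, true
#' transforms as JSON and the seed/config summary as YAML.
#'
#' @param scene an `ihc_scene` (rendered).
#' @param dir output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "ihc_scene"), !is.null(scene$images))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scene$truth$config
  for (r in seq_along(scene$images))
    write_round_tiff(scene$images[[r]],
                     file.path(dir, sprintf("round_%02d_%s.tif", r, cfg$panel[r])))
  if (!is.null(scene$destain_images))
    for (r in seq_along(scene$destain_images))
      write_round_tiff(scene$destain_images[[r]],
                       file.path(dir, sprintf("round_%02d_%s_destained.tif",
                                              r, cfg$panel[r])))
  utils::write.csv(scene$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  for (r in seq_along(scene$truth$transforms))
    write_transform_json(scene$truth$transforms[[r]],
                         file.path(dir, sprintf("transform_round_%02d.json", r)))
  yaml::write_yaml(list(seed = cfg$seed, field_um = cfg$field_um,
                        microns_per_pixel = cfg$microns_per_pixel,
                        panel = as.list(cfg$panel), n_cells = cfg$n_cells,
                        retention_fraction = cfg$retention_fraction,
                        od_sigma = cfg$od_sigma),
                   file.path(dir, "scene.yaml"))
  invisible(dir)
}
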