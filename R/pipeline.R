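#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. All distances and
#' areas are microns / square microns; pixel conversions happen inside the
#' stages. Defaults follow the workflow's stated parameters: a 40 um^2
#' minimum object area for cells, a 100 um(^2) pathology size exclusion,
#' and a 100 um proximity radius in 20 um bins.
#'
#' @param panel ordered marker names, one per staining round.
#' @param stains a [stain_matrix()] (chromogen first, hematoxylin second).
#' @param thresholds optional named per-marker OD thresholds; missing
#'   markers use Otsu.
#' @param min_cell_area minimum cell-object area, um^2.
#' @param pathology_min_size pathology size exclusion (um^2 for
#'   `pathology_size_metric = "area"`, um of equivalent diameter for
#'   `"diameter"`).
#' @param pathology_size_metric how to read `pathology_min_size`.
#' @param radius,bin_width proximity profile radius and bin width, um.
#' @param overlap_fraction marker-positivity overlap rule, see
#'   [colocalize()].
#' @param registration_mode `"rigid"`, `"affine"` or `"deformable"`.
#' @param max_rotation coarse rotation search half-width, degrees.
#' @param reference_round index of the reference (and counterstain) round.
#' @param cell_channel reference channel seeding cell detection.
#' @param plaque_channel,tangle_channel pathology channels.
#' @param gate a [phenotype_gate()].
#' @param touch_tolerance association contact tolerance, um.
#' @param seed optional seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = c("P2Y12", "TMEM119", "Ferritin", "CD45",
                                      "CD68", "IBA1", "GFAP", "PHF1", "Abeta"),
                            stains = default_stain_matrix(),
                            thresholds = NULL,
                            min_cell_area = 40,
                            pathology_min_size = 100,
                            pathology_size_metric = c("area", "diameter"),
                            radius = 100, bin_width = 20,
                            overlap_fraction = 0.25,
                            registration_mode = c("rigid", "affine", "deformable"),
                            max_rotation = 5,
                            reference_round = 1,
                            cell_channel = "IBA1",
                            plaque_channel = "Abeta",
                            tangle_channel = "PHF1",
                            gate = default_phenotype_gate(),
                            touch_tolerance = 0,
                            seed = NULL) {
  registration_mode <- match.arg(registration_mode)
  pathology_size_metric <- match.arg(pathology_size_metric)
  stopifnot(min_cell_area >= 0, pathology_min_size >= 0, radius > 0,
            bin_width > 0, overlap_fraction > 0, overlap_fraction <= 1)
  if (!cell_channel %in% panel)
    stop("'cell_channel' must be in the panel", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d-round panel (%s)\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  cells: %s-seeded, min area %g um^2; pathology min %s %g; radius %g um / %g um bins\n",
              x$cell_channel, x$min_cell_area, x$pathology_size_metric,
              x$pathology_min_size, x$radius, x$bin_width))
  invisible(x)
}

#' Run the full multiplex analysis
#'
#' Executes deconvolve, register, stack, detect, colocalize, classify and
#' proximity on a set of per-round brightfield images:
#' \enumerate{
#'   \item each round's RGB image is converted to OD and deconvolved into
#'     chromogen + hematoxylin density maps;
#'   \item every round is registered onto the reference round's
#'     hematoxylin map (the counterstain is re-applied each round, so it
#'     is the only structure common to all rounds);
#'   \item the warped chromogen channels plus the reference hematoxylin
#'     compose the `N + 1`-channel pseudo-fluorescent stack;
#'   \item cell objects are detected on the cell seed channel with the
#'     minimum-area exclusion, scored for all markers, and gated into
#'     phenotypes;
#'   \item plaque and tangle objects are detected with the pathology size
#'     exclusion, and proximity profiles plus association fractions are
#'     computed.
#' }
#'
#' @param images list of per-round `calibrated_image`s (brightfield RGB),
#'   in staining order, one per panel entry.
#' @param cfg a [pipeline_config()].
#' @param vessels optional vessel masks as an `object_set` (vessels are
#'   identified outside the stain panel).
#' @return An object of class `pipeline_run`: `stack`, `transforms`,
#'   `cells` (classified `object_set`), `phenotype_counts`, `plaques`,
#'   `tangles`, `profiles` (per pathology kind), `association`, `qc`
#'   (clip fractions, registration similarities), `manifest`.
#' @export
run_pipeline <- function(images, cfg = pipeline_config(), vessels = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(images) != length(cfg$panel))
    stop(sprintf("pipeline stage 'input': %d images supplied for a %d-round panel",
                 length(images), length(cfg$panel)), call. = FALSE)
  chrom_name <- cfg$stains$names[1]
  hema_name <- cfg$stains$names[2]

  # stage 1: deconvolution
  dens <- vector("list", length(images))
  clip <- base::matrix(NA_real_, length(images), length(cfg$stains$names),
                       dimnames = list(cfg$panel, cfg$stains$names))
  for (r in seq_along(images)) {
    od <- rgb_to_od(images[[r]])
    d <- deconvolve(od, cfg$stains)
    clip[r, ] <- attr(d, "clip_fraction")
    dens[[r]] <- d
  }

  # stage 2: registration on the counterstain channel
  ref <- cfg$reference_round
  transforms <- vector("list", length(images))
  for (r in seq_along(images)) {
    transforms[[r]] <- if (r == ref)
      identity_transform(fixed_round = ref, moving_round = r)
    else estimate_transform(dens[[ref]][[hema_name]], dens[[r]][[hema_name]],
                            mode = cfg$registration_mode,
                            max_rotation = cfg$max_rotation)
  }

  # stage 3: stack composition
  rounds <- lapply(seq_along(images), function(r)
    list(round = r, marker = cfg$panel[r],
         chromogen = dens[[r]][[chrom_name]],
         counterstain = dens[[r]][[hema_name]],
         transform = transforms[[r]]))
  stack <- compose_stack(rounds, counterstain_round = ref)

  # stage 4: cells -> markers -> phenotypes
  thr <- as.list(cfg$thresholds %||% list())
  cell_ch <- stack_channel(stack, cfg$cell_channel)
  cell_thr <- thr[[cfg$cell_channel]] %||%
    otsu_threshold(cell_ch, mask = stack$valid)
  cells <- detect_objects(cell_ch, threshold = cell_thr,
                          min_area = cfg$min_cell_area, valid = stack$valid)
  cells <- colocalize(cells, stack, thresholds = thr,
                      overlap_fraction = cfg$overlap_fraction)
  cells$table$label <- classify_phenotype(cells$table, cfg$gate)
  counts <- count_phenotypes(cells$table$label, cfg$gate)

  # stage 5: pathology + proximity
  plaques <- tangles <- NULL
  profiles <- list()
  if (!is.null(cfg$plaque_channel) && cfg$plaque_channel %in% stack$channel_names) {
    plaques <- detect_pathology(stack_channel(stack, cfg$plaque_channel),
                                kind = "abeta_plaque",
                                threshold = thr[[cfg$plaque_channel]],
                                min_size = cfg$pathology_min_size,
                                metric = cfg$pathology_size_metric,
                                valid = stack$valid)
  }
  if (!is.null(cfg$tangle_channel) && cfg$tangle_channel %in% stack$channel_names) {
    tangles <- detect_pathology(stack_channel(stack, cfg$tangle_channel),
                                kind = "phf1_tangle",
                                threshold = thr[[cfg$tangle_channel]],
                                min_size = cfg$pathology_min_size,
                                metric = cfg$pathology_size_metric,
                                valid = stack$valid)
  }
  if (!is.null(plaques))
    profiles$abeta_plaque <- withCallingHandlers(
      proximity_profile(cells, plaques, radius = cfg$radius,
                        bin_width = cfg$bin_width, exclude_nearer = tangles),
      warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(tangles))
    profiles$phf1_tangle <- withCallingHandlers(
      proximity_profile(cells, tangles, radius = cfg$radius,
                        bin_width = cfg$bin_width, exclude_nearer = plaques),
      warning = function(w) invokeRestart("muffleWarning"))
  association <- if (!is.null(plaques) && nrow(cells$table) > 0)
    association_summary(cells, plaques, tangles, vessels,
                        touch_tolerance = cfg$touch_tolerance)
    else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("chromoplex")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    panel = cfg$panel,
    parameters = list(min_cell_area = cfg$min_cell_area,
                      pathology_min_size = cfg$pathology_min_size,
                      pathology_size_metric = cfg$pathology_size_metric,
                      radius = cfg$radius, bin_width = cfg$bin_width,
                      overlap_fraction = cfg$overlap_fraction,
                      registration_mode = cfg$registration_mode,
                      reference_round = cfg$reference_round,
                      touch_tolerance = cfg$touch_tolerance,
                      thresholds = cfg$thresholds),
    registration = data.frame(
      round = seq_along(images),
      similarity = vapply(transforms, function(t) t$similarity, numeric(1))))

  structure(list(stack = stack, transforms = transforms, cells = cells,
                 phenotype_counts = counts, plaques = plaques,
                 tangles = tangles, profiles = profiles,
                 association = association,
                 qc = list(clip_fraction = clip,
                           registration = manifest$registration,
                           cell_threshold = cell_thr),
                 manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d channels; %d cell objects\n",
              length(x$stack$channels), nrow(x$cells$table)))
  cat("phenotype counts:\n")
  print(x$phenotype_counts)
  if (!is.null(x$plaques))
    cat(sprintf("pathology: %d plaques, %d tangles\n",
                nrow(x$plaques$table),
                if (is.null(x$tangles)) 0L else nrow(x$tangles$table)))
  invisible(x)
}
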