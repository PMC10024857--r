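#' Calibrated image
#'
#' A 2-D intensity field with physical pixel calibration and a modality tag.
#' Pixels are stored row = y (downward), column = x (rightward); coordinates
#' throughout the package are 0-based pixel centres, converted to microns by
#' multiplying with `microns_per_pixel`. RGB brightfield images are
#' `ny x nx x 3` arrays with intensities in `[0, white_point]`; optical
#' density (`"od"`) images share that shape in OD units; `"density"` and
#' `"mask"` images are plain matrices.
#'
#' @param pixels numeric matrix (`ny x nx`) or array (`ny x nx x 3`).
#' @param microns_per_pixel physical pixel size, microns per pixel (> 0).
#' @param round_id label of the staining round the image came from.
#' @param modality one of `"brightfield_rgb"`, `"od"`, `"density"`, `"mask"`.
#' @param white_point intensity of unstained (blank) glass; required for
#'   brightfield images, defaults to 255 (8-bit).
#'
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(array(200, c(8, 8, 3)), microns_per_pixel = 0.5)
#' img
#' @export
calibrated_image <- function(pixels, microns_per_pixel, round_id = NA_character_,
                             modality = "brightfield_rgb", white_point = 255) {
  modality <- match.arg(modality, c("brightfield_rgb", "od", "density", "mask"))
  if (!is.numeric(pixels)) stop("'pixels' must be numeric", call. = FALSE)
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("'microns_per_pixel' must be a single positive number", call. = FALSE)
  if (any(!is.finite(pixels))) stop("image intensities must be finite", call. = FALSE)
  nd <- length(dim(pixels))
  if (modality %in% c("brightfield_rgb", "od")) {
    if (nd != 3L || dim(pixels)[3] != 3L)
      stop(sprintf("a %s image must have exactly 3 samples per pixel", modality),
           call. = FALSE)
  } else {
    if (nd != 2L) stop(sprintf("a %s image must be a 2-D matrix", modality), call. = FALSE)
  }
  if (modality == "brightfield_rgb") {
    if (!is.numeric(white_point) || length(white_point) != 1L || white_point <= 0)
      stop("'white_point' must be a single positive intensity", call. = FALSE)
    if (min(pixels) < 0 || max(pixels) > white_point)
      stop("brightfield intensities must lie in [0, white_point]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, microns_per_pixel = microns_per_pixel,
         round_id = round_id, modality = modality,
         white_point = if (modality == "brightfield_rgb") white_point else NA_real_),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %s, %d x %d px (%.3g um/px), round %s\n",
              x$modality, d[2], d[1], x$microns_per_pixel,
              as.character(x$round_id)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Per-stain optical-density map
#'
#' A scalar field of one stain's optical density (OD units, >= 0 after
#' clipping) on a calibrated grid; the deconvolved "single-channel image" of
#' one chromogenic round.
#'
#' @param pixels numeric matrix of per-pixel stain density (OD).
#' @param microns_per_pixel microns per pixel (> 0).
#' @param stain stain name (e.g. `"amec_red"`, `"hematoxylin"`).
#' @param round_id originating round label.
#'
#' @return An object of class `density_map`.
#' @export
density_map <- function(pixels, microns_per_pixel, stain, round_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels))) stop("density values must be finite", call. = FALSE)
  if (microns_per_pixel <= 0) stop("'microns_per_pixel' must be > 0", call. = FALSE)
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 stain = as.character(stain), round_id = round_id),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> stain '%s', %d x %d px (%.3g um/px), OD range [%.3g, %.3g]\n",
              x$stain, ncol(x$pixels), nrow(x$pixels), x$microns_per_pixel,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$pixels)

# internal: accept a density_map or a bare matrix, return the matrix
as_density_matrix <- function(x) {
  if (inherits(x, "density_map")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a density_map or numeric matrix", call. = FALSE)
}
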