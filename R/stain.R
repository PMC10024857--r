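#' Stain optical-density vectors and matrices
#'
#' A `stain_vector` is a unit-norm, non-negative 3-vector of RGB absorption
#' coefficients describing one stain's colour in optical-density space; a
#' `stain_matrix` collects two or three linearly independent stain vectors
#' (chromogen, hematoxylin counterstain, optional residual) and is the basis
#' used by [deconvolve()].
#'
#' Published vectors for the AMEC-red chromogen do not exist; the shipped
#' defaults in [default_stain_matrix()] are the vectors the synthetic
#' renderer itself uses (an AEC-like red and a standard hematoxylin). For
#' real slides, supply measured vectors or estimate them from a stained
#' region with [estimate_stain_vector()].
#'
#' @param name stain name.
#' @param od_rgb numeric 3-vector of non-negative absorption coefficients;
#'   normalized to unit Euclidean norm.
#'
#' @return `stain_vector()`: an object of class `stain_vector` with fields
#'   `name` and `od_rgb` (unit norm).
#' @examples
#' stain_vector("hematoxylin", c(0.650, 0.704, 0.286))
#' @export
stain_vector <- function(name, od_rgb) {
  od_rgb <- as.numeric(od_rgb)
  if (length(od_rgb) != 3L || any(!is.finite(od_rgb)))
    stop("'od_rgb' must be a finite numeric 3-vector", call. = FALSE)
  if (any(od_rgb < 0))
    stop("stain vector components must be non-negative", call. = FALSE)
  nrm <- sqrt(sum(od_rgb^2))
  if (nrm < 1e-12) stop("stain vector must be non-zero", call. = FALSE)
  structure(list(name = as.character(name), od_rgb = od_rgb / nrm),
            class = "stain_vector")
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("<stain_vector> %s: (%.4f, %.4f, %.4f)\n", x$name,
              x$od_rgb[1], x$od_rgb[2], x$od_rgb[3]))
  invisible(x)
}

#' @rdname stain_vector
#' @param ... for `stain_matrix()`: two or three `stain_vector` objects.
#' @param max_condition largest acceptable condition number of the stain
#'   basis before it is declared collinear.
#' @return `stain_matrix()`: an object of class `stain_matrix`; `$basis` is
#'   the 3 x k matrix whose columns are the stain vectors.
#' @export
stain_matrix <- function(..., max_condition = 1e6) {
  vecs <- list(...)
  if (length(vecs) == 1L && is.list(vecs[[1]]) && !inherits(vecs[[1]], "stain_vector"))
    vecs <- vecs[[1]]
  if (!all(vapply(vecs, inherits, logical(1), "stain_vector")))
    stop("all arguments must be stain_vector objects", call. = FALSE)
  if (!length(vecs) %in% 2:3)
    stop("a stain matrix holds 2 or 3 stain vectors", call. = FALSE)
  nms <- vapply(vecs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("stain names must be unique", call. = FALSE)
  basis <- vapply(vecs, `[[`, numeric(3), "od_rgb")
  cond <- kappa(basis, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition)
    stop("stain vectors are collinear (condition number ",
         format(cond), "); deconvolution is ill-posed", call. = FALSE)
  structure(list(vectors = vecs, names = nms, basis = basis, condition = cond),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat(sprintf("<stain_matrix> %d stains (%s), condition %.3g\n",
              length(x$names), paste(x$names, collapse = ", "), x$condition))
  invisible(x)
}

#' @rdname stain_vector
#' @export
default_stain_matrix <- function() {
  stain_matrix(
    stain_vector("amec_red",    c(0.2743, 0.6796, 0.6803)),
    stain_vector("hematoxylin", c(0.6500, 0.7040, 0.2860)))
}

#' Brightfield RGB to optical density
#'
#' Applies the Beer-Lambert transform per RGB sample:
#' `OD = -log10(max(I, eps) / white_point)`, so that blank glass
#' (`I = white_point`) maps to OD 0 and a tenfold attenuation maps to OD 1.
#' The `eps` clamp (default one intensity level) keeps saturated-dark pixels
#' finite without biasing any pixel at or above one intensity level.
#'
#' @param img a `calibrated_image` of modality `"brightfield_rgb"`.
#' @param white_point blank-glass intensity; defaults to the image's own.
#' @param eps dark-pixel clamp, in intensity units.
#'
#' @return A `calibrated_image` of modality `"od"` (same grid).
#' @seealso [od_to_rgb()] for the inverse, [deconvolve()] for stain
#'   separation.
#' @examples
#' img <- calibrated_image(array(c(26, 255, 255), c(1, 1, 3)), 0.5)
#' rgb_to_od(img)$pixels[1, 1, ]   # ~ (0.991, 0, 0)
#' @export
rgb_to_od <- function(img, white_point = NULL, eps = 1) {
  if (!inherits(img, "calibrated_image") || img$modality != "brightfield_rgb")
    stop("rgb_to_od() needs a calibrated_image of modality 'brightfield_rgb'",
         call. = FALSE)
  wp <- if (is.null(white_point)) img$white_point else white_point
  if (!is.numeric(wp) || length(wp) != 1L || !is.finite(wp) || wp <= 0)
    stop("'white_point' must be a single positive intensity", call. = FALSE)
  od <- -log10(pmax(img$pixels, eps) / wp)
  od[od < 0] <- 0
  calibrated_image(od, img$microns_per_pixel, round_id = img$round_id,
                   modality = "od")
}

#' @rdname rgb_to_od
#' @param od_img a `calibrated_image` of modality `"od"`.
#' @export
od_to_rgb <- function(od_img, white_point = 255) {
  if (!inherits(od_img, "calibrated_image") || od_img$modality != "od")
    stop("od_to_rgb() needs a calibrated_image of modality 'od'", call. = FALSE)
  I <- white_point * 10^(-od_img$pixels)
  calibrated_image(I, od_img$microns_per_pixel, round_id = od_img$round_id,
                   modality = "brightfield_rgb", white_point = white_point)
}

#' Colour deconvolution of an optical-density image
#'
#' Separates an OD image into per-stain density maps by per-pixel least
#' squares against the stain basis (Moore-Penrose pseudo-inverse). A
#' two-stain basis is completed with the cross-product third vector before
#' inversion, which leaves the two stain coefficients equal to their
#' least-squares projection. Negative densities (noise projected outside the
#' cone of physical mixtures) are clipped to zero; the fraction of clipped
#' pixels per stain is reported in the `"clip_fraction"` attribute for QC.
#'
#' @param od_img `calibrated_image` of modality `"od"`.
#' @param matrix a [stain_matrix()].
#'
#' @return A named list of [density_map()] objects, one per stain, with
#'   attribute `clip_fraction`.
#' @examples
#' sm <- default_stain_matrix()
#' od <- calibrated_image(array(0.7 * sm$basis[, 2], c(1, 1, 3)), 1,
#'                        modality = "od")
#' vapply(deconvolve(od, sm), function(d) d$pixels[1, 1], numeric(1))
#' @export
deconvolve <- function(od_img, matrix) {
  if (!inherits(od_img, "calibrated_image") || od_img$modality != "od")
    stop("deconvolve() needs a calibrated_image of modality 'od'", call. = FALSE)
  if (!inherits(matrix, "stain_matrix"))
    stop("'matrix' must be a stain_matrix", call. = FALSE)
  basis <- matrix$basis
  k <- ncol(basis)
  if (k == 2L) {
    v3 <- c(basis[2, 1] * basis[3, 2] - basis[3, 1] * basis[2, 2],
            basis[3, 1] * basis[1, 2] - basis[1, 1] * basis[3, 2],
            basis[1, 1] * basis[2, 2] - basis[2, 1] * basis[1, 2])
    v3 <- v3 / sqrt(sum(v3^2))
    full <- cbind(basis, v3)
  } else full <- basis
  pinv <- solve(full)[seq_len(k), , drop = FALSE]   # k x 3
  d <- dim(od_img$pixels)
  od_flat <- base::matrix(od_img$pixels, d[1] * d[2], 3L)  # pixels x 3
  dens <- od_flat %*% t(pinv)                              # pixels x k
  clip <- colMeans(dens < -1e-12)
  dens[dens < 0] <- 0
  out <- lapply(seq_len(k), function(j)
    density_map(base::matrix(dens[, j], d[1], d[2]), od_img$microns_per_pixel,
                stain = matrix$names[j], round_id = od_img$round_id))
  names(out) <- matrix$names
  attr(out, "clip_fraction") <- setNames(clip, matrix$names)
  out
}

#' Estimate a stain vector from a stained region
#'
#' Returns the dominant unit direction (first principal direction) of the
#' OD vectors of the pixels selected by `roi_mask`, replacing manual colour
#' picking. Components are clipped to be non-negative and re-normalized.
#'
#' @param img `calibrated_image`, brightfield RGB or OD.
#' @param roi_mask logical matrix selecting stained pixels (>= `min_pixels`
#'   required).
#' @param name name for the returned stain vector.
#' @param min_pixels minimum number of usable stained pixels.
#' @param min_od pixels with total OD below this are ignored (unstained).
#'
#' @return A [stain_vector()].
#' @export
estimate_stain_vector <- function(img, roi_mask, name = "estimated",
                                  min_pixels = 50, min_od = 0.05) {
  if (inherits(img, "calibrated_image") && img$modality == "brightfield_rgb")
    img <- rgb_to_od(img)
  if (!inherits(img, "calibrated_image") || img$modality != "od")
    stop("'img' must be a brightfield RGB or OD calibrated_image", call. = FALSE)
  d <- dim(img$pixels)
  if (!is.logical(roi_mask) || !identical(dim(roi_mask), d[1:2]))
    stop("'roi_mask' must be a logical matrix matching the image grid",
         call. = FALSE)
  od_flat <- base::matrix(img$pixels, d[1] * d[2], 3L)[as.vector(roi_mask), ,
                                                       drop = FALSE]
  od_flat <- od_flat[rowSums(od_flat) >= min_od, , drop = FALSE]
  if (nrow(od_flat) < min_pixels)
    stop(sprintf("ROI contains only %d stained pixels (>= %d required)",
                 nrow(od_flat), min_pixels), call. = FALSE)
  # first principal direction through the origin (OD mixes are conical,
  # not mean-centred)
  sv <- svd(od_flat, nu = 0, nv = 3)
  v <- sv$v[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  stain_vector(name, v)
}
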