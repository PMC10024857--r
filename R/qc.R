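#' Otsu positivity threshold for a density map
#'
#' Data-driven default positivity threshold: Otsu's method on the density
#' histogram. Returns `Inf` for an all-zero (blank) map, so that no pixel
#' is called positive.
#'
#' @param density a [density_map()] or numeric matrix.
#' @param mask optional logical matrix restricting the histogram.
#' @param levels histogram resolution.
#' @param min_threshold floor for the returned threshold (OD). Otsu always
#'   splits the histogram, so on a channel containing no stain it would
#'   land inside the noise; the floor (well below any chromogen density,
#'   well above acquisition noise) keeps such channels all-negative.
#' @return Threshold in OD units.
#' @export
otsu_threshold <- function(density, mask = NULL, levels = 256,
                           min_threshold = 0.1) {
  m <- as_density_matrix(density)
  v <- if (is.null(mask)) m else m[mask]
  mx <- max(v)
  if (mx <= 0) return(Inf)
  max(EBImage::otsu(EBImage::Image(v), range = c(0, mx), levels = levels),
      min_threshold)
}

#' Stained area fraction
#'
#' Percent of tissue pixels at or above a positivity threshold — the
#' standard brightfield area-quantification statistic used to grade
#' de-staining and blocking efficacy.
#'
#' @param density [density_map()] or matrix.
#' @param threshold positivity threshold (OD, > 0).
#' @param tissue_mask logical matrix of tissue pixels (default: whole
#'   field).
#' @param valid logical matrix of in-field pixels (e.g. a warp validity
#'   mask); excluded pixels count neither as tissue nor as positive.
#' @return Percent, in `[0, 100]`.
#' @examples
#' m <- matrix(0, 10, 10); m[1:5, 1:7] <- 1
#' area_fraction(m, 0.5)   # 35
#' @export
area_fraction <- function(density, threshold, tissue_mask = NULL, valid = NULL) {
  m <- as_density_matrix(density)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive OD value", call. = FALSE)
  mask <- if (is.null(tissue_mask)) base::matrix(TRUE, nrow(m), ncol(m)) else tissue_mask
  if (!is.null(valid)) mask <- mask & valid
  n <- sum(mask)
  if (n == 0) stop("tissue mask is empty", call. = FALSE)
  100 * sum(m[mask] >= threshold) / n
}

#' Residual staining after chromogen removal
#'
#' Quantifies how much stain survives a de-staining (or blocking) step:
#' the *post* image is registered onto the *pre* image, both are
#' thresholded with the same positivity threshold (default: Otsu on the
#' pre image), and the residual percentage is the fraction of pre-positive
#' pixels still positive afterwards. The whole-tissue post area fraction
#' is reported alongside, since a removal percentage computed on the
#' pre-positive region and one computed on whole tissue answer different
#' questions (blocked re-development vs genuinely new staining). A
#' tile-level residual map exposes spatially non-uniform blocking.
#'
#' @param pre,post [density_map()]s of the same marker before and after
#'   removal/re-development.
#' @param t a [round_transform()] mapping pre-grid coordinates onto the
#'   post image; `NULL` for already-aligned pairs, or `"auto"` to estimate
#'   it with [estimate_transform()] (then `register_on` supplies the two
#'   counterstain maps).
#' @param threshold positivity threshold (OD); default Otsu on `pre`.
#' @param tissue_mask optional logical tissue mask on the pre grid.
#' @param marker marker label for the report.
#' @param tile tile size (pixels) of the spatial residual map.
#' @param register_on optional list `(pre, post)` of counterstain
#'   [density_map()]s used when `t = "auto"`.
#'
#' @return An object of class `qc_record`: marker, threshold,
#'   `pre_area_fraction`, `post_area_fraction` (whole tissue, %),
#'   `residual_percent` (pre-positive region, %; `NA` if nothing was
#'   positive before removal), and `tile_map` (matrix of per-tile residual
#'   %).
#' @export
residual_stain <- function(pre, post, t = NULL, threshold = NULL,
                           tissue_mask = NULL, marker = NULL, tile = 256,
                           register_on = NULL) {
  stopifnot(inherits(pre, "density_map"), inherits(post, "density_map"))
  if (is.null(marker)) marker <- pre$stain
  if (identical(t, "auto")) {
    anchors <- if (is.null(register_on)) list(pre = pre, post = post) else register_on
    t <- estimate_transform(anchors$pre, anchors$post)
  }
  if (is.null(threshold)) threshold <- otsu_threshold(pre, mask = tissue_mask)
  # threshold in the post image's native frame, then map the positive mask
  # through the transform: warping the binary markup at the 0.5 level is
  # area-preserving, where warping densities first would smear
  # partial-amplitude pixels below threshold
  if (is.null(t)) {
    post_pos0 <- post$pixels >= threshold
    valid <- base::matrix(TRUE, nrow(post_pos0), ncol(post_pos0))
  } else {
    w <- warp((post$pixels >= threshold) * 1, t)
    post_pos0 <- w >= 0.5
    valid <- attr(w, "valid")
  }
  mask <- if (is.null(tissue_mask)) base::matrix(TRUE, nrow(pre$pixels), ncol(pre$pixels))
          else tissue_mask
  mask <- mask & valid
  pre_pos <- pre$pixels >= threshold & mask
  post_pos <- post_pos0 & mask
  n_pre <- sum(pre_pos)
  residual <- if (n_pre == 0) NA_real_ else 100 * sum(post_pos & pre_pos) / n_pre

  # tile-level residual for spatial-uniformity QC
  ny <- nrow(pre$pixels); nx <- ncol(pre$pixels)
  ty <- ceiling(ny / tile); tx <- ceiling(nx / tile)
  tile_map <- base::matrix(NA_real_, ty, tx)
  for (i in seq_len(ty)) for (j in seq_len(tx)) {
    rows <- ((i - 1) * tile + 1):min(i * tile, ny)
    cols <- ((j - 1) * tile + 1):min(j * tile, nx)
    np <- sum(pre_pos[rows, cols])
    if (np > 0)
      tile_map[i, j] <- 100 * sum(post_pos[rows, cols] & pre_pos[rows, cols]) / np
  }
  structure(list(
    marker = marker, threshold = threshold,
    pre_area_fraction = if (sum(mask)) 100 * sum(pre_pos) / sum(mask) else NA_real_,
    post_area_fraction = if (sum(mask)) 100 * sum(post_pos) / sum(mask) else NA_real_,
    residual_percent = residual,
    n_pre_positive = n_pre,
    tile_map = tile_map),
    class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(sprintf(
    "<qc_record> %s: pre %.3f%%, post %.4f%% of tissue; residual %.4f%% of pre-positive (thr %.3g OD)\n",
    x$marker, x$pre_area_fraction, x$post_area_fraction,
    x$residual_percent, x$threshold))
  invisible(x)
}

#' @rdname residual_stain
#' @param records list of `qc_record`s.
#' @return `qc_report()`: one-row-per-marker data frame.
#' @export
qc_report <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(marker = r$marker, threshold = r$threshold,
               pre_area_fraction = r$pre_area_fraction,
               post_area_fraction = r$post_area_fraction,
               residual_percent = r$residual_percent,
               n_pre_positive = r$n_pre_positive)))
}
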