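#' Detect objects in a density channel
#'
#' Thresholds the channel, labels 4-connected components, converts
#' geometry to micron units, and discards components below the minimum
#' area — the size exclusion that keeps process fragments and other
#' sub-cellular debris (default floor 40 square microns for cell
#' candidates) out of the object table.
#'
#' @param channel a [density_map()].
#' @param threshold positivity threshold (OD); default Otsu via
#'   [otsu_threshold()].
#' @param min_area minimum object area, square microns (components with
#'   smaller area are discarded).
#' @param max_area optional maximum area, square microns.
#' @param valid optional logical in-field mask.
#'
#' @return An object of class `object_set`: `table` (data frame with id,
#'   centroid `x_um`/`y_um`, `area_um2`, `equiv_diameter_um`, `n_px`),
#'   `pixels` (per-object sorted linear indices), `boundary` (per-object
#'   contour, n x 2 matrix of micron coordinates), `labels` (integer
#'   markup matrix), `microns_per_pixel`, `dim`.
#' @export
detect_objects <- function(channel, threshold = NULL, min_area = 40,
                           max_area = NULL, valid = NULL) {
  stopifnot(inherits(channel, "density_map"))
  if (min_area < 0) stop("'min_area' must be >= 0", call. = FALSE)
  mpp <- channel$microns_per_pixel
  if (!is.finite(mpp) || mpp <= 0) stop("channel calibration unknown", call. = FALSE)
  if (is.null(threshold)) threshold <- otsu_threshold(channel)
  bin <- channel$pixels >= threshold
  if (!is.null(valid)) bin <- bin & valid
  lab <- EBImage::bwlabel(bin)
  labm <- base::matrix(as.integer(EBImage::imageData(lab)), nrow(bin), ncol(bin))
  n <- max(labm)
  px_area <- mpp^2
  if (n == 0)
    return(empty_object_set(dim(bin), mpp))
  npx <- tabulate(labm[labm > 0L], nbins = n)
  keep <- which(npx * px_area >= min_area &
                (if (is.null(max_area)) TRUE else npx * px_area <= max_area))
  if (length(keep) == 0)
    return(empty_object_set(dim(bin), mpp))
  # relabel kept objects 1..k
  remap <- integer(n); remap[keep] <- seq_along(keep)
  labm2 <- base::matrix(0L, nrow(bin), ncol(bin))
  sel <- labm > 0L
  labm2[sel] <- remap[labm[sel]]
  k <- length(keep)
  idx <- which(labm2 > 0L)
  ord <- order(labm2[idx], idx)
  idx <- idx[ord]
  grp <- labm2[idx]
  pixels <- split(idx, grp)
  ny <- nrow(bin)
  x0 <- (idx - 1L) %/% ny          # 0-based column = x
  y0 <- (idx - 1L) %% ny           # 0-based row = y
  cx <- vapply(split(x0, grp), mean, numeric(1)) * mpp
  cy <- vapply(split(y0, grp), mean, numeric(1)) * mpp
  area <- npx[keep] * px_area
  contours <- EBImage::ocontour(EBImage::Image(labm2))
  boundary <- lapply(seq_len(k), function(i) {
    oc <- contours[[i]]
    # ocontour coordinates are 0-based (dim1, dim2) = (y, x)
    cbind(x_um = oc[, 2] * mpp, y_um = oc[, 1] * mpp)
  })
  structure(list(
    table = data.frame(id = seq_len(k), x_um = unname(cx), y_um = unname(cy),
                       area_um2 = area,
                       equiv_diameter_um = 2 * sqrt(area / pi),
                       n_px = npx[keep]),
    pixels = unname(pixels), boundary = boundary, labels = labm2,
    microns_per_pixel = mpp, dim = dim(bin), threshold = threshold),
    class = "object_set")
}

empty_object_set <- function(d, mpp, threshold = NA_real_) {
  structure(list(
    table = data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                       area_um2 = numeric(), equiv_diameter_um = numeric(),
                       n_px = integer()),
    pixels = list(), boundary = list(),
    labels = base::matrix(0L, d[1], d[2]),
    microns_per_pixel = mpp, dim = d, threshold = threshold),
    class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d objects, %d x %d px grid (%.3g um/px)\n",
              nrow(x$table), x$dim[2], x$dim[1], x$microns_per_pixel))
  if (nrow(x$table)) print(head(x$table))
  invisible(x)
}

#' @export
length.object_set <- function(x) nrow(x$table)

#' Detect pathology objects with the large-structure size exclusion
#'
#' Wraps [detect_objects()] for amyloid plaques, tangle (PHF1+) cell
#' bodies and vessel masks, applying the 100-micron size exclusion used to
#' keep small diffuse amyloid and stained neurites out of the proximity
#' analysis. The exclusion is interpreted as minimum *area* (square
#' microns) by default; set `metric = "diameter"` to read it as minimum
#' equivalent diameter in microns instead.
#'
#' @inheritParams detect_objects
#' @param kind one of `"abeta_plaque"`, `"phf1_tangle"`, `"vessel"`.
#' @param min_size size exclusion: square microns when `metric = "area"`,
#'   microns when `metric = "diameter"`.
#' @param metric how to read `min_size`.
#' @return An `object_set` whose elements carry `kind` in the table.
#' @export
detect_pathology <- function(channel, kind = c("abeta_plaque", "phf1_tangle",
                                               "vessel"),
                             threshold = NULL, min_size = 100,
                             metric = c("area", "diameter"), valid = NULL) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  min_area <- if (metric == "area") min_size else pi * (min_size / 2)^2
  objs <- detect_objects(channel, threshold = threshold, min_area = min_area,
                         valid = valid)
  if (nrow(objs$table)) objs$table$kind <- kind else objs$table$kind <- character()
  objs$kind <- kind
  objs
}

#' Assign per-object marker vectors from the stack
#'
#' A marker is called positive on an object when at least
#' `overlap_fraction` of the object's pixels exceed that marker's
#' positivity threshold — an overlap rule that is robust to partial-volume
#' edges. Per-channel mean densities and positive-pixel fractions are
#' recorded alongside the boolean calls.
#'
#' @param objects an [detect_objects()] `object_set` (reference channel,
#'   typically IBA1).
#' @param stack a [compose_stack()] `channel_stack`.
#' @param markers channels to score; default all non-counterstain
#'   channels.
#' @param thresholds named per-marker OD thresholds; missing entries
#'   default to Otsu on that channel.
#' @param overlap_fraction minimum fraction of object pixels above
#'   threshold for a positive call.
#'
#' @return The `object_set` with columns `pos_<marker>` (logical),
#'   `frac_<marker>`, `dens_<marker>` added to its table.
#' @export
colocalize <- function(objects, stack, markers = NULL, thresholds = NULL,
                       overlap_fraction = 0.25) {
  stopifnot(inherits(objects, "object_set"), inherits(stack, "channel_stack"))
  if (is.null(markers))
    markers <- setdiff(stack$channel_names, "hematoxylin")
  missing <- setdiff(markers, stack$channel_names)
  if (length(missing))
    stop("markers not in stack: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(objects$dim, dim(stack$channels[[1]])))
    stop("object grid does not match stack grid", call. = FALSE)
  tab <- objects$table
  for (m in markers) {
    ch <- stack$channels[[m]]
    thr <- thresholds[[m]] %||% otsu_threshold(ch, mask = stack$valid)
    if (nrow(tab)) {
      frac <- vapply(objects$pixels, function(p) mean(ch[p] >= thr), numeric(1))
      dens <- vapply(objects$pixels, function(p) mean(ch[p]), numeric(1))
    } else frac <- dens <- numeric()
    tab[[paste0("pos_", m)]] <- frac >= overlap_fraction
    tab[[paste0("frac_", m)]] <- frac
    tab[[paste0("dens_", m)]] <- dens
  }
  objects$table <- tab
  objects$markers <- markers
  objects
}
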