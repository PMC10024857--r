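#' Distance from a cell to a pathology object
#'
#' Euclidean distance (microns) from the cell centroid to the object's
#' boundary, zero when the centroid lies inside the object — the
#' centroid-to-edge convention of typical proximity modules, robust for
#' small cells.
#'
#' @param cell a length-2 numeric `(x_um, y_um)`, or a list/one-row data
#'   frame with `x_um`, `y_um`.
#' @param obj a pathology object: either an element produced by
#'   [pathology_objects()] or an [detect_objects()] `object_set` with a
#'   single object.
#' @return Distance in microns.
#' @export
distance_to_object <- function(cell, obj) {
  p <- if (is.numeric(cell) && length(cell) == 2L) cell
       else c(cell$x_um, cell$y_um)
  if (inherits(obj, "object_set")) {
    if (nrow(obj$table) != 1L)
      stop("'obj' must contain exactly one object; see pathology_objects()",
           call. = FALSE)
    obj <- pathology_objects(obj)[[1]]
  }
  if (is.null(obj$boundary) || nrow(obj$boundary) == 0L)
    stop("degenerate (empty) pathology object", call. = FALSE)
  object_distances(base::matrix(p, 1L), list(obj))[1]
}

#' Explode an object set into standalone pathology objects
#'
#' @param objs an `object_set` (e.g. from [detect_pathology()]).
#' @return List of objects, each with `id`, `kind`, `boundary` (micron
#'   coordinates), `pixels`, `inside` (logical matrix), `microns_per_pixel`.
#' @export
pathology_objects <- function(objs) {
  stopifnot(inherits(objs, "object_set"))
  kind <- objs$kind %||% NA_character_
  lapply(seq_len(nrow(objs$table)), function(i) {
    inside <- base::matrix(FALSE, objs$dim[1], objs$dim[2])
    inside[objs$pixels[[i]]] <- TRUE
    list(id = objs$table$id[i], kind = kind, boundary = objs$boundary[[i]],
         pixels = objs$pixels[[i]], inside = inside,
         microns_per_pixel = objs$microns_per_pixel)
  })
}

# minimum distance from each point (n x 2, microns) to the nearest of a
# list of pathology objects; 0 for points inside an object
object_distances <- function(pts, objects) {
  n <- nrow(pts)
  if (length(objects) == 0L) return(rep(Inf, n))
  d <- rep(Inf, n)
  for (obj in objects) {
    di <- dist_points_to_polyline(pts, obj$boundary)
    if (!is.null(obj$inside)) {
      mpp <- obj$microns_per_pixel
      px <- as.integer(round(pts[, 1] / mpp))
      py <- as.integer(round(pts[, 2] / mpp))
      ny <- nrow(obj$inside); nx <- ncol(obj$inside)
      ok <- px >= 0L & px < nx & py >= 0L & py < ny
      ii <- which(ok)
      if (length(ii)) {
        lin <- px[ii] * ny + py[ii] + 1L
        di[ii[obj$inside[lin]]] <- 0
      }
    }
    d <- pmin(d, di)
  }
  d
}

# distance from points (n x 2) to a closed polyline (m x 2), exact
# point-to-segment geometry
dist_points_to_polyline <- function(pts, poly) {
  m <- nrow(poly)
  if (m == 1L)
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  A <- poly
  B <- poly[c(2:m, 1L), , drop = FALSE]
  d2 <- rep(Inf, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (s in seq_len(m)) {
    ax <- A[s, 1]; ay <- A[s, 2]
    vx <- B[s, 1] - ax; vy <- B[s, 2] - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 < 1e-24) rep(0, length(px))
         else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Distance-binned proximity profile of phenotypes around pathology
#'
#' Assigns each classified cell to the distance bin of its nearest
#' pathology object (within `radius`; farther cells are excluded) and
#' tabulates counts per phenotype per bin. Both normalizations are
#' emitted: `row_pct` (per bin, over phenotypes, rows summing to 100 where
#' nonempty — the "relative percentage at each distance interval" view)
#' and `col_pct` (per phenotype, over bins).
#'
#' @param cells a classified `object_set` or a data frame with `x_um`,
#'   `y_um`, `label`.
#' @param pathology an `object_set` from [detect_pathology()], or a list
#'   from [pathology_objects()].
#' @param radius profile radius, microns.
#' @param bin_width bin width, microns; must divide `radius`.
#' @param phenotypes labels to profile (others are dropped); default the
#'   five phenotype labels.
#' @param exclude_nearer optional second pathology set: cells strictly
#'   nearer to it than to `pathology` are excluded, so overlapping plaque
#'   and tangle neighbourhoods are split by the nearer object.
#'
#' @return An object of class `proximity_profile`: `counts`, `row_pct`,
#'   `col_pct` (bins x phenotypes), `bin_edges`, `n_excluded`,
#'   `n_cells_total`, `pathology_kind`, and per-cell `distances`.
#' @export
proximity_profile <- function(cells, pathology, radius = 100, bin_width = 20,
                              phenotypes = phenotype_labels(),
                              exclude_nearer = NULL) {
  if (inherits(cells, "object_set")) cells <- cells$table
  stopifnot(is.data.frame(cells), radius > 0, bin_width > 0)
  if (abs(radius / bin_width - round(radius / bin_width)) > 1e-9)
    stop("'bin_width' must divide 'radius'", call. = FALSE)
  if (!"label" %in% names(cells))
    stop("cells must carry a 'label' column (classify first)", call. = FALSE)
  objs <- if (inherits(pathology, "object_set")) pathology_objects(pathology)
          else pathology
  kind <- if (length(objs)) objs[[1]]$kind else NA_character_
  edges <- seq(0, radius, by = bin_width)
  nb <- length(edges) - 1L
  cells <- cells[cells$label %in% phenotypes, , drop = FALSE]
  counts <- base::matrix(0L, nb, length(phenotypes),
                         dimnames = list(
                           paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
                           phenotypes))
  if (length(objs) == 0L) {
    warning("no pathology objects; returning an empty profile")
    return(structure(list(pathology_kind = kind, bin_edges = edges,
                          counts = counts, row_pct = counts * NA_real_,
                          col_pct = counts * NA_real_, n_excluded = nrow(cells),
                          n_cells_total = nrow(cells), distances = numeric()),
                     class = "proximity_profile"))
  }
  pts <- cbind(cells$x_um, cells$y_um)
  d <- object_distances(pts, objs)
  keep <- d <= radius
  if (!is.null(exclude_nearer)) {
    alt <- if (inherits(exclude_nearer, "object_set"))
      pathology_objects(exclude_nearer) else exclude_nearer
    if (length(alt)) keep <- keep & d <= object_distances(pts, alt)
  }
  bin <- findInterval(d[keep], edges, rightmost.closed = TRUE)
  ph <- factor(cells$label[keep], levels = phenotypes)
  if (length(bin))
    counts <- unclass(table(factor(bin, levels = seq_len(nb)), ph)) +
      counts * 0L
  dimnames(counts) <- list(paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
                           phenotypes)
  rs <- rowSums(counts); cs <- colSums(counts)
  row_pct <- sweep(counts, 1, ifelse(rs > 0, rs, NA), "/") * 100
  col_pct <- sweep(counts, 2, ifelse(cs > 0, cs, NA), "/") * 100
  structure(list(pathology_kind = kind, bin_edges = edges, counts = counts,
                 row_pct = row_pct, col_pct = col_pct,
                 n_excluded = sum(!keep), n_cells_total = nrow(cells),
                 distances = d),
            class = "proximity_profile")
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat(sprintf("<proximity_profile> %s: %d cells binned, %d excluded (> %g um)\n",
              as.character(x$pathology_kind),
              sum(x$counts), x$n_excluded, max(x$bin_edges)))
  print(x$counts)
  invisible(x)
}

#' Touching/association fractions per phenotype
#'
#' Classifies each cell once into pathology-associated (touching a plaque
#' or tangle), vessel-associated, or neither, in that priority order, and
#' reports per-phenotype percentages; independent per-kind touching
#' fractions (plaque, tangle) are reported alongside. "Touching" means
#' the cell's mask overlaps the object or its boundary-to-boundary
#' distance is within `touch_tolerance` microns.
#'
#' @param cells a classified `object_set`.
#' @param plaques,tangles,vessels `object_set`s (or
#'   [pathology_objects()] lists); `tangles`/`vessels` may be `NULL`.
#'   With no vessel masks supplied the vessel column is `NA`
#'   (not computed), not 0.
#' @param touch_tolerance microns; 0 = contact/overlap.
#' @param phenotypes labels to summarize.
#' @return Data frame of class `association_summary`: one row per
#'   phenotype with `n`, `pct_touching_pathology`, `pct_vessel_associated`,
#'   `pct_non_pathology`, `pct_touching_plaque`, `pct_touching_tangle`.
#' @export
association_summary <- function(cells, plaques, tangles = NULL, vessels = NULL,
                                touch_tolerance = 0,
                                phenotypes = phenotype_labels()) {
  stopifnot(inherits(cells, "object_set"))
  tab <- cells$table
  if (!"label" %in% names(tab))
    stop("cells must carry a 'label' column (classify first)", call. = FALSE)
  as_list <- function(x) {
    if (is.null(x)) NULL
    else if (inherits(x, "object_set")) pathology_objects(x)
    else x
  }
  pl <- as_list(plaques); tg <- as_list(tangles); vs <- as_list(vessels)
  tol <- touch_tolerance + 1e-9
  touch_set <- function(objects) {
    if (is.null(objects) || length(objects) == 0L)
      return(rep(FALSE, nrow(tab)))
    inside_any <- Reduce(`|`, lapply(objects, `[[`, "inside"))
    vapply(seq_len(nrow(tab)), function(i) {
      if (any(inside_any[cells$pixels[[i]]])) return(TRUE)   # mask overlap
      if (touch_tolerance <= 0) return(FALSE)  # contact = overlap at tol 0
      bd <- cells$boundary[[i]]
      min(object_distances(bd, objects)) <= tol
    }, logical(1))
  }
  t_pl <- touch_set(pl)
  t_tg <- touch_set(tg)
  t_vs <- if (is.null(vs)) rep(NA, nrow(tab)) else touch_set(vs)
  t_path <- t_pl | t_tg
  out <- do.call(rbind, lapply(phenotypes, function(ph) {
    sel <- tab$label == ph
    n <- sum(sel)
    pct <- function(x) if (n == 0) NA_real_ else 100 * sum(x[sel]) / n
    vessel_pct <- if (is.null(vs)) NA_real_ else pct(!t_path & t_vs)
    non_pct <- if (n == 0) NA_real_
               else if (is.null(vs)) 100 - pct(t_path)
               else 100 - pct(t_path) - vessel_pct
    data.frame(phenotype = ph, n = n,
               pct_touching_pathology = pct(t_path),
               pct_vessel_associated = vessel_pct,
               pct_non_pathology = non_pct,
               pct_touching_plaque = pct(t_pl),
               pct_touching_tangle = if (is.null(tg)) NA_real_ else pct(t_tg))
  }))
  class(out) <- c("association_summary", "data.frame")
  out
}
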