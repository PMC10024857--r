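#' 2-D affine transforms between staining rounds
#'
#' A transform maps *fixed* (reference-round) pixel coordinates to *moving*
#' (later-round) pixel coordinates, the pull-back convention used by
#' [warp()]: the warped image at fixed pixel `p` is the moving image sampled
#' at `T(p)`. Coordinates are 0-based pixel centres, x rightward, y
#' downward, units pixels.
#'
#' @param A 2 x 3 affine parameter matrix: `T(x, y) = A %*% c(x, y, 1)`.
#' @param fixed_round,moving_round round labels.
#' @param similarity image-similarity score (normalized cross-correlation)
#'   achieved by the registration that produced the transform, if any.
#' @param displacement optional per-pixel displacement field (list of two
#'   matrices `dx`, `dy`, in pixels) added on top of the affine part.
#'
#' @return An object of class `round_transform`.
#' @export
round_transform <- function(A, fixed_round = NA, moving_round = NA,
                            similarity = NA_real_, displacement = NULL) {
  A <- base::matrix(as.numeric(A), 2L, 3L)
  if (any(!is.finite(A))) stop("affine parameters must be finite", call. = FALSE)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-12) stop("affine part is singular", call. = FALSE)
  if (!is.null(displacement)) {
    stopifnot(is.list(displacement), all(c("dx", "dy") %in% names(displacement)))
    if (any(!is.finite(displacement$dx)) || any(!is.finite(displacement$dy)))
      stop("displacement field must be finite", call. = FALSE)
  }
  structure(list(A = A, fixed_round = fixed_round, moving_round = moving_round,
                 similarity = similarity, displacement = displacement),
            class = "round_transform")
}

#' @rdname round_transform
#' @param angle_deg rotation angle, degrees, about `center` (positive =
#'   x-towards-y, i.e. clockwise on screen with y downward).
#' @param tx,ty translation, pixels: the content shift of the moving image
#'   relative to the fixed image.
#' @param center rotation centre `(x, y)` in pixels; defaults to the origin.
#' @export
rigid_transform <- function(angle_deg = 0, tx = 0, ty = 0, center = c(0, 0),
                            fixed_round = NA, moving_round = NA) {
  th <- angle_deg * pi / 180
  R <- base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  off <- center - R %*% center + c(tx, ty)
  round_transform(cbind(R, off), fixed_round, moving_round)
}

#' @rdname round_transform
#' @export
identity_transform <- function(fixed_round = NA, moving_round = NA) {
  round_transform(cbind(diag(2), c(0, 0)), fixed_round, moving_round)
}

#' @export
print.round_transform <- function(x, ...) {
  p <- decompose_transform(x)
  cat(sprintf(
    "<round_transform> %s -> %s: rot %.3f deg, shift (%.3f, %.3f) px, scale %.4f%s%s\n",
    as.character(x$fixed_round), as.character(x$moving_round),
    p["angle_deg"], p["tx"], p["ty"], p["scale"],
    if (!is.na(x$similarity)) sprintf(", NCC %.4f", x$similarity) else "",
    if (!is.null(x$displacement)) ", + displacement field" else ""))
  invisible(x)
}

#' @rdname round_transform
#' @param t,t1,t2 `round_transform` objects.
#' @export
invert_transform <- function(t) {
  R <- t$A[, 1:2]
  Ri <- solve(R)
  round_transform(cbind(Ri, -Ri %*% t$A[, 3]),
                  fixed_round = t$moving_round, moving_round = t$fixed_round)
}

#' @rdname round_transform
#' @export
compose_transform <- function(t1, t2) {
  # (t1 o t2)(x) = t1(t2(x))
  R <- t1$A[, 1:2] %*% t2$A[, 1:2]
  off <- t1$A[, 1:2] %*% t2$A[, 3] + t1$A[, 3]
  round_transform(cbind(R, off), fixed_round = t2$fixed_round,
                  moving_round = t1$moving_round)
}

#' @rdname round_transform
#' @param pts n x 2 matrix of `(x, y)` pixel coordinates.
#' @export
apply_transform <- function(t, pts) {
  pts <- base::matrix(as.numeric(pts), ncol = 2L)
  sweep(pts %*% t(t$A[, 1:2]), 2L, t$A[, 3], `+`)
}

# rotation angle / scale / shift summary of the affine part
decompose_transform <- function(t) {
  A <- t$A
  c(angle_deg = atan2(A[2, 1], A[1, 1]) * 180 / pi,
    tx = A[1, 3], ty = A[2, 3],
    scale = sqrt(abs(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])))
}

#' Serialize transforms to and from JSON
#'
#' @param t a `round_transform`.
#' @param path file path.
#' @return `read_transform_json()` returns a `round_transform`.
#' @export
write_transform_json <- function(t, path) {
  obj <- list(affine = as.vector(t$A), fixed_round = t$fixed_round,
              moving_round = t$moving_round, similarity = t$similarity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  round_transform(obj$affine, obj$fixed_round, obj$moving_round,
                  similarity = obj$similarity %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
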