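#' Resample an image through a transform
#'
#' Pull-back warping with bilinear interpolation: the output at fixed pixel
#' `(x, y)` is the moving image sampled at `T(x, y)` (plus the transform's
#' displacement field, if present). Samples falling outside the moving
#' image are set to 0 and recorded in the `"valid"` attribute, a logical
#' matrix that downstream area statistics use to exclude out-of-field
#' pixels.
#'
#' @param img a [density_map()], or a bare numeric matrix.
#' @param t a [round_transform()].
#' @param output_dim output grid `(ny, nx)`; defaults to the input grid.
#'
#' @return Same type as `img`, resampled onto the fixed grid, with
#'   attribute `valid` on the pixel matrix.
#' @export
warp <- function(img, t, output_dim = NULL) {
  m <- as_density_matrix(img)
  ny <- nrow(m); nx <- ncol(m)
  od <- if (is.null(output_dim)) c(ny, nx) else as.integer(output_dim)
  xs <- rep(seq_len(od[2]) - 1, each = od[1])
  ys <- rep.int(seq_len(od[1]) - 1, od[2])
  xm <- t$A[1, 1] * xs + t$A[1, 2] * ys + t$A[1, 3]
  ym <- t$A[2, 1] * xs + t$A[2, 2] * ys + t$A[2, 3]
  if (!is.null(t$displacement)) {
    xm <- xm + as.vector(t$displacement$dx)
    ym <- ym + as.vector(t$displacement$dy)
  }
  valid <- xm >= -1e-9 & ym >= -1e-9 & xm <= nx - 1 + 1e-9 & ym <= ny - 1 + 1e-9
  # clamp indices so gathers stay in bounds; invalid pixels zeroed below
  x0c <- pmin(pmax(floor(xm), 0), nx - 2); y0c <- pmin(pmax(floor(ym), 0), ny - 2)
  fx <- xm - x0c; fy <- ym - y0c
  i00 <- x0c * ny + y0c + 1
  v <- (1 - fx) * ((1 - fy) * m[i00] + fy * m[i00 + 1]) +
       fx       * ((1 - fy) * m[i00 + ny] + fy * m[i00 + ny + 1])
  v[!valid] <- 0
  out <- base::matrix(v, od[1], od[2])
  attr(out, "valid") <- base::matrix(valid, od[1], od[2])
  if (inherits(img, "density_map")) {
    dm <- density_map(out, img$microns_per_pixel, img$stain, img$round_id)
    attr(dm$pixels, "valid") <- attr(out, "valid")
    dm
  } else out
}

# integer-peak phase correlation; returns content shift s = (sx, sy) of the
# moving image relative to fixed, i.e. moving(x) ~ fixed(x - s)
phase_correlate <- function(fixed, moving) {
  f <- fixed - mean(fixed); g <- moving - mean(moving)
  Ff <- stats::fft(f); Fg <- stats::fft(g)
  cp <- Ff * Conj(Fg)
  mag <- Mod(cp)
  r <- Re(stats::fft(cp / pmax(mag, 1e-12), inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r)) - 1L     # (dy, dx), wrapped
  ny <- nrow(r); nx <- ncol(r)
  dy <- pk[1]; dx <- pk[2]
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(sx = -dx, sy = -dy)
}

ncc <- function(a, b, mask = NULL) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-12) return(0)
  sum(a * b) / den
}

#' Estimate the transform aligning one round onto the reference
#'
#' Registers the moving round's counterstain (hematoxylin) density map onto
#' the fixed round's: the counterstain is re-applied every round and so is
#' the only structure common to all rounds. The estimate is a coarse
#' rotation grid + phase-correlation translation initialization followed by
#' Nelder-Mead refinement of normalized cross-correlation (NCC). `"affine"`
#' refines all six affine parameters from the rigid solution; `"deformable"`
#' adds a block-wise phase-correlation displacement field (bilinearly
#' interpolated between block centres) on top of the rigid/affine fit.
#'
#' @param fixed,moving [density_map()] objects (or matrices) on the same
#'   calibration.
#' @param mode `"rigid"` (default), `"affine"`, or `"deformable"`.
#' @param max_rotation half-width of the coarse rotation search, degrees.
#' @param min_similarity registration-failure floor: final NCC below this
#'   raises an error of class `registration_failure`.
#' @param block_size block size (pixels) of the deformable displacement
#'   grid.
#'
#' @return A [round_transform()] with its `similarity` field set.
#' @export
estimate_transform <- function(fixed, moving,
                               mode = c("rigid", "affine", "deformable"),
                               max_rotation = 5, min_similarity = 0.1,
                               block_size = 128) {
  mode <- match.arg(mode)
  if (inherits(fixed, "density_map") && inherits(moving, "density_map") &&
      abs(fixed$microns_per_pixel - moving$microns_per_pixel) > 1e-9)
    stop("fixed and moving images have different calibrations", call. = FALSE)
  fr <- if (inherits(fixed, "density_map")) fixed$round_id else NA
  mr <- if (inherits(moving, "density_map")) moving$round_id else NA
  f <- as_density_matrix(fixed); g <- as_density_matrix(moving)
  if (!identical(dim(f), dim(g)))
    stop("fixed and moving images must share a grid", call. = FALSE)
  ctr <- c((ncol(f) - 1) / 2, (nrow(f) - 1) / 2)

  # coarse search: rotation grid x phase-correlation translation
  angles <- if (max_rotation > 0) seq(-max_rotation, max_rotation, by = 1) else 0
  best <- NULL
  for (a in angles) {
    tr <- rigid_transform(a, 0, 0, center = ctr)
    ga <- if (a == 0) g else warp(g, tr)
    s <- phase_correlate(f, ga)
    # shift applies in the rotated frame: T = rot o shift
    cand <- compose_transform(tr, rigid_transform(0, s["sx"], s["sy"]))
    w <- warp(g, cand)
    sc <- ncc(f, w, attr(w, "valid"))
    if (is.null(best) || sc > best$score)
      best <- list(par = c(a, apply_transform(cand, base::matrix(c(0, 0), 1))),
                   score = sc, cand = cand)
  }
  p0 <- c(decompose_transform(best$cand)["angle_deg"],
          best$cand$A[1, 3], best$cand$A[2, 3])

  obj_rigid <- function(p) {
    tr <- round_transform(cbind(rot2(p[1]), p[2:3]))
    w <- warp(g, tr)
    -ncc(f, w, attr(w, "valid"))
  }
  opt <- stats::optim(p0, obj_rigid, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  A <- cbind(rot2(opt$par[1]), opt$par[2:3])

  if (mode == "affine") {
    obj_aff <- function(p) {
      w <- warp(g, round_transform(base::matrix(p, 2, 3)))
      -ncc(f, w, attr(w, "valid"))
    }
    opt2 <- stats::optim(as.vector(A), obj_aff, method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 800))
    if (opt2$value < opt$value) { A <- base::matrix(opt2$par, 2, 3); opt <- opt2 }
  }

  t_out <- round_transform(A, fixed_round = fr, moving_round = mr,
                           similarity = -opt$value)

  if (mode == "deformable") {
    w <- warp(g, t_out)
    disp <- block_displacement(f, w, block_size)
    t_def <- round_transform(A, fixed_round = fr, moving_round = mr,
                             displacement = disp)
    wd <- warp(g, t_def)
    sc <- ncc(f, wd, attr(wd, "valid"))
    if (sc > t_out$similarity) {
      t_def$similarity <- sc
      t_out <- t_def
    }
  }

  if (t_out$similarity < min_similarity) {
    cond <- structure(
      class = c("registration_failure", "error", "condition"),
      list(message = sprintf(
        "registration similarity %.3f below floor %.3f; falling back to identity is the caller's choice",
        t_out$similarity, min_similarity), call = sys.call(-1)))
    stop(cond)
  }
  t_out
}

rot2 <- function(angle_deg) {
  th <- angle_deg * pi / 180
  base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# residual displacement between f and already-warped w, per block, then
# bilinearly interpolated to the full grid
block_displacement <- function(f, w, block_size) {
  ny <- nrow(f); nx <- ncol(f)
  by <- unique(pmin(seq(1, ny, by = block_size), ny - block_size + 1))
  bx <- unique(pmin(seq(1, nx, by = block_size), nx - block_size + 1))
  by <- by[by >= 1]; bx <- bx[bx >= 1]
  if (length(by) < 2L || length(bx) < 2L) {
    s <- phase_correlate(f, w)
    return(list(dx = base::matrix(s["sx"], ny, nx),
                dy = base::matrix(s["sy"], ny, nx)))
  }
  cy <- by + block_size / 2 - 1; cx <- bx + block_size / 2 - 1
  dxg <- base::matrix(0, length(by), length(bx))
  dyg <- dxg
  for (i in seq_along(by)) for (j in seq_along(bx)) {
    rows <- by[i]:(by[i] + block_size - 1)
    cols <- bx[j]:(bx[j] + block_size - 1)
    fb <- f[rows, cols]; wb <- w[rows, cols]
    if (sd(fb) < 1e-9 || sd(wb) < 1e-9) next
    s <- phase_correlate(fb, wb)
    # clamp: local flows beyond a quarter block are spurious
    lim <- block_size / 4
    dxg[i, j] <- max(min(s["sx"], lim), -lim)
    dyg[i, j] <- max(min(s["sy"], lim), -lim)
  }
  list(dx = interp_grid(dxg, cy, cx, ny, nx),
       dy = interp_grid(dyg, cy, cx, ny, nx))
}

# bilinear interpolation of a coarse grid (values at centres cy x cx) onto
# the full ny x nx pixel grid, constant extrapolation at borders
interp_grid <- function(vals, cy, cx, ny, nx) {
  yq <- pmin(pmax(seq_len(ny) - 1, cy[1]), cy[length(cy)])
  xq <- pmin(pmax(seq_len(nx) - 1, cx[1]), cx[length(cx)])
  iy <- findInterval(yq, cy, all.inside = TRUE)
  ix <- findInterval(xq, cx, all.inside = TRUE)
  fy <- (yq - cy[iy]) / pmax(cy[iy + 1] - cy[iy], 1e-9)
  fx <- (xq - cx[ix]) / pmax(cx[ix + 1] - cx[ix], 1e-9)
  v00 <- vals[cbind(rep(iy, length(ix)), rep(ix, each = length(iy)))]
  v10 <- vals[cbind(rep(iy + 1, length(ix)), rep(ix, each = length(iy)))]
  v01 <- vals[cbind(rep(iy, length(ix)), rep(ix + 1, each = length(iy)))]
  v11 <- vals[cbind(rep(iy + 1, length(ix)), rep(ix + 1, each = length(iy)))]
  FY <- rep(fy, length(ix)); FX <- rep(fx, each = length(iy))
  base::matrix((1 - FX) * ((1 - FY) * v00 + FY * v10) +
               FX * ((1 - FY) * v01 + FY * v11), ny, nx)
}
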